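#' @useDynLib sproutscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Declarative layer specifications.
#
# A layer_spec is a plain list describing one network block: either a leaf
# (convolution, pooling, upsampling, activation, linear) or a composite whose
# `children` carry the actual weights.  Composites come in two generic
# topologies ("seq" chains its children, "par" applies every child to the same
# input and concatenates along channels) plus a handful of structured kinds
# (c2f, sppf, se, bottleneck, orepa, focalmod) whose routing is implemented in
# the complexity walker and the forward engine.  Parameter counts of any
# composite are, by construction, the sum over its children.
# ---------------------------------------------------------------------------

VALID_KINDS <- c("conv", "dwconv", "pwconv", "linear", "activation",
                 "upsample", "maxpool", "avgpool", "globalpool", "identity",
                 "scale", "se", "seq", "par", "bottleneck", "c2f", "sppf",
                 "orepa", "focalmod")

VALID_ACTS <- c("silu", "relu", "h-swish", "h-sigmoid", "gelu", "sigmoid", "none")

new_layer_spec <- function(kind, ...) {
  spec <- c(list(kind = kind), list(...))
  class(spec) <- "layer_spec"
  spec
}

#' Test for layer specification objects
#' @param x object
#' @return logical
#' @export
is_layer_spec <- function(x) inherits(x, "layer_spec")

#' Convolution layer specification
#'
#' Describes a 2-d convolution with optional batch normalisation and fused
#' activation.  `kind` is derived from the arguments: `groups == in_channels ==
#' out_channels` gives a depthwise convolution, `kernel == 1` with
#' `groups == 1` a pointwise one.
#'
#' @param in_channels,out_channels channel counts
#' @param kernel odd kernel size (same padding `kernel %/% 2` is implied)
#' @param stride stride (1 or 2 in every assembled variant)
#' @param groups convolution groups; must divide both channel counts
#' @param bias logical, add a per-output-channel bias
#' @param bn logical, batch normalisation after the convolution
#' @param act activation name (one of silu, relu, h-swish, h-sigmoid, gelu,
#'   sigmoid, none)
#' @param name optional label used in per-layer reports
#' @return a `layer_spec`
#' @export
spec_conv <- function(in_channels, out_channels, kernel = 1, stride = 1,
                      groups = 1, bias = FALSE, bn = TRUE, act = "silu",
                      name = NULL) {
  stopifnot(in_channels >= 1, out_channels >= 1, kernel >= 1, stride >= 1)
  if (in_channels %% groups != 0 || out_channels %% groups != 0)
    stop("groups must divide in_channels and out_channels")
  act <- match.arg(act, VALID_ACTS)
  kind <- "conv"
  if (groups == in_channels && in_channels == out_channels && groups > 1)
    kind <- "dwconv"
  else if (kernel == 1 && groups == 1)
    kind <- "pwconv"
  new_layer_spec(kind,
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 groups = as.integer(groups), bias = bias, bn = bn, act = act,
                 name = name, children = list())
}

#' Depthwise convolution specification
#' @inheritParams spec_conv
#' @param channels channel count (preserved)
#' @export
spec_dwconv <- function(channels, kernel = 3, stride = 1, bias = FALSE,
                        bn = TRUE, act = "silu", name = NULL) {
  spec_conv(channels, channels, kernel, stride, groups = channels,
            bias = bias, bn = bn, act = act, name = name)
}

#' Pointwise (1x1) convolution specification
#' @inheritParams spec_conv
#' @export
spec_pwconv <- function(in_channels, out_channels, bias = FALSE, bn = TRUE,
                        act = "silu", name = NULL) {
  spec_conv(in_channels, out_channels, kernel = 1, stride = 1, groups = 1,
            bias = bias, bn = bn, act = act, name = name)
}

spec_activation <- function(channels, act) {
  new_layer_spec("activation", in_channels = channels, out_channels = channels,
                 act = match.arg(act, VALID_ACTS), children = list())
}

spec_upsample <- function(channels, factor = 2L) {
  new_layer_spec("upsample", in_channels = channels, out_channels = channels,
                 factor = as.integer(factor), children = list())
}

spec_maxpool <- function(channels, kernel = 5L, stride = 1L) {
  new_layer_spec("maxpool", in_channels = channels, out_channels = channels,
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 children = list())
}

spec_identity <- function(channels) {
  new_layer_spec("identity", in_channels = channels, out_channels = channels,
                 children = list())
}

# per-output-channel affine scaling (diagonal 1x1 conv); affine, so it can be
# folded during re-parameterization
spec_scale <- function(channels) {
  new_layer_spec("scale", in_channels = channels, out_channels = channels,
                 children = list())
}

#' Sequential composite
#' @param ... child `layer_spec`s (or a single list of them)
#' @param name optional label
#' @return a `layer_spec` of kind "seq"
#' @export
spec_seq <- function(..., name = NULL) {
  children <- list(...)
  if (length(children) == 1 && !is_layer_spec(children[[1]]))
    children <- children[[1]]
  stopifnot(length(children) >= 1, all(vapply(children, is_layer_spec, TRUE)))
  cin <- children[[1]]$in_channels
  cout <- children[[length(children)]]$out_channels
  new_layer_spec("seq", in_channels = cin, out_channels = cout,
                 name = name, children = children)
}

#' Parallel composite (channel concatenation)
#'
#' Every child is applied to the same input; outputs are concatenated along
#' the channel axis.  All children must agree on input channels and spatial
#' stride.
#' @inheritParams spec_seq
#' @export
spec_par <- function(..., name = NULL) {
  children <- list(...)
  if (length(children) == 1 && !is_layer_spec(children[[1]]))
    children <- children[[1]]
  cin <- unique(vapply(children, function(s) s$in_channels, 1L))
  stopifnot(length(cin) == 1)
  cout <- sum(vapply(children, function(s) s$out_channels, 1L))
  new_layer_spec("par", in_channels = cin, out_channels = as.integer(cout),
                 name = name, children = children)
}

#' Squeeze-and-excitation block specification
#'
#' Global average pooling followed by two 1x1 projections (ReLU then
#' hard-sigmoid gate) whose output rescales the channels.
#' @param channels input/output channels
#' @param reduction bottleneck reduction ratio
#' @export
spec_se <- function(channels, reduction = 4L) {
  mid <- max(1L, as.integer(channels) %/% as.integer(reduction))
  fc1 <- spec_conv(channels, mid, 1, bias = TRUE, bn = FALSE, act = "relu")
  fc2 <- spec_conv(mid, channels, 1, bias = TRUE, bn = FALSE, act = "h-sigmoid")
  new_layer_spec("se", in_channels = channels, out_channels = channels,
                 reduction = as.integer(reduction), children = list(fc1, fc2))
}

# YOLOv8 residual bottleneck: two 3x3 convs, optional identity shortcut
spec_bottleneck_yolo <- function(channels, shortcut = TRUE) {
  cv1 <- spec_conv(channels, channels, 3, act = "silu")
  cv2 <- spec_conv(channels, channels, 3, act = "silu")
  new_layer_spec("bottleneck", in_channels = channels, out_channels = channels,
                 shortcut = shortcut, children = list(cv1, cv2))
}

#' C2f cross-stage block specification
#'
#' The YOLOv8 cross-stage partial block: a 1x1 expansion split in half, `n`
#' residual bottlenecks chained on the second half, concatenation of all
#' intermediate chunks and a final 1x1 projection.
#' @param c1,c2 input / output channels
#' @param n number of bottlenecks
#' @param shortcut use identity shortcuts inside bottlenecks
#' @param e hidden-width expansion ratio
#' @export
spec_c2f <- function(c1, c2, n = 1L, shortcut = FALSE, e = 0.5) {
  h <- as.integer(round(c2 * e))
  cv1 <- spec_conv(c1, 2L * h, 1, act = "silu")
  m <- lapply(seq_len(n), function(i) spec_bottleneck_yolo(h, shortcut))
  cv2 <- spec_conv((2L + n) * h, c2, 1, act = "silu")
  new_layer_spec("c2f", in_channels = as.integer(c1),
                 out_channels = as.integer(c2), n = as.integer(n),
                 hidden = h, shortcut = shortcut,
                 children = c(list(cv1), m, list(cv2)))
}

#' SPPF spatial pyramid pooling specification
#' @param c1,c2 input / output channels
#' @param k pooling kernel (applied three times, stride 1)
#' @export
spec_sppf <- function(c1, c2, k = 5L) {
  h <- as.integer(c1) %/% 2L
  cv1 <- spec_conv(c1, h, 1, act = "silu")
  cv2 <- spec_conv(4L * h, c2, 1, act = "silu")
  new_layer_spec("sppf", in_channels = as.integer(c1),
                 out_channels = as.integer(c2), pool_kernel = as.integer(k),
                 hidden = h, children = list(cv1, cv2))
}

#' @export
print.layer_spec <- function(x, indent = 0, ...) {
  pad <- strrep("  ", indent)
  hdr <- sprintf("%s%s %d->%d", pad, x$kind,
                 x$in_channels %||% NA_integer_, x$out_channels %||% NA_integer_)
  if (!is.null(x$kernel)) hdr <- paste0(hdr, sprintf(" k%d", x$kernel))
  if (!is.null(x$stride) && identical(x$stride, 2L)) hdr <- paste0(hdr, " s2")
  if (!is.null(x$name)) hdr <- paste0(hdr, "  [", x$name, "]")
  cat(hdr, "\n")
  for (ch in x$children) print(ch, indent = indent + 1)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
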