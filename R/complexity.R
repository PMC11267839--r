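# ---------------------------------------------------------------------------
# Complexity accounting over layer_spec trees and variant graphs.
#
# Parameter counts are exact enumeration of weights: a convolution contributes
# (C_in/groups) * K^2 * C_out weights, plus C_out if it has a bias, plus
# 2 * C_out (gamma, beta) if it is followed by batch normalisation; running
# statistics are not parameters.  The headline FLOP figure follows the
# 2 * H * W * (C_in K^2 / groups + [bias]) * C_out convention, i.e. one
# multiply-accumulate = 2 FLOPs, summed over convolution/linear layers only;
# elementwise work (BN, activations, pooling, upsampling, additions) is
# tallied in a separate column of the per-layer table and excluded from the
# headline GFLOPs, matching how the printed budgets of deployed detectors are
# conventionally measured.
# ---------------------------------------------------------------------------

#' Parameter count of a layer specification
#'
#' Exact weight enumeration: convolutions count `(C_in/groups) * K^2 * C_out`
#' weights plus bias and batch-norm affine terms; composites are the sum over
#' their children.  A re-parameterized (deployed) OREPA block counts as a
#' single 3x3 convolution with bias.
#'
#' @param spec a `layer_spec`
#' @return integer-valued numeric count
#' @export
layer_params <- function(spec) {
  stopifnot(is_layer_spec(spec))
  k <- spec$kind
  if (k %in% c("conv", "dwconv", "pwconv", "linear")) {
    if (is.null(spec$in_channels) || is.null(spec$out_channels))
      stop("unresolved layer spec: channel counts missing")
    w <- (spec$in_channels / spec$groups) * spec$kernel^2 * spec$out_channels
    w + (if (isTRUE(spec$bias)) spec$out_channels else 0) +
      (if (isTRUE(spec$bn)) 2 * spec$out_channels else 0)
  } else if (k == "scale") {
    spec$out_channels
  } else if (k == "orepa" && isTRUE(spec$deployed)) {
    spec$in_channels * 9 * spec$out_channels + spec$out_channels
  } else if (k %in% c("activation", "upsample", "maxpool", "avgpool",
                      "globalpool", "identity")) {
    0
  } else {
    sum(vapply(spec$children, layer_params, numeric(1)))
  }
}

conv_out_hw <- function(h, w, kernel, stride) {
  p <- kernel %/% 2
  c(floor((h + 2 * p - kernel) / stride) + 1,
    floor((w + 2 * p - kernel) / stride) + 1)
}

#' Output shape of a layer specification
#' @param spec a `layer_spec`
#' @param shape input shape `c(channels, height, width)`
#' @return output shape `c(channels, height, width)`
#' @export
spec_out_shape <- function(spec, shape) {
  stopifnot(is_layer_spec(spec), length(shape) == 3)
  k <- spec$kind
  if (k %in% c("conv", "dwconv", "pwconv")) {
    if (shape[1] != spec$in_channels)
      stop(sprintf("channel mismatch: spec expects %d, input has %d",
                   spec$in_channels, shape[1]))
    hw <- conv_out_hw(shape[2], shape[3], spec$kernel, spec$stride)
    c(spec$out_channels, hw)
  } else if (k == "maxpool" || k == "avgpool") {
    hw <- conv_out_hw(shape[2], shape[3], spec$kernel, spec$stride)
    c(shape[1], hw)
  } else if (k == "upsample") {
    c(shape[1], shape[2] * spec$factor, shape[3] * spec$factor)
  } else if (k == "globalpool") {
    c(shape[1], 1, 1)
  } else if (k == "seq") {
    for (ch in spec$children) shape <- spec_out_shape(ch, shape)
    shape
  } else if (k == "par") {
    shapes <- lapply(spec$children, spec_out_shape, shape = shape)
    hs <- unique(vapply(shapes, `[`, 1, i = 2))
    stopifnot(length(hs) == 1)
    c(sum(vapply(shapes, `[`, 1, i = 1)), shapes[[1]][2], shapes[[1]][3])
  } else {
    # shape-preserving structured blocks (channel count from the spec)
    if (shape[1] != spec$in_channels)
      stop(sprintf("channel mismatch: spec expects %d, input has %d",
                   spec$in_channels, shape[1]))
    c(spec$out_channels, shape[2], shape[3])
  }
}

#' FLOP count of a layer specification
#'
#' Headline count: `2 * H_out * W_out * (C_in K^2 / groups + [bias]) * C_out`
#' per convolution/linear layer, summed over the tree; `[bias]` is 1 when the
#' layer has a bias and 0 otherwise.  Elementwise operations (batch
#' normalisation, activations, pooling comparisons, upsampling copies,
#' residual additions) are counted at 1-2 ops per element and returned
#' separately.
#'
#' @param spec a `layer_spec`
#' @param h,w input spatial size
#' @return named numeric vector `c(conv = ..., elem = ...)`
#' @export
layer_flops <- function(spec, h, w) {
  stopifnot(is_layer_spec(spec))
  if (missing(h) || missing(w) || is.null(h) || is.null(w))
    stop("input spatial size is required for FLOP accounting")
  k <- spec$kind
  zero <- c(conv = 0, elem = 0)
  if (k %in% c("conv", "dwconv", "pwconv", "linear")) {
    hw <- conv_out_hw(h, w, spec$kernel, spec$stride)
    n_out <- hw[1] * hw[2] * spec$out_channels
    macs <- hw[1] * hw[2] * (spec$in_channels / spec$groups) * spec$kernel^2 *
      spec$out_channels
    conv <- 2 * macs + (if (isTRUE(spec$bias)) 2 * hw[1] * hw[2] * spec$out_channels else 0)
    elem <- (if (isTRUE(spec$bn)) 2 * n_out else 0) +
      (if (!identical(spec$act, "none")) n_out else 0)
    c(conv = conv, elem = elem)
  } else if (k == "scale") {
    c(conv = 0, elem = h * w * spec$out_channels)
  } else if (k == "activation") {
    c(conv = 0, elem = h * w * spec$in_channels)
  } else if (k == "upsample") {
    c(conv = 0, elem = (h * spec$factor) * (w * spec$factor) * spec$in_channels)
  } else if (k %in% c("maxpool", "avgpool")) {
    hw <- conv_out_hw(h, w, spec$kernel, spec$stride)
    c(conv = 0, elem = hw[1] * hw[2] * spec$in_channels * spec$kernel^2)
  } else if (k == "globalpool") {
    c(conv = 0, elem = h * w * spec$in_channels)
  } else if (k == "identity") {
    zero
  } else if (k == "seq") {
    tot <- zero
    shape <- c(spec$in_channels, h, w)
    for (ch in spec$children) {
      tot <- tot + layer_flops(ch, shape[2], shape[3])
      shape <- spec_out_shape(ch, shape)
    }
    tot
  } else if (k == "par") {
    Reduce(`+`, lapply(spec$children, layer_flops, h = h, w = w), zero)
  } else if (k == "bottleneck") {
    tot <- Reduce(`+`, lapply(spec$children, layer_flops, h = h, w = w), zero)
    if (isTRUE(spec$shortcut)) tot["elem"] <- tot["elem"] + h * w * spec$out_channels
    tot
  } else if (k == "c2f") {
    tot <- Reduce(`+`, lapply(spec$children, layer_flops, h = h, w = w), zero)
    tot["elem"] <- tot["elem"] + h * w * spec$hidden  # split bookkeeping
    tot
  } else if (k == "sppf") {
    cv1 <- layer_flops(spec$children[[1]], h, w)
    cv2 <- layer_flops(spec$children[[2]], h, w)
    pools <- 3 * h * w * spec$hidden * spec$pool_kernel^2
    cv1 + cv2 + c(conv = 0, elem = pools)
  } else if (k == "se") {
    inner <- Reduce(`+`, lapply(spec$children, layer_flops, h = 1, w = 1), zero)
    inner + c(conv = 0, elem = 2 * h * w * spec$in_channels)
  } else if (k == "orepa") {
    if (isTRUE(spec$deployed)) {
      n_out <- h * w * spec$out_channels
      c(conv = 2 * h * w * (spec$in_channels * 9 + 1) * spec$out_channels,
        elem = 0)
    } else {
      tot <- Reduce(`+`, lapply(spec$children, layer_flops, h = h, w = w), zero)
      tot + c(conv = 0, elem = (length(spec$children) - 1) * h * w * spec$out_channels)
    }
  } else if (k == "focalmod") {
    tot <- Reduce(`+`, lapply(spec$children, layer_flops, h = h, w = w), zero)
    # gating, modulation and the global-average level are elementwise
    tot + c(conv = 0, elem = (spec$levels + 3) * h * w * spec$dim)
  } else {
    stop("unknown layer kind: ", k)
  }
}

# --------------------------------------------------------------------------
# Graph walkers.  A variant graph is a list of nodes
#   list(id = "p3", from = c("a", "b"), spec = <layer_spec> or NULL)
# evaluated in order; multiple inputs are concatenated along channels, a NULL
# spec is a pure concatenation/identity node.  The graph input is named "in".
# --------------------------------------------------------------------------

graph_walk_shapes <- function(graph, in_shape) {
  env <- list("in" = in_shape)
  for (nd in graph) {
    shapes <- lapply(nd$from, function(f) {
      if (is.null(env[[f]])) stop("graph references unknown node: ", f)
      env[[f]]
    })
    hs <- unique(vapply(shapes, `[`, 1, i = 2))
    ws <- unique(vapply(shapes, `[`, 1, i = 3))
    if (length(hs) != 1 || length(ws) != 1)
      stop("spatial mismatch at graph node ", nd$id)
    shape <- c(sum(vapply(shapes, `[`, 1, i = 1)), hs, ws)
    if (!is.null(nd$spec)) shape <- spec_out_shape(nd$spec, shape)
    env[[nd$id]] <- shape
  }
  env
}

graph_params <- function(graph) {
  sum(vapply(graph, function(nd)
    if (is.null(nd$spec)) 0 else layer_params(nd$spec), numeric(1)))
}

graph_flops <- function(graph, in_shape) {
  env <- list("in" = in_shape)
  per <- data.frame(node = character(0), params = numeric(0),
                    flops = numeric(0), elem_ops = numeric(0),
                    out_c = integer(0), out_h = integer(0), out_w = integer(0),
                    stringsAsFactors = FALSE)
  for (nd in graph) {
    shapes <- lapply(nd$from, function(f) env[[f]])
    shape <- c(sum(vapply(shapes, `[`, 1, i = 1)),
               shapes[[1]][2], shapes[[1]][3])
    fl <- c(conv = 0, elem = 0)
    pp <- 0
    if (!is.null(nd$spec)) {
      fl <- layer_flops(nd$spec, shape[2], shape[3])
      pp <- layer_params(nd$spec)
      shape <- spec_out_shape(nd$spec, shape)
    }
    per <- rbind(per, data.frame(node = nd$id, params = pp, flops = fl[["conv"]],
                                 elem_ops = fl[["elem"]], out_c = shape[1],
                                 out_h = shape[2], out_w = shape[3],
                                 stringsAsFactors = FALSE))
    env[[nd$id]] <- shape
  }
  per
}

#' Complexity report for a variant or a single block
#'
#' Aggregates exact parameter counts and the Eq.-style FLOP accounting over a
#' model variant (or any `layer_spec`), reporting totals in the print format
#' used for detector budgets: parameters in millions to 2 decimals, GFLOPs to
#' 1 decimal, and the serialized checkpoint size at the requested precision.
#'
#' @param x a `variant_spec` (see [assemble_variant()]) or a `layer_spec`
#' @param input_size input image side in pixels; must be divisible by 32 for
#'   variant graphs
#' @param precision "fp16" or "fp32"; governs the weight-size estimate
#' @return an object of class `complexity_report` with fields `params`,
#'   `params_millions`, `flops`, `gflops`, `weight_bytes` and a `per_layer`
#'   data frame
#' @export
complexity_report <- function(x, input_size = 640, precision = c("fp16", "fp32")) {
  precision <- match.arg(precision)
  bytes <- if (precision == "fp16") 2 else 4
  if (inherits(x, "variant_spec")) {
    if (input_size %% 32 != 0)
      stop("input_size must be divisible by 32")
    per <- graph_flops(x$graph, c(3, input_size, input_size))
    # fixed box-distribution (DFL) kernel; applied during decoding
    per <- rbind(per, data.frame(node = "dfl", params = x$reg_max, flops = 0,
                                 elem_ops = 0, out_c = 4L, out_h = NA_integer_,
                                 out_w = NA_integer_, stringsAsFactors = FALSE))
    params <- sum(per$params)
    flops <- sum(per$flops)
    n_tensors <- length(flatten_weight_slots(x))
  } else if (is_layer_spec(x)) {
    if (is.null(x$in_channels)) stop("unresolved spec")
    params <- layer_params(x)
    fl <- layer_flops(x, input_size, input_size)
    flops <- fl[["conv"]]
    per <- data.frame(node = x$kind, params = params, flops = flops,
                      elem_ops = fl[["elem"]], stringsAsFactors = FALSE)
    n_tensors <- max(1, round(params / 1000))
  } else stop("x must be a variant_spec or layer_spec")
  out <- list(params = params,
              params_millions = round(params / 1e6, 2),
              flops = flops,
              gflops = round(flops / 1e9, 1),
              weight_bytes = params * bytes + 64 * n_tensors + 32,
              precision = precision,
              input_size = input_size,
              per_layer = per)
  class(out) <- "complexity_report"
  out
}

#' @export
print.complexity_report <- function(x, ...) {
  cat(sprintf("complexity report (input %dx%d, %s)\n", x$input_size,
              x$input_size, x$precision))
  cat(sprintf("  params : %s  (%.2f M)\n", format(x$params, big.mark = ","),
              x$params_millions))
  cat(sprintf("  flops  : %s  (%.1f G)\n", format(x$flops, big.mark = ","),
              x$gflops))
  cat(sprintf("  weights: %.1f MB (%s)\n", x$weight_bytes / 2^20, x$precision))
  invisible(x)
}
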