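# ---------------------------------------------------------------------------
# Online re-parameterization (OREPA): a multi-branch block of purely affine
# branches (3x3 conv, 1x1 conv, 1x1->3x3 sequence, average-pool prior, each
# with batch norm and a per-branch channel scaling) trained as a sum and
# squeezed exactly into one 3x3 convolution + bias for deployment.
# ---------------------------------------------------------------------------

OREPA_BRANCH_TYPES <- c("conv3", "conv1", "conv1_3", "avgprior")

#' OREPA block specification
#'
#' @param in_channels,out_channels channel counts (3x3 convolution, stride 1)
#' @param deployed if TRUE the spec describes the squeezed single 3x3
#'   convolution + bias; otherwise the multi-branch training form
#' @param branches character vector of branch types out of
#'   `conv3`, `conv1`, `conv1_3`, `avgprior`
#' @param mid hidden width of the 1x1->3x3 branch
#' @return a `layer_spec` of kind "orepa"
#' @export
spec_orepa <- function(in_channels, out_channels, deployed = FALSE,
                       branches = OREPA_BRANCH_TYPES,
                       mid = max(4L, in_channels %/% 2L)) {
  stopifnot(all(branches %in% OREPA_BRANCH_TYPES))
  cin <- as.integer(in_channels); cout <- as.integer(out_channels)
  children <- list()
  if (!deployed) {
    mk <- function(type) {
      body <- switch(type,
        conv3 = list(spec_conv(cin, cout, 3, bn = TRUE, act = "none")),
        conv1 = list(spec_conv(cin, cout, 1, bn = TRUE, act = "none")),
        conv1_3 = list(spec_conv(cin, mid, 1, bn = FALSE, act = "none"),
                       spec_conv(mid, cout, 3, bn = TRUE, act = "none")),
        avgprior = list(spec_conv(cin, cout, 1, bn = FALSE, act = "none"),
                        new_layer_spec("avgpool", in_channels = cout,
                                       out_channels = cout, kernel = 3L,
                                       stride = 1L, children = list()),
                        # batch norm after the pool (a per-channel affine,
                        # held as a depthwise 1x1): keeps the zero-padded
                        # border rows exactly squeezable
                        spec_conv(cout, cout, 1, groups = cout, bn = TRUE,
                                  act = "none")))
      spec_seq(c(body, list(spec_scale(cout))), name = paste0("orepa_", type))
    }
    children <- lapply(branches, mk)
  }
  new_layer_spec("orepa", in_channels = cin, out_channels = cout,
                 deployed = deployed, branches = branches, mid = as.integer(mid),
                 children = children)
}

#' Construct an instantiated OREPA block
#'
#' Builds the multi-branch training form with randomly initialised weights
#' and (optionally non-trivial) frozen batch-norm statistics, ready for
#' [orepa_forward()] and [squeeze_orepa()].
#'
#' @inheritParams spec_orepa
#' @param frozen whether batch-norm statistics are frozen (squeezing is exact
#'   only with frozen statistics)
#' @param seed RNG seed for the weight draw
#' @return an object of class `orepa_block`
#' @export
orepa_block <- function(in_channels, out_channels,
                        branches = OREPA_BRANCH_TYPES,
                        mid = max(4L, in_channels %/% 2L),
                        frozen = TRUE, seed = NULL) {
  spec <- spec_orepa(in_channels, out_channels, deployed = FALSE,
                     branches = branches, mid = mid)
  if (!is.null(seed)) set.seed(seed)
  weights <- init_weights(spec, bn_random = TRUE)
  structure(list(spec = spec, weights = weights, frozen = frozen),
            class = "orepa_block")
}

#' Multi-branch OREPA forward pass
#'
#' Evaluates the block as the sum over its affine branches.  Refuses squeezed
#' blocks (use the plain convolution path for those).
#'
#' @param block an `orepa_block`
#' @param x input array of shape (H, W, C_in)
#' @return output array of shape (H, W, C_out)
#' @export
orepa_forward <- function(block, x) {
  stopifnot(inherits(block, "orepa_block"))
  if (isTRUE(block$spec$deployed))
    stop("block is squeezed; route through the single-convolution path")
  spec_forward(block$spec, block$weights, x)
}

#' Squeeze an OREPA block into a single 3x3 convolution
#'
#' Exact re-parameterization: 1x1 kernels are zero-padded to the 3x3 centre,
#' 1x1->3x3 sequences are merged by kernel composition, the average-pool
#' prior becomes a uniform 1/9 kernel composed with its 1x1 projection, batch
#' norm is folded as `w * gamma / sigma`, `b = beta - mu * gamma / sigma`,
#' and per-branch channel scalings multiply through.  The branch kernels and
#' biases are then summed.
#'
#' @param block an `orepa_block` with frozen batch-norm statistics
#' @return an `orepa_block` whose spec is the deployed single convolution,
#'   with weight fields `w` (3,3,C_in,C_out) and `b` (C_out)
#' @export
squeeze_orepa <- function(block) {
  stopifnot(inherits(block, "orepa_block"))
  if (!isTRUE(block$frozen))
    stop("batch-norm statistics are not frozen; squeezing would not be exact")
  spec <- block$spec
  cin <- spec$in_channels; cout <- spec$out_channels
  W <- array(0, dim = c(3, 3, cin, cout))
  b <- numeric(cout)
  for (bi in seq_along(spec$children)) {
    br <- spec$children[[bi]]
    wts <- block$weights$children[[bi]]
    eq <- squeeze_branch(br, wts, cin, cout)
    W <- W + eq$w
    b <- b + eq$b
  }
  dep_spec <- spec_orepa(cin, cout, deployed = TRUE, branches = spec$branches,
                         mid = spec$mid)
  structure(list(spec = dep_spec, weights = list(w = W, b = b),
                 frozen = TRUE), class = "orepa_block")
}

# Fold one affine branch into an equivalent (3x3 kernel, bias) pair.
# Branch layouts (built by spec_orepa): conv3 = [conv3+BN, scale];
# conv1 = [conv1+BN, scale]; conv1_3 = [conv1, conv3+BN, scale];
# avgprior = [conv1+BN, avgpool3, scale].
squeeze_branch <- function(branch, wts, cin, cout) {
  type <- sub("^orepa_", "", branch$name)
  kids <- branch$children
  kw <- wts$children
  bn_fold <- function(W, b, bn) {
    g <- bn$gamma / sqrt(bn$var + bn$eps)
    for (o in seq_len(cout)) W[, , , o] <- W[, , , o] * g[o]
    list(w = W, b = b * g + bn$beta - bn$mean * g)
  }
  if (type == "conv3") {
    W <- kw[[1]]$w
    f <- bn_fold(W, numeric(cout), kw[[1]]$bn)
    scale_i <- 2L
  } else if (type == "conv1") {
    W <- array(0, dim = c(3, 3, cin, cout))
    W[2, 2, , ] <- kw[[1]]$w[1, 1, , ]
    f <- bn_fold(W, numeric(cout), kw[[1]]$bn)
    scale_i <- 2L
  } else if (type == "conv1_3") {
    W1 <- matrix(kw[[1]]$w[1, 1, , ], nrow = cin)           # cin x mid
    W3 <- kw[[2]]$w                                          # 3,3,mid,cout
    W <- array(0, dim = c(3, 3, cin, cout))
    for (u in 1:3) for (v in 1:3)
      W[u, v, , ] <- W1 %*% matrix(W3[u, v, , ], nrow = ncol(W1))
    f <- bn_fold(W, numeric(cout), kw[[2]]$bn)
    scale_i <- 3L
  } else if (type == "avgprior") {
    W <- array(0, dim = c(3, 3, cin, cout))
    w1 <- matrix(kw[[1]]$w[1, 1, , ], nrow = cin)
    for (u in 1:3) for (v in 1:3) W[u, v, , ] <- w1 / 9
    # per-channel affine (depthwise 1x1 + BN) applied after the pool
    wdw <- as.numeric(kw[[3]]$w)
    for (o in seq_len(cout)) W[, , , o] <- W[, , , o] * wdw[o]
    f <- bn_fold(W, numeric(cout), kw[[3]]$bn)
    scale_i <- 4L
  } else stop("unknown OREPA branch type: ", type)
  s <- kw[[scale_i]]$s
  for (o in seq_len(cout)) f$w[, , , o] <- f$w[, , , o] * s[o]
  f$b <- f$b * s
  f
}
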