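# ---------------------------------------------------------------------------
# Numeric forward engine.  Feature maps are numeric arrays (H, W, C);
# convolution weights are (kh, kw, cin_per_group, cout) arrays evaluated by
# the compiled kernels in src/.  Weights mirror the layer_spec tree:
# leaves get list(w, b, bn = list(gamma, beta, mean, var, eps), s), composites
# get list(children = list(...)).
# ---------------------------------------------------------------------------

relu6 <- function(x) pmin(pmax(x, 0), 6)

apply_act <- function(x, act) {
  switch(act,
         none = x,
         silu = x * stats::plogis(x),
         relu = pmax(x, 0),
         `h-swish` = x * relu6(x + 3) / 6,
         `h-sigmoid` = relu6(x + 3) / 6,
         gelu = 0.5 * x * (1 + tanh(sqrt(2 / pi) * (x + 0.044715 * x^3))),
         sigmoid = stats::plogis(x),
         stop("unknown activation: ", act))
}

concat_ch <- function(lst) {
  d <- dim(lst[[1]])
  array(unlist(lst, use.names = FALSE),
        dim = c(d[1], d[2], sum(vapply(lst, function(a) dim(a)[3], 1))))
}

apply_bn <- function(x, bn) {
  C <- dim(x)[3]
  g <- bn$gamma / sqrt(bn$var + bn$eps)
  b <- bn$beta - bn$mean * g
  x * rep(g, each = dim(x)[1] * dim(x)[2]) + rep(b, each = dim(x)[1] * dim(x)[2])
}

# Random-normal weight initialisation mirroring a spec tree.  bn_random draws
# non-trivial frozen batch-norm statistics and channel scalings, used to
# exercise re-parameterization; the default is identity statistics.
init_weights <- function(spec, bn_random = FALSE) {
  k <- spec$kind
  if (k %in% c("conv", "dwconv", "pwconv", "linear")) {
    cpg <- spec$in_channels / spec$groups
    fan_in <- cpg * spec$kernel^2
    w <- array(stats::rnorm(spec$kernel^2 * cpg * spec$out_channels,
                            sd = sqrt(2 / fan_in)),
               dim = c(spec$kernel, spec$kernel, cpg, spec$out_channels))
    out <- list(w = w)
    if (isTRUE(spec$bias)) out$b <- numeric(spec$out_channels)
    if (isTRUE(spec$bn)) {
      out$bn <- if (bn_random)
        list(gamma = stats::runif(spec$out_channels, 0.5, 1.5),
             beta = stats::rnorm(spec$out_channels, 0, 0.2),
             mean = stats::rnorm(spec$out_channels, 0, 0.5),
             var = stats::runif(spec$out_channels, 0.5, 2),
             eps = 1e-5)
      else
        list(gamma = rep(1, spec$out_channels),
             beta = numeric(spec$out_channels),
             mean = numeric(spec$out_channels),
             var = rep(1, spec$out_channels), eps = 1e-5)
    }
    out
  } else if (k == "scale") {
    list(s = if (bn_random) stats::runif(spec$out_channels, 0.5, 1.5)
         else rep(1, spec$out_channels))
  } else if (k == "orepa" && isTRUE(spec$deployed)) {
    fan_in <- spec$in_channels * 9
    list(w = array(stats::rnorm(9 * spec$in_channels * spec$out_channels,
                                sd = sqrt(2 / fan_in)),
                   dim = c(3, 3, spec$in_channels, spec$out_channels)),
         b = numeric(spec$out_channels))
  } else if (length(spec$children) > 0) {
    list(children = lapply(spec$children, init_weights, bn_random = bn_random))
  } else {
    list()
  }
}

#' Forward pass through a layer specification
#'
#' @param spec a `layer_spec`
#' @param weights matching weight tree (see [init_weights()] internals)
#' @param x numeric array (H, W, C)
#' @return numeric array (H', W', C')
#' @export
spec_forward <- function(spec, weights, x) {
  k <- spec$kind
  if (k %in% c("conv", "dwconv", "pwconv", "linear")) {
    y <- conv2d_hwc(x, weights[["w"]],
                    if (is.null(weights[["b"]])) numeric(0) else weights[["b"]],
                    spec$stride, spec$kernel %/% 2L, spec$groups)
    if (!is.null(weights[["bn"]])) y <- apply_bn(y, weights[["bn"]])
    apply_act(y, spec$act)
  } else if (k == "scale") {
    x * rep(weights[["s"]], each = dim(x)[1] * dim(x)[2])
  } else if (k == "activation") {
    apply_act(x, spec$act)
  } else if (k == "identity") {
    x
  } else if (k == "upsample") {
    upsample_nearest_hwc(x, spec$factor)
  } else if (k == "maxpool") {
    pool2d_hwc(x, spec$kernel, spec$stride, spec$kernel %/% 2L, TRUE)
  } else if (k == "avgpool") {
    pool2d_hwc(x, spec$kernel, spec$stride, spec$kernel %/% 2L, FALSE)
  } else if (k == "globalpool") {
    m <- apply(x, 3, mean)
    array(rep(m, each = 1), dim = c(1, 1, length(m)))
  } else if (k == "seq") {
    for (i in seq_along(spec$children))
      x <- spec_forward(spec$children[[i]], weights[["children"]][[i]], x)
    x
  } else if (k == "par") {
    concat_ch(lapply(seq_along(spec$children), function(i)
      spec_forward(spec$children[[i]], weights[["children"]][[i]], x)))
  } else if (k == "bottleneck") {
    y <- spec_forward(spec$children[[1]], weights[["children"]][[1]], x)
    y <- spec_forward(spec$children[[2]], weights[["children"]][[2]], y)
    if (isTRUE(spec$shortcut)) x + y else y
  } else if (k == "c2f") {
    n <- spec$n; h <- spec$hidden
    y <- spec_forward(spec$children[[1]], weights[["children"]][[1]], x)
    chunks <- list(y[, , seq_len(h), drop = FALSE],
                   y[, , h + seq_len(h), drop = FALSE])
    cur <- chunks[[2]]
    for (i in seq_len(n)) {
      cur <- spec_forward(spec$children[[1 + i]], weights[["children"]][[1 + i]], cur)
      chunks[[length(chunks) + 1]] <- cur
    }
    spec_forward(spec$children[[n + 2]], weights[["children"]][[n + 2]],
                 concat_ch(chunks))
  } else if (k == "sppf") {
    y <- spec_forward(spec$children[[1]], weights[["children"]][[1]], x)
    p1 <- pool2d_hwc(y, spec$pool_kernel, 1L, spec$pool_kernel %/% 2L, TRUE)
    p2 <- pool2d_hwc(p1, spec$pool_kernel, 1L, spec$pool_kernel %/% 2L, TRUE)
    p3 <- pool2d_hwc(p2, spec$pool_kernel, 1L, spec$pool_kernel %/% 2L, TRUE)
    spec_forward(spec$children[[2]], weights[["children"]][[2]],
                 concat_ch(list(y, p1, p2, p3)))
  } else if (k == "se") {
    m <- apply(x, 3, mean)
    w1 <- weights[["children"]][[1]]; s1 <- spec$children[[1]]
    w2 <- weights[["children"]][[2]]; s2 <- spec$children[[2]]
    v <- apply_act(drop(crossprod(matrix(w1[["w"]][1, 1, , ],
                                         nrow = s1$in_channels), m)) + w1[["b"]],
                   s1$act)
    g <- apply_act(drop(crossprod(matrix(w2[["w"]][1, 1, , ],
                                         nrow = s2$in_channels), v)) + w2[["b"]],
                   s2$act)
    x * rep(g, each = dim(x)[1] * dim(x)[2])
  } else if (k == "orepa") {
    if (isTRUE(spec$deployed)) {
      conv2d_hwc(x, weights[["w"]], weights[["b"]], 1L, 1L, 1L)
    } else {
      outs <- lapply(seq_along(spec$children), function(i)
        spec_forward(spec$children[[i]], weights[["children"]][[i]], x))
      Reduce(`+`, outs)
    }
  } else if (k == "focalmod") {
    L <- spec$levels
    q <- spec_forward(spec$children[[1]], weights[["children"]][[1]], x)
    z <- spec_forward(spec$children[[2]], weights[["children"]][[2]], x)
    gates <- spec_forward(spec$children[[3]], weights[["children"]][[3]], x)
    hw <- dim(x)[1] * dim(x)[2]
    m <- array(0, dim = dim(q))
    for (l in seq_len(L)) {
      z <- spec_forward(spec$children[[3 + l]], weights[["children"]][[3 + l]], z)
      m <- m + z * rep(as.vector(gates[, , l]), times = spec$dim)
    }
    zg <- rep(apply(z, 3, mean), each = hw)   # global-average context level
    m <- m + array(zg, dim = dim(q)) * rep(as.vector(gates[, , L + 1]),
                                           times = spec$dim)
    m <- spec_forward(spec$children[[L + 4]], weights[["children"]][[L + 4]], m)
    spec_forward(spec$children[[L + 5]], weights[["children"]][[L + 5]], q * m)
  } else stop("no forward rule for kind: ", k)
}

#' Instantiate a runnable model from a variant specification
#'
#' @param variant a `variant_spec` from [assemble_variant()]
#' @param seed RNG seed for the weight draw
#' @return an object of class `germ_model`
#' @export
instantiate_model <- function(variant, seed = 1L) {
  stopifnot(inherits(variant, "variant_spec"))
  set.seed(seed)
  weights <- list()
  for (nd in variant$graph)
    if (!is.null(nd$spec)) weights[[nd$id]] <- init_weights(nd$spec)
  # distributional box decoding kernel: fixed expectation weights 0..reg_max-1
  weights[["dfl"]] <- list(w = array(seq_len(variant$reg_max) - 1,
                                     dim = c(1, 1, variant$reg_max, 1)))
  structure(list(variant = variant, weights = weights), class = "germ_model")
}

#' Forward pass of an assembled variant
#'
#' @param model a `germ_model`
#' @param x numeric array (H, W, 3) with H, W divisible by 32
#' @param nodes optional node ids to return (default: the three detection
#'   scale outputs)
#' @return named list of output arrays
#' @export
model_forward <- function(model, x, nodes = NULL) {
  stopifnot(inherits(model, "germ_model"))
  v <- model$variant
  if (is.null(nodes)) nodes <- v$outputs
  env <- list("in" = x)
  need <- nodes
  for (nd in v$graph) {
    ins <- lapply(nd$from, function(f) env[[f]])
    xx <- if (length(ins) == 1) ins[[1]] else concat_ch(ins)
    env[[nd$id]] <- if (is.null(nd$spec)) xx
                    else spec_forward(nd$spec, model$weights[[nd$id]], xx)
  }
  stats::setNames(lapply(need, function(n) env[[n]]), need)
}

# --------------------------------------------------------------------------
# Weight enumeration and checkpoint serialization.
# --------------------------------------------------------------------------

flatten_tensors <- function(w, prefix = "") {
  out <- list()
  if (!is.null(w[["w"]])) out[[paste0(prefix, ".w")]] <- w[["w"]]
  if (!is.null(w[["b"]])) out[[paste0(prefix, ".b")]] <- w[["b"]]
  if (!is.null(w[["s"]])) out[[paste0(prefix, ".s")]] <- w[["s"]]
  if (!is.null(w[["bn"]])) {
    for (f in c("gamma", "beta", "mean", "var"))
      out[[paste0(prefix, ".bn.", f)]] <- w[["bn"]][[f]]
  }
  if (!is.null(w[["children"]]))
    for (i in seq_along(w[["children"]]))
      out <- c(out, flatten_tensors(w[["children"]][[i]],
                                    sprintf("%s.%d", prefix, i)))
  out
}

model_tensors <- function(model) {
  out <- list()
  for (id in names(model$weights))
    out <- c(out, flatten_tensors(model$weights[[id]], id))
  out
}

# spec-level tensor-slot census (names and lengths only), used for the
# serialized-size estimate before instantiation
flatten_weight_slots <- function(x) {
  count_spec <- function(spec) {
    k <- spec$kind
    if (k %in% c("conv", "dwconv", "pwconv", "linear")) {
      n <- 1L + as.integer(isTRUE(spec$bias)) + if (isTRUE(spec$bn)) 4L else 0L
      n
    } else if (k == "scale") 1L
    else if (k == "orepa" && isTRUE(spec$deployed)) 2L
    else if (length(spec$children) > 0)
      sum(vapply(spec$children, count_spec, 1L))
    else 0L
  }
  if (inherits(x, "variant_spec")) {
    n <- sum(vapply(x$graph, function(nd)
      if (is.null(nd$spec)) 0L else count_spec(nd$spec), 1L)) + 1L  # + DFL
    vector("list", n)
  } else vector("list", count_spec(x))
}

#' Enumerate a model's trainable parameters
#'
#' Counts every weight element actually held by the instantiated model
#' (convolution kernels, biases, batch-norm gamma/beta, channel scalings and
#' the fixed box-distribution kernel); running statistics are excluded.
#'
#' @param model a `germ_model`
#' @return numeric count
#' @export
model_params <- function(model) {
  tens <- model_tensors(model)
  keep <- !grepl("\\.bn\\.(mean|var)$", names(tens))
  sum(vapply(tens[keep], length, 1))
}

#' Serialize model weights
#'
#' Writes a flat binary checkpoint (magic, tensor count, then per tensor:
#' name, dtype, dims, payload).  Half precision stores 2 bytes per value.
#'
#' @param model a `germ_model`
#' @param path output file
#' @param precision "fp16" or "fp32"
#' @return invisibly, the file size in bytes
#' @export
save_checkpoint <- function(model, path, precision = c("fp16", "fp32")) {
  precision <- match.arg(precision)
  tens <- model_tensors(model)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("GERMCKPT"), con)
  writeBin(as.integer(c(1L, length(tens), if (precision == "fp16") 16L else 32L)),
           con, size = 4)
  for (nm in names(tens)) {
    x <- tens[[nm]]
    d <- dim(x) %||% length(x)
    raw_nm <- charToRaw(nm)
    writeBin(length(raw_nm), con, size = 4)
    writeBin(raw_nm, con)
    writeBin(as.integer(length(d)), con, size = 4)
    writeBin(as.integer(d), con, size = 4)
    if (precision == "fp16") writeBin(pack_fp16(as.numeric(x)), con)
    else writeBin(as.numeric(x), con, size = 4)
  }
  invisible(file.size(path))
}

#' Read back a checkpoint written by [save_checkpoint()]
#' @param path checkpoint file
#' @return named list of numeric arrays
#' @export
load_checkpoint <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8))
  if (magic != "GERMCKPT") stop("not a checkpoint file")
  hdr <- readBin(con, "integer", 3, size = 4)
  n <- hdr[2]; bits <- hdr[3]
  out <- list()
  for (i in seq_len(n)) {
    nl <- readBin(con, "integer", 1, size = 4)
    nm <- rawToChar(readBin(con, "raw", nl))
    nd <- readBin(con, "integer", 1, size = 4)
    d <- readBin(con, "integer", nd, size = 4)
    len <- prod(d)
    x <- if (bits == 16L) unpack_fp16(readBin(con, "raw", 2 * len))
         else readBin(con, "numeric", len, size = 4)
    if (nd > 1) dim(x) <- d
    out[[nm]] <- x
  }
  out
}
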