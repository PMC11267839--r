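# ---------------------------------------------------------------------------
# Composable network blocks: DepthSepConv, the PP-LCNet backbone schedule,
# the CCFM cross-scale fusion neck, FocalModulation and the LADH head.
# Builders return either a single layer_spec (blocks) or a list of graph
# nodes plus named taps (backbone / neck), consumed by assemble_variant().
# ---------------------------------------------------------------------------

gnode <- function(id, from, spec = NULL) list(id = id, from = from, spec = spec)

#' Depthwise-separable convolution block
#'
#' The PP-LCNet building block: a depthwise `kernel x kernel` convolution
#' (BN + h-swish), an optional squeeze-and-excitation gate (ReLU /
#' hard-sigmoid), and a pointwise 1x1 projection (BN + h-swish).  There is no
#' skip connection.
#'
#' @param in_channels,out_channels channel counts
#' @param kernel 3 or 5
#' @param stride 1 or 2
#' @param se add a squeeze-and-excitation gate after the depthwise stage
#' @param se_reduction SE bottleneck ratio (default 4, the PP-LCNet convention)
#' @return a composite `layer_spec`
#' @export
make_depthsepconv <- function(in_channels, out_channels, kernel = 3,
                              stride = 1, se = FALSE, se_reduction = 4) {
  if (!kernel %in% c(3, 5))
    stop("invalid DepthSepConv configuration: kernel must be 3 or 5")
  if (!stride %in% c(1, 2))
    stop("invalid DepthSepConv configuration: stride must be 1 or 2")
  dw <- spec_conv(in_channels, in_channels, kernel, stride,
                  groups = in_channels, act = "h-swish")
  pw <- spec_conv(in_channels, out_channels, 1, act = "h-swish")
  children <- if (se) list(dw, spec_se(in_channels, se_reduction), pw)
              else list(dw, pw)
  spec_seq(children, name = sprintf("DepthSepConv%dx%d", kernel, kernel))
}

# Published PP-LCNet schedule: (kernel, out_channels at 1.0x, stride, se).
# Stages are cut at strides 8/16/32 for the detection taps; the classifier
# head of the original network is dropped.
pplcnet_stage_table <- function() {
  list(
    stem = c(k = 3, c = 16, s = 2),
    blocks = list(
      c(3,  32, 1, 0),
      c(3,  64, 2, 0), c(3,  64, 1, 0),
      c(3, 128, 2, 0), c(3, 128, 1, 0),
      c(3, 256, 2, 0),
      c(5, 256, 1, 0), c(5, 256, 1, 0), c(5, 256, 1, 0), c(5, 256, 1, 0),
      c(5, 256, 1, 0),
      c(5, 512, 2, 1), c(5, 512, 1, 1)
    ))
}

scale_ch <- function(c, m, divisor = 4) {
  max(divisor, as.integer(round(c * m / divisor)) * divisor)
}

#' PP-LCNet backbone
#'
#' Builds the staged depthwise-separable backbone: a 3x3 stride-2 stem
#' followed by 3x3 and 5x5 DepthSepConv blocks, with squeeze-and-excitation in
#' the final (stride-32) stage, exposing feature taps at strides 8, 16 and 32.
#' `extra_blocks` appends stride-1 DepthSepConv repeats at the end of the
#' stride-4/8/16/32 stages; together with `width_multiplier` these are the
#' calibration knobs that set the backbone budget.
#'
#' @param width_multiplier channel width scaling applied to the published
#'   schedule (default 0.25)
#' @param extra_blocks integer vector of length 4: extra stride-1 blocks for
#'   the stride-4, 8, 16 and 32 stages
#' @param extra_se logical vector of length 4: use SE in those extra blocks
#' @return list with `nodes` (graph node list starting from "in") and `taps`
#'   (node ids at strides 8, 16, 32)
#' @export
make_pplcnet_backbone <- function(width_multiplier = 0.25,
                                  extra_blocks = c(0L, 0L, 0L, 0L),
                                  extra_se = c(FALSE, FALSE, FALSE, TRUE)) {
  if (width_multiplier <= 0) stop("width_multiplier must be positive")
  tab <- pplcnet_stage_table()
  m <- width_multiplier
  nodes <- list()
  stem_c <- scale_ch(tab$stem[["c"]], m)
  nodes[[1]] <- gnode("stem", "in",
                      spec_conv(3, stem_c, 3, 2, act = "h-swish"))
  prev_id <- "stem"
  prev_c <- stem_c
  stride <- 2L
  taps <- character(0)
  i <- 0L
  add_block <- function(k, cout, s, se) {
    i <<- i + 1L
    id <- sprintf("bb%02d", i)
    nodes[[length(nodes) + 1L]] <<- gnode(id, prev_id,
      make_depthsepconv(prev_c, cout, k, s, se = se))
    prev_id <<- id
    prev_c <<- cout
  }
  stage_of_stride <- c(`4` = 1L, `8` = 2L, `16` = 3L, `32` = 4L)
  blocks <- tab$blocks
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    cout <- scale_ch(b[2], m)
    if (b[3] == 2) {
      # close the previous stage with its calibrated extra repeats
      st <- unname(stage_of_stride[as.character(stride)])
      if (!is.na(st) && extra_blocks[st] > 0) {
        kk <- if (stride >= 16) 5 else 3
        for (j in seq_len(extra_blocks[st]))
          add_block(kk, prev_c, 1, se = extra_se[st])
      }
      if (stride %in% c(8L, 16L)) taps <- c(taps, prev_id)
      stride <- stride * 2L
    }
    add_block(b[1], cout, b[3], se = b[4] == 1)
  }
  st <- unname(stage_of_stride[as.character(stride)])
  if (extra_blocks[st] > 0)
    for (j in seq_len(extra_blocks[st]))
      add_block(5, prev_c, 1, se = extra_se[st])
  taps <- c(taps, prev_id)
  names(taps) <- c("p3", "p4", "p5")
  list(nodes = nodes, taps = taps,
       tap_channels = vapply(taps, function(id) {
         nd <- Filter(function(n) n$id == id, nodes)[[1]]
         nd$spec$out_channels
       }, 1L))
}

#' FocalModulation block specification
#'
#' Shape- and channel-preserving attention-style block used as the SPPF
#' replacement: a query projection, a hierarchical context branch (stacked
#' depthwise convolutions of growing receptive field plus a global-average
#' level), gated aggregation of the context levels into a modulator, and an
#' output projection of query x modulator.
#'
#' @param channels input/output channels
#' @param dim internal modulation width
#' @param levels number of depthwise context levels
#' @param kernels depthwise kernel size per level
#' @return a `layer_spec` of kind "focalmod"
#' @export
spec_focal <- function(channels, dim, levels = 3L, kernels = c(3L, 5L, 7L)) {
  stopifnot(length(kernels) == levels)
  q <- spec_conv(channels, dim, 1, bias = TRUE, bn = FALSE, act = "none")
  ctx <- spec_conv(channels, dim, 1, bias = TRUE, bn = FALSE, act = "none")
  gates <- spec_conv(channels, levels + 1L, 1, bias = TRUE, bn = FALSE,
                     act = "none")
  dws <- lapply(kernels, function(k)
    spec_conv(dim, dim, k, groups = dim, bias = TRUE, bn = FALSE, act = "gelu"))
  hproj <- spec_conv(dim, dim, 1, bias = TRUE, bn = FALSE, act = "none")
  oproj <- spec_conv(dim, channels, 1, bias = TRUE, bn = FALSE, act = "none")
  new_layer_spec("focalmod", in_channels = as.integer(channels),
                 out_channels = as.integer(channels), dim = as.integer(dim),
                 levels = as.integer(levels), kernels = as.integer(kernels),
                 children = c(list(q, ctx, gates), dws, list(hproj, oproj)))
}

#' CCFM cross-scale feature-fusion neck
#'
#' Lateral 1x1 projections bring the three backbone taps to a uniform width,
#' a top-down path (nearest upsampling + fusion) and a bottom-up path
#' (stride-2 DepthSepConv + fusion) exchange information across scales.  The
#' fusion blocks are C2f in the plain variant and stacked re-parameterized
#' OREPA 3x3 convolutions in the OREPA variants; their per-site widths are
#' calibration knobs.
#'
#' @param channel_list input channels of the three taps (P3, P4, P5)
#' @param width uniform neck width
#' @param fusion "c2f" or "orepa"
#' @param fusion_cfg list of 4 per-site configurations (sites: top-down at
#'   stride 16, top-down at stride 8, bottom-up at stride 16, bottom-up at
#'   stride 32).  For "c2f": `list(n=, e=)`; for "orepa": `list(hidden=)`,
#'   a vector of intermediate widths for the stacked 3x3 convolutions.
#' @param taps character vector of the three source node ids
#' @return list with `nodes` and `outputs` (ids of the three fused maps)
#' @export
make_ccfm_neck <- function(channel_list, width, fusion = c("c2f", "orepa"),
                           fusion_cfg = NULL, taps = c("p3", "p4", "p5")) {
  if (length(channel_list) != 3)
    stop("channel_list must have exactly three entries (P3, P4, P5)")
  fusion <- match.arg(fusion)
  if (is.null(fusion_cfg))
    fusion_cfg <- rep(list(list(n = 1L, e = 0.5, hidden = integer(0))), 4)
  w <- as.integer(width)
  fuse <- function(cin, site) {
    cfg <- fusion_cfg[[site]]
    if (fusion == "c2f") {
      spec_c2f(cin, w, n = cfg$n %||% 1L, shortcut = FALSE, e = cfg$e %||% 0.5)
    } else {
      widths <- c(cin, cfg$hidden, w)
      convs <- lapply(seq_len(length(widths) - 1L), function(i)
        spec_orepa(widths[i], widths[i + 1L], deployed = TRUE))
      if (length(convs) == 1) convs[[1]] else spec_seq(convs)
    }
  }
  nodes <- list(
    gnode("lat3", taps[1], spec_conv(channel_list[1], w, 1, act = "silu")),
    gnode("lat4", taps[2], spec_conv(channel_list[2], w, 1, act = "silu")),
    gnode("lat5", taps[3], spec_conv(channel_list[3], w, 1, act = "silu")),
    gnode("up5", "lat5", spec_upsample(w)),
    gnode("td4", c("up5", "lat4"), fuse(2L * w, 1)),
    gnode("up4", "td4", spec_upsample(w)),
    gnode("td3", c("up4", "lat3"), fuse(2L * w, 2)),
    gnode("dn3", "td3", make_depthsepconv(w, w, 3, 2)),
    gnode("bu4", c("dn3", "td4"), fuse(2L * w, 3)),
    gnode("dn4", "bu4", make_depthsepconv(w, w, 3, 2)),
    gnode("bu5", c("dn4", "lat5"), fuse(2L * w, 4))
  )
  list(nodes = nodes, outputs = c("td3", "bu4", "bu5"),
       out_channels = c(w, w, w))
}

#' Lightweight asymmetric dual head (LADH)
#'
#' Per detection scale, an asymmetric pair of branches built from depthwise
#' 3x3 convolutions and pointwise projections: a shallow classification
#' branch (one depthwise stage) and a deeper regression branch (two depthwise
#' stages) that keeps the distributional box encoding with `reg_max` bins.
#' The two 1x1 output projections are concatenated into a joint
#' `(num_classes + 4 * reg_max)`-channel map.
#'
#' @param num_classes number of object classes (>= 1)
#' @param channel_list input channels of the three scales
#' @param cls_width,reg_width hidden widths of the two branches; either a
#'   single value or one per scale (the per-scale compression ratios of the
#'   asymmetric head)
#' @param reg_max distribution bins per box side
#' @return list of three `layer_spec`s (one per scale)
#' @export
make_ladh_head <- function(num_classes, channel_list, cls_width = 64L,
                           reg_width = 240L, reg_max = 16L) {
  if (num_classes < 1) stop("num_classes must be >= 1")
  if (length(channel_list) != 3) stop("three input scales are required")
  cls_w <- rep_len(as.integer(cls_width), 3)
  reg_w <- rep_len(as.integer(reg_width), 3)
  lapply(seq_along(channel_list), function(si) {
    c_in <- channel_list[si]
    cls_width <- cls_w[si]
    reg_width <- reg_w[si]
    cls <- spec_seq(
      spec_dwconv(c_in, 3, act = "h-swish"),
      spec_pwconv(c_in, cls_width, act = "h-swish"),
      spec_conv(cls_width, num_classes, 1, bias = TRUE, bn = FALSE,
                act = "none"),
      name = "ladh_cls")
    reg <- spec_seq(
      spec_dwconv(c_in, 3, act = "h-swish"),
      spec_pwconv(c_in, reg_width, act = "h-swish"),
      spec_dwconv(reg_width, 3, act = "h-swish"),
      spec_pwconv(reg_width, reg_width, act = "h-swish"),
      spec_conv(reg_width, 4L * reg_max, 1, bias = TRUE, bn = FALSE,
                act = "none"),
      name = "ladh_reg")
    spec_par(list(cls, reg), name = "ladh")
  })
}

# YOLOv8 Detect head branches for one scale (classification + regression,
# concatenated): the stock symmetric head used by the baseline and the
# intermediate variants.
make_detect_head <- function(num_classes, channel_list, reg_max = 16L) {
  c2 <- max(16L, channel_list[1] %/% 4L, 4L * reg_max)
  c3 <- max(channel_list[1], min(num_classes, 100L))
  lapply(channel_list, function(c_in) {
    reg <- spec_seq(
      spec_conv(c_in, c2, 3, act = "silu"),
      spec_conv(c2, c2, 3, act = "silu"),
      spec_conv(c2, 4L * reg_max, 1, bias = TRUE, bn = FALSE, act = "none"),
      name = "detect_reg")
    cls <- spec_seq(
      spec_conv(c_in, c3, 3, act = "silu"),
      spec_conv(c3, c3, 3, act = "silu"),
      spec_conv(c3, num_classes, 1, bias = TRUE, bn = FALSE, act = "none"),
      name = "detect_cls")
    spec_par(list(cls, reg), name = "detect")
  })
}
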