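# ---------------------------------------------------------------------------
# Assembly of the six ablation variants.  The ladder applies cumulative
# substitutions to the YOLOv8n baseline: backbone -> PP-LCNet (P-), neck ->
# CCFM (PC-), neck fusion -> re-parameterized OREPA (PCO-), SPPF ->
# FocalModulation (PCOF-), detection head -> LADH (YOLOv8-R).
# ---------------------------------------------------------------------------

VARIANT_NAMES <- c("YOLOv8n", "P-YOLOv8", "PC-YOLOv8", "PCO-YOLOv8",
                   "PCOF-YOLOv8", "YOLOv8-R")

#' Names of the assembleable variants
#' @return character vector
#' @export
variant_names <- function() VARIANT_NAMES

#' Calibrated architecture configuration
#'
#' The published ablation table fixes each variant's parameter/FLOP budget but
#' not the internal channel schedule; these constants were calibrated once so
#' that every assembled variant reproduces its printed budget at the table's
#' rounding (PP-LCNet width multiplier and stage repeats, uniform CCFM neck
#' width, per-site fusion widths, FocalModulation inner width, LADH branch
#' widths).
#'
#' @return named list of knobs consumed by [assemble_variant()]
#' @export
variant_config <- function() {
  list(
    backbone_width = 0.25,
    backbone_extra = c(3L, 1L, 4L, 1L),
    backbone_extra_se = c(FALSE, FALSE, FALSE, TRUE),
    neck_width = 48L,
    pc_fusion = list(list(n = 1L, e = 42 / 48), list(n = 2L, e = 36 / 48),
                     list(n = 3L, e = 42 / 48), list(n = 1L, e = 12 / 48)),
    pco_fusion = list(list(hidden = 4L), list(hidden = integer(0)),
                      list(hidden = 16L), list(hidden = 272L)),
    focal_dim = 54L,
    focal_levels = 3L,
    focal_kernels = c(3L, 5L, 7L),
    ladh_cls_width = c(64L, 64L, 64L),
    ladh_reg_width = c(268L, 192L, 212L)
  )
}

# Baseline YOLOv8n at depth 0.33 / width 0.25: backbone channels
# (16, 32, 64, 128, 256), C2f repeats (1, 2, 2, 1), SPPF, PAN neck, decoupled
# anchor-free head with 16-bin distributional box regression.
yolov8n_graph <- function(num_classes) {
  nc <- as.integer(num_classes)
  g <- list(
    gnode("b0", "in", spec_conv(3, 16, 3, 2)),
    gnode("b1", "b0", spec_conv(16, 32, 3, 2)),
    gnode("b2", "b1", spec_c2f(32, 32, 1, TRUE)),
    gnode("b3", "b2", spec_conv(32, 64, 3, 2)),
    gnode("b4", "b3", spec_c2f(64, 64, 2, TRUE)),
    gnode("b5", "b4", spec_conv(64, 128, 3, 2)),
    gnode("b6", "b5", spec_c2f(128, 128, 2, TRUE)),
    gnode("b7", "b6", spec_conv(128, 256, 3, 2)),
    gnode("b8", "b7", spec_c2f(256, 256, 1, TRUE)),
    gnode("p5", "b8", spec_sppf(256, 256)),
    gnode("u1", "p5", spec_upsample(256)),
    gnode("n1", c("u1", "b6"), spec_c2f(384, 128, 1, FALSE)),
    gnode("u2", "n1", spec_upsample(128)),
    gnode("n2", c("u2", "b4"), spec_c2f(192, 64, 1, FALSE)),
    gnode("d1", "n2", spec_conv(64, 64, 3, 2)),
    gnode("n3", c("d1", "n1"), spec_c2f(192, 128, 1, FALSE)),
    gnode("d2", "n3", spec_conv(128, 128, 3, 2)),
    gnode("n4", c("d2", "p5"), spec_c2f(384, 256, 1, FALSE))
  )
  head <- make_detect_head(nc, c(64L, 128L, 256L))
  c(g, list(gnode("det8", "n2", head[[1]]),
            gnode("det16", "n3", head[[2]]),
            gnode("det32", "n4", head[[3]])))
}

# YOLOv8 PAN neck over PP-LCNet taps, with the downsampling convolutions
# replaced by DepthSepConv; output widths stay at the baseline (64, 128, 256).
pan_neck_dsc <- function(tap_channels, taps) {
  t3 <- tap_channels[1]; t4 <- tap_channels[2]; t5 <- tap_channels[3]
  list(
    gnode("u1", "sppf", spec_upsample(t5)),
    gnode("n1", c("u1", taps[2]), spec_c2f(t5 + t4, 128, 1, FALSE)),
    gnode("u2", "n1", spec_upsample(128)),
    gnode("n2", c("u2", taps[1]), spec_c2f(128 + t3, 64, 1, FALSE)),
    gnode("d1", "n2", make_depthsepconv(64, 64, 3, 2)),
    gnode("n3", c("d1", "n1"), spec_c2f(192, 128, 1, FALSE)),
    gnode("d2", "n3", make_depthsepconv(128, 128, 3, 2)),
    gnode("n4", c("d2", "sppf"), spec_c2f(128 + t5, 256, 1, FALSE))
  )
}

#' Assemble an ablation variant
#'
#' Builds the declarative graph (a tree of `layer_spec`s wired between named
#' nodes) for one of the six variants.  The result can be measured with
#' [complexity_report()] or instantiated with [instantiate_model()] for a
#' runnable forward pass producing detection maps at strides 8/16/32.
#'
#' @param name one of `variant_names()`
#' @param num_classes number of detection classes (default 2:
#'   sprout / not-sprout)
#' @param input_size nominal square input side (pixels)
#' @param config calibration constants, see [variant_config()]
#' @return an object of class `variant_spec`
#' @export
assemble_variant <- function(name, num_classes = 2L, input_size = 640L,
                             config = variant_config()) {
  if (!name %in% VARIANT_NAMES)
    stop("unknown variant '", name, "'; valid names: ",
         paste(VARIANT_NAMES, collapse = ", "))
  nc <- as.integer(num_classes)
  if (name == "YOLOv8n") {
    graph <- yolov8n_graph(nc)
    head_ch <- c(64L, 128L, 256L)
  } else {
    bb <- make_pplcnet_backbone(config$backbone_width, config$backbone_extra,
                                config$backbone_extra_se)
    tch <- as.integer(bb$tap_channels)
    t5 <- tch[3]
    spp <- if (name %in% c("PCOF-YOLOv8", "YOLOv8-R"))
      spec_focal(t5, config$focal_dim, config$focal_levels,
                 config$focal_kernels)
    else spec_sppf(t5, t5)
    graph <- c(bb$nodes, list(gnode("sppf", bb$taps[["p5"]], spp)))
    if (name == "P-YOLOv8") {
      graph <- c(graph, pan_neck_dsc(tch, unname(bb$taps)))
      head_ch <- c(64L, 128L, 256L)
      feat <- c("n2", "n3", "n4")
    } else {
      fusion <- if (name == "PC-YOLOv8") "c2f" else "orepa"
      fcfg <- if (fusion == "c2f") config$pc_fusion else config$pco_fusion
      neck <- make_ccfm_neck(tch, config$neck_width, fusion, fcfg,
                             taps = c(bb$taps[["p3"]], bb$taps[["p4"]], "sppf"))
      graph <- c(graph, neck$nodes)
      head_ch <- neck$out_channels
      feat <- neck$outputs
    }
    head <- if (name == "YOLOv8-R")
      make_ladh_head(nc, head_ch, config$ladh_cls_width, config$ladh_reg_width)
    else make_detect_head(nc, head_ch)
    graph <- c(graph, list(gnode("det8", feat[1], head[[1]]),
                           gnode("det16", feat[2], head[[2]]),
                           gnode("det32", feat[3], head[[3]])))
  }
  structure(list(name = name, num_classes = nc,
                 input_size = as.integer(input_size), graph = graph,
                 outputs = c("det8", "det16", "det32"),
                 strides = c(8L, 16L, 32L), reg_max = 16L,
                 head_channels = head_ch),
            class = "variant_spec")
}

#' Total declarative parameter count of a variant
#'
#' Sum over the graph's layer specifications plus the fixed box-distribution
#' kernel, i.e. the count that weight enumeration of an instantiated model
#' must reproduce exactly.
#' @param variant a `variant_spec`
#' @return numeric count
#' @export
variant_params <- function(variant) {
  stopifnot(inherits(variant, "variant_spec"))
  graph_params(variant$graph) + variant$reg_max
}

#' Per-scale output shapes of a variant
#' @param variant a `variant_spec`
#' @param input_size input side length (pixels, divisible by 32)
#' @return named list of `c(channels, height, width)` per detection scale
#' @export
variant_out_shapes <- function(variant, input_size = variant$input_size) {
  if (input_size %% 32 != 0) stop("input_size must be divisible by 32")
  env <- graph_walk_shapes(variant$graph, c(3, input_size, input_size))
  stats::setNames(lapply(variant$outputs, function(o) env[[o]]),
                  variant$outputs)
}

#' @export
print.variant_spec <- function(x, ...) {
  cat(sprintf("<variant_spec> %s  (classes: %d, input %dx%d)\n", x$name,
              x$num_classes, x$input_size, x$input_size))
  rep <- complexity_report(x, x$input_size)
  cat(sprintf("  %.2f M params, %.1f GFLOPs\n", rep$params_millions,
              rep$gflops))
  invisible(x)
}

strip_spec <- function(x) {
  if (is_layer_spec(x)) x <- unclass(x)
  if (is.list(x)) lapply(x, strip_spec) else x
}

#' Write a variant definition as a YAML config
#'
#' Serializes the declarative LayerSpec tree (graph nodes, wiring and layer
#' fields) so a variant can be versioned and inspected outside R.
#' @param variant a `variant_spec`
#' @param path output file
#' @export
write_variant_yaml <- function(variant, path) {
  obj <- list(name = variant$name, num_classes = variant$num_classes,
              input_size = variant$input_size,
              strides = variant$strides, reg_max = variant$reg_max,
              graph = lapply(variant$graph, function(nd)
                list(id = nd$id, from = as.list(nd$from),
                     spec = strip_spec(nd$spec))))
  yaml::write_yaml(obj, path)
  invisible(path)
}
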