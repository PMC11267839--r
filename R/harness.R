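# ---------------------------------------------------------------------------
# Desk-scale harness: run configuration, head-only smoke training on
# synthetic frames, single-image detection, treatment-grid simulation and the
# end-to-end pipeline (generate -> split -> detect/oracle -> evaluate ->
# vitality).
# ---------------------------------------------------------------------------

#' Training run configuration
#'
#' Default hyperparameters of the training recipe: 100 epochs, batch 16,
#' 640 x 640 inputs, Adam with learning rate 1e-4, weight decay 1e-4,
#' momentum 0.937, 8 workers.  The smoke harness overrides epochs/batch/size
#' for desk-scale runs and logs every override.
#'
#' @param ... overrides of the defaults
#' @return a `run_config` list with an `overrides` attribute
#' @export
run_config <- function(...) {
  defaults <- list(epochs = 100L, batch = 16L, imgsz = 640L,
                   optimizer = "Adam", lr = 1e-4, weight_decay = 1e-4,
                   momentum = 0.937, workers = 8L)
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown run_config field(s): ",
                        paste(bad, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  attr(cfg, "overrides") <- names(over)
  class(cfg) <- "run_config"
  cfg
}

# hidden activations of a head branch (all layers but the final 1x1), plus
# that final conv's spec/weights; works for both the symmetric and the
# asymmetric (LADH) head
branch_hidden <- function(branch_spec, branch_w, feat) {
  k <- length(branch_spec$children)
  h <- feat
  for (i in seq_len(k - 1))
    h <- spec_forward(branch_spec$children[[i]], branch_w$children[[i]], h)
  h
}

rasterise_targets <- function(boxes, image_size, stride, num_classes,
                              reg_max, labels = CLASS_LABELS) {
  S <- image_size %/% stride
  y_cls <- array(0, dim = c(S, S, num_classes))
  pos <- NULL
  if (nrow(boxes)) for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    cx <- (b$x1 + b$x2) / 2 / stride
    cy <- (b$y1 + b$y2) / 2 / stride
    col <- min(S, max(1L, ceiling(cx)))
    row <- min(S, max(1L, ceiling(cy)))
    cl <- match(b$label, labels)
    y_cls[row, col, cl] <- 1
    # ltrb distances from the cell centre, in stride units, binned
    ccx <- (col - 0.5); ccy <- (row - 0.5)
    ltrb <- c(ccx - b$x1 / stride, ccy - b$y1 / stride,
              b$x2 / stride - ccx, b$y2 / stride - ccy)
    bins <- pmin(pmax(floor(ltrb), 0), reg_max - 1) + 1L
    pos <- rbind(pos, c(row, col, bins))
  }
  list(cls = y_cls, pos = pos)
}

#' Smoke-train a variant head on synthetic frames
#'
#' Desk-scale training: the randomly initialised backbone and neck are kept
#' frozen as a feature extractor, and the final 1x1 output projections of the
#' classification and box-distribution branches are fitted by gradient
#' descent (the objective is convex in those weights).  Loss is
#' binary cross-entropy on the per-cell class map plus cross-entropy of the
#' binned box distances at positive cells.  This verifies the training
#' plumbing and that the detection target encoding is learnable; it is not a
#' full-accuracy training run.
#'
#' @param variant_name variant to train (default "YOLOv8-R")
#' @param n_images number of synthetic frames
#' @param epochs gradient epochs
#' @param image_size frame side (divisible by 32); 160 keeps a CPU run fast
#' @param lr learning rate for the head fit (overrides the full-scale recipe;
#'   logged)
#' @param seed RNG seed (scene, schedule and weight initialisation)
#' @param config architecture configuration
#' @return a `smoke_fit`: the model (with fitted head), `loss_trace`
#'   (per-epoch), the run configuration and the training frames' records
#' @export
train_smoke <- function(variant_name = "YOLOv8-R", n_images = 50L,
                        epochs = 5L, image_size = 160L, lr = 0.2,
                        seed = 1L, config = variant_config()) {
  rc <- run_config(epochs = as.integer(epochs), batch = as.integer(n_images),
                   imgsz = as.integer(image_size), lr = lr)
  variant <- assemble_variant(variant_name, 2L, image_size, config)
  model <- instantiate_model(variant, seed = seed)
  nc <- variant$num_classes; rm_ <- variant$reg_max
  # synthetic training frames: one cell sequence sampled across time
  sc <- scene_config(cells = 4L, seeds_per_cell = 8L, image_size = image_size,
                     seed = seed)
  sched <- sample_schedule(sc, "CK", seed = seed)
  times <- seq(12, 44, length.out = ceiling(n_images / sc$cells))
  frames <- list()
  for (cell in seq_len(sc$cells)) for (t in times) {
    if (length(frames) >= n_images) break
    frames[[length(frames) + 1]] <- render_frame(sc, sched, cell, round(t / 0.25) * 0.25)
  }
  # head input node per scale
  feat_ids <- vapply(variant$outputs, function(o) {
    nd <- Filter(function(n) n$id == o, variant$graph)[[1]]
    nd$from[1]
  }, "")
  # cache hidden activations and targets once
  cache <- lapply(frames, function(fr) {
    feats <- model_forward(model, fr$image, nodes = unname(feat_ids))
    lapply(seq_along(feats), function(si) {
      hs <- variant$graph[[which(vapply(variant$graph, function(n)
        n$id == variant$outputs[si], TRUE))]]$spec
      ws <- model$weights[[variant$outputs[si]]]
      list(h_cls = branch_hidden(hs$children[[1]], ws$children[[1]], feats[[si]]),
           h_reg = branch_hidden(hs$children[[2]], ws$children[[2]], feats[[si]]),
           tgt = rasterise_targets(fr$record$boxes, image_size,
                                   variant$strides[si], nc, rm_))
    })
  })
  get_final <- function(si, branch) {
    hs <- variant$graph[[which(vapply(variant$graph, function(n)
      n$id == variant$outputs[si], TRUE))]]$spec
    k <- length(hs$children[[branch]]$children)
    list(spec = hs$children[[branch]]$children[[k]], k = k)
  }
  loss_trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    total <- 0
    for (si in 1:3) {
      fc <- get_final(si, 1); fr_ <- get_final(si, 2)
      wc <- model$weights[[variant$outputs[si]]]$children[[1]]$children[[fc$k]]
      wr <- model$weights[[variant$outputs[si]]]$children[[2]]$children[[fr_$k]]
      gWc <- array(0, dim = dim(wc$w)); gbc <- numeric(length(wc$b))
      gWr <- array(0, dim = dim(wr$w)); gbr <- numeric(length(wr$b))
      for (ci in seq_along(cache)) {
        cc <- cache[[ci]][[si]]
        HW <- dim(cc$h_cls)[1] * dim(cc$h_cls)[2]
        Hc <- matrix(cc$h_cls, HW); Hr <- matrix(cc$h_reg, HW)
        z <- Hc %*% matrix(wc$w[1, 1, , ], ncol = nc) +
          matrix(wc$b, HW, nc, byrow = TRUE)
        p <- stats::plogis(z)
        y <- matrix(cc$tgt$cls, HW)
        eps <- 1e-9
        total <- total - sum(y * log(p + eps) + (1 - y) * log(1 - p + eps)) /
          (HW * nc * length(cache))
        dz <- (p - y) / (HW * nc * length(cache))
        gWc[1, 1, , ] <- gWc[1, 1, , ] + crossprod(Hc, dz)
        gbc <- gbc + colSums(dz)
        pos <- cc$tgt$pos
        if (!is.null(pos)) {
          npos <- nrow(pos) * 4 * length(cache)
          S <- dim(cc$h_cls)[1]
          for (pi in seq_len(nrow(pos))) {
            cell <- pos[pi, 1] + (pos[pi, 2] - 1) * S
            zr <- drop(Hr[cell, ] %*% matrix(wr$w[1, 1, , ], ncol = 4 * rm_)) + wr$b
            for (s4 in 1:4) {
              zz <- zr[(s4 - 1) * rm_ + seq_len(rm_)]
              sm <- exp(zz - max(zz)); sm <- sm / sum(sm)
              tb <- pos[pi, 2 + s4]
              total <- total - log(sm[tb] + 1e-9) / npos
              dzr <- sm; dzr[tb] <- dzr[tb] - 1
              idx <- (s4 - 1) * rm_ + seq_len(rm_)
              gWr[1, 1, , idx] <- gWr[1, 1, , idx] +
                outer(Hr[cell, ], dzr) / npos
              gbr[idx] <- gbr[idx] + dzr / npos
            }
          }
        }
      }
      wc$w <- wc$w - lr * gWc; wc$b <- wc$b - lr * gbc
      wr$w <- wr$w - lr * gWr; wr$b <- wr$b - lr * gbr
      model$weights[[variant$outputs[si]]]$children[[1]]$children[[fc$k]] <- wc
      model$weights[[variant$outputs[si]]]$children[[2]]$children[[fr_$k]] <- wr
    }
    if (!is.finite(total)) stop("non-finite training loss at epoch ", ep)
    loss_trace[ep] <- total
  }
  structure(list(model = model, loss_trace = loss_trace, run_config = rc,
                 frames = lapply(frames, `[[`, "record")),
            class = "smoke_fit")
}

#' @export
print.smoke_fit <- function(x, ...) {
  cat(sprintf("smoke fit (%s): loss %s\n", x$model$variant$name,
              paste(sprintf("%.4f", x$loss_trace), collapse = " -> ")))
  invisible(x)
}

#' Detect seeds in one frame
#'
#' Runs the model forward, decodes the per-scale maps and applies soft (or
#' hard) non-maximum suppression.
#'
#' @param model a `germ_model`
#' @param image numeric array (H, W, 3)
#' @param conf_threshold pre-NMS confidence threshold
#' @param use_soft_nms apply Gaussian soft-NMS (default) or hard NMS
#' @param sigma,score_threshold soft-NMS settings
#' @return a detection table
#' @export
detect_seeds <- function(model, image, conf_threshold = 0.25,
                         use_soft_nms = TRUE, sigma = 0.5,
                         score_threshold = 0.01) {
  outs <- model_forward(model, image)
  d <- decode_head_outputs(outs, conf_threshold,
                           strides = model$variant$strides,
                           num_classes = model$variant$num_classes,
                           reg_max = model$variant$reg_max)
  if (use_soft_nms) soft_nms(d, sigma, score_threshold) else nms_hard(d)
}

#' Simulate the full treatment-grid germination experiment
#'
#' Draws per-seed germination schedules for every treatment of the 5 x 5
#' NaCl x ZnO grid under the experimental design (4 cells per treatment per
#' repetition, 3 repetitions) and converts them to cumulative count
#' observations at the capture interval.
#'
#' @param config a `scene_config` (cells field ignored; cells are set by
#'   `cells_per_rep`)
#' @param treatments treatment codes (default: all 25)
#' @param replicates repetitions per treatment
#' @param cells_per_rep cells sown per treatment and repetition
#' @param seed base RNG seed
#' @return observation data.frame for [vitality_series()]
#' @export
simulate_observations <- function(config = scene_config(),
                                  treatments = treatment_grid()$treatment,
                                  replicates = 3L, cells_per_rep = 4L,
                                  seed = 1L) {
  if (!length(treatments)) stop("empty treatment grid")
  times <- capture_times(config)
  out <- list()
  cfg1 <- config; cfg1$cells <- as.integer(cells_per_rep)
  for (tr in treatments) for (rep_ in seq_len(replicates)) {
    sch <- sample_schedule(cfg1, tr,
                           seed = seed + 7919L * match(tr, treatments) + rep_)
    for (cell in seq_len(cells_per_rep)) {
      idx <- (cell - 1L) * cfg1$seeds_per_cell + seq_len(cfg1$seeds_per_cell)
      tt <- sch$times[idx]
      out[[length(out) + 1]] <- data.frame(
        treatment = tr, replicate = rep_, cell = cell, time_h = times,
        germinated = vapply(times, function(t) sum(tt <= t), 1L),
        total = cfg1$seeds_per_cell, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' End-to-end pipeline on synthetic data
#'
#' Generates a synthetic run, splits it by dish, produces detections (oracle
#' mode feeds the ground truth back at confidence 1; model mode runs a
#' supplied or smoke-trained detector), evaluates mAP50 and recovers the
#' vitality indices from the detections.
#'
#' @param config a `scene_config`
#' @param treatment treatment code for the run
#' @param oracle use ground truth as detections (pipeline identity check)
#' @param model optional `germ_model` for model-based detection
#' @param out_dir directory for the generated run
#' @return a `pipeline_report` list: `split`, `evaluation`, `vitality`,
#'   `n_images`
#' @export
run_pipeline <- function(config = scene_config(cells = 4L, seeds_per_cell = 6L,
                                               image_size = 256L,
                                               interval_h = 2, duration_h = 48,
                                               seed = 1L),
                         treatment = "CK", oracle = TRUE, model = NULL,
                         out_dir = tempfile("germrun")) {
  man <- generate_run(config, out_dir, treatment = treatment, render = "none")
  xml_dir <- file.path(out_dir, "annotations")
  recs <- lapply(man$image_id, function(id)
    read_voc_xml(file.path(xml_dir, paste0(id, ".xml"))))
  split <- dish_stratified_split(
    recs, dish_map = list(train = seq_len(max(1, config$cells - 2)),
                          test = config$cells - 1, val = config$cells))
  gt_list <- lapply(recs, function(r) r$boxes)
  det_list <- if (oracle) {
    lapply(gt_list, function(g)
      detections(g$x1, g$y1, g$x2, g$y2, g$label, rep(1, nrow(g))))
  } else {
    if (is.null(model)) stop("model mode requires a germ_model")
    sched <- sample_schedule(config, treatment)
    lapply(seq_along(recs), function(i) {
      fr <- render_frame(config, sched, recs[[i]]$cell_id,
                         recs[[i]]$timestamp_h)
      detect_seeds(model, fr$image)
    })
  }
  ev <- evaluate_detections(det_list, gt_list)
  det_frames <- data.frame(
    treatment = treatment, replicate = 1L,
    cell = vapply(recs, function(r) r$cell_id, 1L),
    time_h = vapply(recs, function(r) r$timestamp_h, 1),
    n_sprout = vapply(det_list, function(d) sum(d$label == "sprout"), 1),
    n_total = vapply(det_list, nrow, 1), stringsAsFactors = FALSE)
  obs <- counts_from_detections(det_frames)
  vit <- vitality_series(obs, energy_cutoff_hours = min(32, config$duration_h))
  structure(list(split = split, evaluation = ev, vitality = vit,
                 n_images = nrow(man), out_dir = out_dir),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline report: %d frames\n", x$n_images))
  print(table(x$split$split))
  print(x$evaluation)
  print(x$vitality)
  invisible(x)
}
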