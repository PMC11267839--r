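# Shared helpers: small random scenes, box builders, and an exhaustive
# matching oracle independent of the greedy implementation.

rand_boxes <- function(n, size = 100, seed = NULL, labels = c("sprout",
                                                              "not_sprout")) {
  if (!is.null(seed)) set.seed(seed)
  x1 <- runif(n, 0, size * 0.7)
  y1 <- runif(n, 0, size * 0.7)
  data.frame(x1 = x1, y1 = y1,
             x2 = x1 + runif(n, size * 0.1, size * 0.3),
             y2 = y1 + runif(n, size * 0.1, size * 0.3),
             label = sample(labels, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

as_dets <- function(boxes, confidence = NULL) {
  if (is.null(confidence)) confidence <- rep(1, nrow(boxes))
  detections(boxes$x1, boxes$y1, boxes$x2, boxes$y2, boxes$label, confidence)
}

# Exhaustive one-to-one assignment: maximise the number of same-class pairs
# with IoU >= threshold (ties broken by total IoU).  Returns the maximal TP
# count.  Only usable for tiny scenes.
brute_force_tp <- function(dets, gts, iou_threshold = 0.5) {
  nd <- nrow(dets); ng <- nrow(gts)
  if (nd == 0 || ng == 0) return(0)
  iou_m <- matrix(0, nd, ng)
  for (i in seq_len(nd)) for (j in seq_len(ng)) {
    if (dets$label[i] == gts$label[j])
      iou_m[i, j] <- box_iou(as.numeric(dets[i, c("x1", "y1", "x2", "y2")]),
                             as.numeric(gts[j, c("x1", "y1", "x2", "y2")]))
  }
  feas <- iou_m >= iou_threshold
  best <- 0
  assign_next <- function(i, used, count) {
    if (count + (nd - i + 1) <= best) return()
    if (i > nd) { best <<- max(best, count); return() }
    assign_next(i + 1, used, count)              # detection i unmatched
    for (j in which(feas[i, ] & !used)) {
      used2 <- used; used2[j] <- TRUE
      assign_next(i + 1, used2, count + 1)
    }
  }
  assign_next(1, rep(FALSE, ng), 0)
  best
}

tiny_scene <- function(seed = 1L, cells = 2L, image_size = 160L,
                       interval_h = 4, seeds = 5L) {
  scene_config(cells = cells, seeds_per_cell = seeds,
               image_size = image_size, interval_h = interval_h,
               duration_h = 48, seed = seed)
}
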