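# ---------------------------------------------------------------------------
# Detection post-processing: IoU, hard NMS, Gaussian soft-NMS and decoding of
# the anchor-free head outputs.  A detection table is a data.frame with
# columns x1, y1, x2, y2 (pixels, x2 > x1, y2 > y1), label ("sprout" /
# "not_sprout") and confidence in [0, 1].
# ---------------------------------------------------------------------------

CLASS_LABELS <- c("sprout", "not_sprout")

#' Construct a detection table
#' @param x1,y1,x2,y2 box corners (pixels)
#' @param label class labels
#' @param confidence scores in `[0, 1]`
#' @return data.frame of class `detections`
#' @export
detections <- function(x1, y1, x2, y2, label, confidence) {
  d <- data.frame(x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                  label = as.character(label), confidence = confidence,
                  stringsAsFactors = FALSE)
  if (nrow(d)) {
    if (any(d$x2 <= d$x1 | d$y2 <= d$y1)) stop("degenerate box (area <= 0)")
    if (any(d$confidence < 0 | d$confidence > 1))
      stop("confidence must lie in [0, 1]")
  }
  class(d) <- c("detections", "data.frame")
  d
}

#' Intersection over union of two boxes
#' @param a,b numeric vectors `c(x1, y1, x2, y2)`
#' @return IoU in `[0, 1]`
#' @export
box_iou <- function(a, b) {
  if (a[3] <= a[1] || a[4] <= a[2] || b[3] <= b[1] || b[4] <= b[2])
    stop("degenerate box (area <= 0)")
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

# IoU of one box against the rows of a matrix (vectorised)
iou_vec <- function(box, m) {
  if (nrow(m) == 0) return(numeric(0))
  iw <- pmin(box[3], m[, 3]) - pmax(box[1], m[, 1])
  ih <- pmin(box[4], m[, 4]) - pmax(box[2], m[, 2])
  inter <- pmax(iw, 0) * pmax(ih, 0)
  union <- (box[3] - box[1]) * (box[4] - box[2]) +
    (m[, 3] - m[, 1]) * (m[, 4] - m[, 2]) - inter
  inter / union
}

#' Hard non-maximum suppression
#'
#' Greedy per-class suppression: repeatedly keep the highest-confidence box
#' and drop every remaining same-class box with IoU above `iou_threshold`.
#'
#' @param dets a detection table
#' @param iou_threshold overlap threshold
#' @return the surviving subset, ordered by confidence
#' @export
nms_hard <- function(dets, iou_threshold = 0.45) {
  if (nrow(dets) == 0) return(dets)
  keep <- logical(0)
  out <- dets[0, ]
  for (cl in unique(dets$label)) {
    d <- dets[dets$label == cl, , drop = FALSE]
    d <- d[order(-d$confidence), , drop = FALSE]
    m <- as.matrix(d[, c("x1", "y1", "x2", "y2")])
    alive <- rep(TRUE, nrow(d))
    for (i in seq_len(nrow(d))) {
      if (!alive[i]) next
      rest <- which(alive & seq_len(nrow(d)) > i)
      if (length(rest)) {
        ious <- iou_vec(m[i, ], m[rest, , drop = FALSE])
        alive[rest[ious > iou_threshold]] <- FALSE
      }
    }
    out <- rbind(out, d[alive, , drop = FALSE])
  }
  out <- out[order(-out$confidence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gaussian soft non-maximum suppression
#'
#' Instead of deleting overlapping boxes, decays their confidence by
#' `exp(-IoU^2 / sigma)` relative to each selected box, then prunes boxes
#' whose decayed confidence falls below `score_threshold`.  Suppression is
#' per class.  Defaults follow the tuned post-processing settings
#' (`sigma = 0.5`, threshold `0.01`).
#'
#' @param dets a detection table
#' @param sigma Gaussian decay width (> 0)
#' @param score_threshold post-decay pruning threshold
#' @return surviving detections with decayed confidences, ordered by final
#'   confidence
#' @export
soft_nms <- function(dets, sigma = 0.5, score_threshold = 0.01) {
  if (sigma <= 0) stop("sigma must be positive")
  if (nrow(dets) == 0) return(dets)
  out <- dets[0, ]
  for (cl in unique(dets$label)) {
    d <- dets[dets$label == cl, , drop = FALSE]
    m <- as.matrix(d[, c("x1", "y1", "x2", "y2")])
    scores <- d$confidence
    alive <- rep(TRUE, nrow(d))
    kept <- integer(0)
    kept_scores <- numeric(0)
    while (any(alive)) {
      i <- which(alive)[which.max(scores[alive])]
      kept <- c(kept, i)
      kept_scores <- c(kept_scores, scores[i])
      alive[i] <- FALSE
      rest <- which(alive)
      if (length(rest)) {
        ious <- iou_vec(m[i, ], m[rest, , drop = FALSE])
        scores[rest] <- scores[rest] * exp(-ious^2 / sigma)
        drop <- rest[scores[rest] < score_threshold]
        alive[drop] <- FALSE
      }
    }
    dk <- d[kept, , drop = FALSE]
    dk$confidence <- kept_scores
    out <- rbind(out, dk)
  }
  out <- out[out$confidence >= score_threshold, , drop = FALSE]
  out <- out[order(-out$confidence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Decode raw head outputs into detections
#'
#' Converts the three per-scale output maps of an assembled variant (channels
#' = `num_classes + 4 * reg_max`) into pixel-space boxes: class scores by
#' sigmoid, box sides as the expectation of the softmax over `reg_max`
#' distance bins times the scale stride, measured from the cell centre
#' (left, top, right, bottom).
#'
#' @param outputs named list of three arrays (H, W, nc + 4 * reg_max), as
#'   returned by [model_forward()]
#' @param conf_threshold minimum class score retained (pre-NMS)
#' @param strides per-scale strides
#' @param num_classes number of classes
#' @param reg_max distribution bins
#' @param labels class label names
#' @return a detection table
#' @export
decode_head_outputs <- function(outputs, conf_threshold = 0.25,
                                strides = c(8, 16, 32), num_classes = 2,
                                reg_max = 16, labels = CLASS_LABELS) {
  if (length(outputs) != length(strides))
    stop("expected one output map per detection scale")
  res <- list()
  for (si in seq_along(outputs)) {
    o <- outputs[[si]]
    stride <- strides[si]
    H <- dim(o)[1]; W <- dim(o)[2]
    if (dim(o)[3] != num_classes + 4 * reg_max)
      stop("output channel count does not match head configuration")
    cls <- stats::plogis(o[, , seq_len(num_classes), drop = FALSE])
    reg <- o[, , num_classes + seq_len(4 * reg_max), drop = FALSE]
    # distribution expectation per side
    bins <- seq_len(reg_max) - 1
    dist <- array(0, dim = c(H, W, 4))
    for (s in 1:4) {
      logit <- reg[, , (s - 1) * reg_max + seq_len(reg_max), drop = FALSE]
      mx <- apply(logit, c(1, 2), max)
      e <- exp(logit - array(mx, dim = dim(logit)))
      den <- apply(e, c(1, 2), sum)
      num <- apply(e * rep(bins, each = H * W), c(1, 2), sum)
      dist[, , s] <- num / den
    }
    score <- apply(cls, c(1, 2), max)
    lab_i <- apply(cls, c(1, 2), which.max)
    hit <- which(score >= conf_threshold, arr.ind = TRUE)
    if (nrow(hit)) {
      cy <- (hit[, 1] - 0.5) * stride
      cx <- (hit[, 2] - 0.5) * stride
      l <- dist[cbind(hit, 1)] * stride
      t <- dist[cbind(hit, 2)] * stride
      r <- dist[cbind(hit, 3)] * stride
      b <- dist[cbind(hit, 4)] * stride
      res[[length(res) + 1]] <- data.frame(
        x1 = cx - l, y1 = cy - t, x2 = cx + r, y2 = cy + b,
        label = labels[lab_i[hit]], confidence = score[hit],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(detections(numeric(0), numeric(0), numeric(0),
                                      numeric(0), character(0), numeric(0)))
  d <- do.call(rbind, res)
  d <- d[d$x2 > d$x1 & d$y2 > d$y1, , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("detections", "data.frame")
  d
}

#' Write detections to CSV
#' @param dets detection table
#' @param path output file
#' @param image image identifier recorded in the first column
#' @export
write_detections_csv <- function(dets, path, image = "image") {
  df <- cbind(data.frame(image = rep(image, nrow(dets))), as.data.frame(dets))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
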