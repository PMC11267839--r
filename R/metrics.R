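# ---------------------------------------------------------------------------
# Detection evaluation: greedy confidence-ordered matching against ground
# truth, precision/recall, average precision (area under the monotone
# precision envelope, all-point interpolation) and mAP50.
# ---------------------------------------------------------------------------

#' Match detections to ground-truth boxes
#'
#' Greedy one-to-one matching: detections are processed in order of
#' descending confidence; each claims the highest-IoU unmatched ground-truth
#' box of its class if that IoU reaches `iou_threshold` (a true positive),
#' otherwise it is a false positive.  Ties at equal IoU are broken by
#' ground-truth index, so evaluation is deterministic.  Unmatched ground
#' truth counts as false negatives.
#'
#' @param dets detection table (columns x1, y1, x2, y2, label, confidence)
#' @param gts ground-truth table (columns x1, y1, x2, y2, label)
#' @param iou_threshold matching threshold (0.5 for mAP50)
#' @return a `match_result`: data.frame of detections with logical `tp`, plus
#'   attributes `fn` (count) and `n_gt`
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  ord <- order(-dets$confidence)
  dets <- dets[ord, , drop = FALSE]
  tp <- logical(nrow(dets))
  matched_gt <- rep(FALSE, nrow(gts))
  if (nrow(dets)) {
    gm <- as.matrix(gts[, c("x1", "y1", "x2", "y2")])
    for (i in seq_len(nrow(dets))) {
      cand <- which(!matched_gt & gts$label == dets$label[i])
      if (!length(cand)) next
      ious <- iou_vec(as.numeric(dets[i, c("x1", "y1", "x2", "y2")]),
                      gm[cand, , drop = FALSE])
      best <- cand[which.max(ious)]   # first index wins ties
      if (max(ious) >= iou_threshold) {
        tp[i] <- TRUE
        matched_gt[best] <- TRUE
      }
    }
  }
  out <- dets
  out$tp <- tp
  structure(out, fn = sum(!matched_gt), n_gt = nrow(gts),
            class = c("match_result", "data.frame"))
}

#' Precision and recall of a match result
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`.  With zero detections the
#' precision is reported as 1 by convention (no false positives were made);
#' with zero ground truth the recall is likewise 1.
#'
#' @param match a `match_result`
#' @return named numeric `c(precision = , recall = )`
#' @export
precision_recall <- function(match) {
  tp <- sum(match$tp)
  fp <- sum(!match$tp)
  fn <- attr(match, "fn")
  c(precision = if (tp + fp == 0) 1 else tp / (tp + fp),
    recall = if (tp + fn == 0) 1 else tp / (tp + fn))
}

#' Average precision from a confidence-ranked TP/FP sequence
#'
#' Area under the precision-recall curve using the monotone precision
#' envelope (all-point interpolation): precision at each recall level is
#' replaced by the maximum precision at any equal-or-higher recall before
#' integrating over recall.
#'
#' @param tp logical vector, detections in descending confidence order
#' @param n_gt number of ground-truth boxes of the class
#' @return AP in `[0, 1]`
#' @export
average_precision <- function(tp, n_gt) {
  if (length(tp) == 0 || n_gt == 0 || !any(tp)) return(0)
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  recall <- cum_tp / n_gt
  precision <- cum_tp / (cum_tp + cum_fp)
  # monotone envelope from the right
  penv <- rev(cummax(rev(precision)))
  r <- c(0, recall)
  sum((r[-1] - r[-length(r)]) * penv)
}

#' Mean average precision over classes
#' @param per_class_ap numeric vector of per-class APs
#' @return mean AP
#' @export
map50 <- function(per_class_ap) {
  if (length(per_class_ap) == 0) stop("at least one class is required")
  mean(per_class_ap)
}

#' Evaluate detections against ground truth over a set of images
#'
#' Pools detections of all images (per class), ranks them by confidence,
#' matches per image at `iou_threshold`, and computes per-class AP, mAP and
#' the precision/recall at the confidence maximising F1 (the operating point
#' reported alongside mAP).
#'
#' @param det_list named list of detection tables, one per image
#' @param gt_list named list of ground-truth tables (same names)
#' @param iou_threshold IoU threshold (0.5 for mAP50)
#' @param classes class label vocabulary
#' @return an `ap_result` list: `per_class_ap`, `map50`, `precision`,
#'   `recall`, `f1_confidence`, `curves`
#' @export
evaluate_detections <- function(det_list, gt_list, iou_threshold = 0.5,
                                classes = CLASS_LABELS) {
  stopifnot(length(det_list) == length(gt_list))
  imgs <- seq_along(det_list)
  # per-image matching (one-to-one inside each image)
  matches <- lapply(imgs, function(i)
    match_detections(det_list[[i]], gt_list[[i]], iou_threshold))
  pooled <- do.call(rbind, lapply(imgs, function(i) {
    m <- matches[[i]]
    if (nrow(m) == 0) return(NULL)
    data.frame(label = m$label, confidence = m$confidence, tp = m$tp,
               stringsAsFactors = FALSE)
  }))
  n_gt_class <- vapply(classes, function(cl)
    sum(vapply(gt_list, function(g) sum(g$label == cl), 1)), 1)
  per_class_ap <- vapply(classes, function(cl) {
    if (is.null(pooled)) return(0)
    d <- pooled[pooled$label == cl, , drop = FALSE]
    d <- d[order(-d$confidence), , drop = FALSE]
    average_precision(d$tp, n_gt_class[[cl]])
  }, 1)
  # operating point: sweep pooled confidences for the best F1
  total_gt <- sum(n_gt_class)
  best <- c(p = 1, r = 0, f1 = -1, conf = 1)
  if (!is.null(pooled) && nrow(pooled)) {
    d <- pooled[order(-pooled$confidence), , drop = FALSE]
    cum_tp <- cumsum(d$tp); cum_fp <- cumsum(!d$tp)
    p <- cum_tp / (cum_tp + cum_fp)
    r <- if (total_gt > 0) cum_tp / total_gt else rep(1, nrow(d))
    f1 <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
    i <- which.max(f1)
    best <- c(p = p[i], r = r[i], f1 = f1[i], conf = d$confidence[i])
  }
  structure(list(per_class_ap = per_class_ap, map50 = map50(per_class_ap),
                 precision = unname(best["p"]), recall = unname(best["r"]),
                 f1_confidence = unname(best["conf"]),
                 n_gt = n_gt_class),
            class = "ap_result")
}

#' @export
print.ap_result <- function(x, ...) {
  cat("detection evaluation (IoU 0.5)\n")
  for (cl in names(x$per_class_ap))
    cat(sprintf("  AP[%s] = %.4f  (n_gt = %d)\n", cl, x$per_class_ap[[cl]],
                x$n_gt[[cl]]))
  cat(sprintf("  mAP50 = %.4f\n", x$map50))
  cat(sprintf("  P = %.4f, R = %.4f at confidence %.3f\n", x$precision,
              x$recall, x$f1_confidence))
  invisible(x)
}
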