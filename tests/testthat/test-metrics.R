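# Matching, precision/recall, AP and mAP.

test_that("greedy matching handles the canonical cases", {
  gt <- data.frame(x1 = 0, y1 = 0, x2 = 10, y2 = 10, label = "sprout",
                   stringsAsFactors = FALSE)
  d1 <- detections(0, 0, 10, 10, "sprout", 0.9)
  m <- match_detections(d1, gt)
  expect_equal(sum(m$tp), 1)
  expect_equal(attr(m, "fn"), 0)
  # two coincident detections on one GT: one TP, one FP (one-to-one rule)
  d2 <- detections(c(0, 0), c(0, 0), c(10, 10), c(10, 10),
                   c("sprout", "sprout"), c(0.9, 0.8))
  m2 <- match_detections(d2, gt)
  expect_equal(sum(m2$tp), 1)
  expect_equal(sum(!m2$tp), 1)
  # class mismatch never matches
  d3 <- detections(0, 0, 10, 10, "not_sprout", 0.9)
  m3 <- match_detections(d3, gt)
  expect_equal(sum(m3$tp), 0)
  expect_equal(attr(m3, "fn"), 1)
})

test_that("greedy matching equals exhaustive assignment on small scenes", {
  set.seed(31)
  for (k in 1:20) {
    gt <- rand_boxes(sample(1:5, 1), seed = 310 + k)
    dd <- rand_boxes(sample(1:5, 1), seed = 620 + k)
    # mix in some near-copies of GT so matches exist
    if (nrow(gt) >= 2) {
      jit <- gt[1:2, ]
      jit$x1 <- jit$x1 + 1; jit$x2 <- jit$x2 + 1
      dd <- rbind(dd, jit)
    }
    d <- as_dets(dd, runif(nrow(dd), 0.5, 1))
    m <- match_detections(d, gt, 0.5)
    expect_equal(sum(m$tp), brute_force_tp(d, gt, 0.5))
  }
})

test_that("precision and recall follow their definitions and conventions", {
  fake <- function(tp, fp, fn) {
    d <- data.frame(tp = c(rep(TRUE, tp), rep(FALSE, fp)))
    structure(d, fn = fn, n_gt = tp + fn, class = c("match_result",
                                                    "data.frame"))
  }
  expect_equal(precision_recall(fake(9, 1, 0))[["precision"]], 0.9)
  expect_equal(precision_recall(fake(9, 0, 3))[["recall"]], 0.75)
  pr <- precision_recall(fake(0, 0, 0))
  expect_equal(unname(pr), c(1, 1))   # vacuous case
})

test_that("average precision: perfect, empty and hand-computed curves", {
  expect_equal(average_precision(rep(TRUE, 10), 10), 1)
  expect_equal(average_precision(rep(FALSE, 5), 5), 0)
  expect_equal(average_precision(logical(0), 3), 0)
  # 3-detection toy: TP, FP, TP with 2 GT
  # recalls 0.5, 0.5, 1.0; precisions 1, 1/2, 2/3; envelope -> 1, 2/3, 2/3
  # area = 0.5 * 1 + 0.5 * 2/3
  expect_equal(average_precision(c(TRUE, FALSE, TRUE), 2),
               0.5 * 1 + 0.5 * 2 / 3)
})

test_that("removing a true positive never increases AP", {
  set.seed(32)
  for (k in 1:10) {
    tp <- sample(c(TRUE, FALSE), 8, replace = TRUE)
    if (!any(tp)) tp[1] <- TRUE
    n_gt <- sum(tp) + sample(0:3, 1)
    ap <- average_precision(tp, n_gt)
    drop1 <- which(tp)[1]
    ap2 <- average_precision(tp[-drop1], n_gt)
    expect_lte(ap2, ap + 1e-12)
  }
})

test_that("mAP is the class mean and needs at least one class", {
  expect_equal(map50(c(1, 0.5)), 0.75)
  expect_equal(map50(0.8), 0.8)
  expect_error(map50(numeric(0)), "class")
})

test_that("feeding ground truth back as detections is a perfect evaluation", {
  set.seed(33)
  gt_list <- lapply(1:6, function(i) rand_boxes(sample(2:6, 1), seed = 330 + i))
  det_list <- lapply(gt_list, as_dets)
  ev <- evaluate_detections(det_list, gt_list)
  expect_equal(ev$map50, 1)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
})

test_that("evaluation is invariant to image order and uniform score rescaling", {
  set.seed(34)
  gt_list <- lapply(1:4, function(i) rand_boxes(4, seed = 340 + i))
  det_list <- lapply(seq_along(gt_list), function(i) {
    g <- gt_list[[i]]
    keep <- runif(4) < 0.8
    extra <- rand_boxes(2, seed = 680 + i)
    as_dets(rbind(g[keep, ], extra),
            c(runif(sum(keep), 0.6, 1), runif(2, 0.1, 0.5)))
  })
  ev1 <- evaluate_detections(det_list, gt_list)
  perm <- c(3, 1, 4, 2)
  ev2 <- evaluate_detections(det_list[perm], gt_list[perm])
  expect_equal(ev1$map50, ev2$map50)
  det_scaled <- lapply(det_list, function(d) {
    d$confidence <- d$confidence * 0.5
    d
  })
  ev3 <- evaluate_detections(det_scaled, gt_list)
  expect_equal(ev1$map50, ev3$map50)
})
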