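# IoU, hard/soft NMS and head decoding.

test_that("IoU handles the canonical cases", {
  expect_equal(box_iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(box_iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_equal(box_iou(c(0, 0, 2, 2), c(1, 0, 3, 2)), 1 / 3)
  expect_equal(box_iou(c(1, 0, 3, 2), c(0, 0, 2, 2)), 1 / 3)  # symmetry
  expect_error(box_iou(c(0, 0, 0, 2), c(0, 0, 1, 1)), "degenerate")
})

test_that("soft-NMS decays coincident boxes by the Gaussian factor", {
  d <- detections(c(0, 0), c(0, 0), c(10, 10), c(10, 10),
                  c("sprout", "sprout"), c(0.9, 0.8))
  out <- soft_nms(d, sigma = 0.5, score_threshold = 0.01)
  expect_equal(nrow(out), 2)
  expect_equal(out$confidence[1], 0.9)
  expect_equal(out$confidence[2], 0.8 * exp(-1 / 0.5), tolerance = 1e-12)
  # at a higher threshold the decayed box is pruned
  out2 <- soft_nms(d, sigma = 0.5, score_threshold = 0.2)
  expect_equal(nrow(out2), 1)
})

test_that("non-overlapping boxes keep their scores; empty input passes through", {
  d <- detections(c(0, 50), c(0, 50), c(10, 60), c(10, 60),
                  c("sprout", "sprout"), c(0.9, 0.8))
  out <- soft_nms(d)
  expect_equal(sort(out$confidence), c(0.8, 0.9))
  empty <- d[0, ]
  expect_equal(nrow(soft_nms(empty)), 0)
  expect_equal(nrow(nms_hard(empty)), 0)
})

test_that("sigma -> 0 soft-NMS converges to hard NMS on overlapping boxes", {
  set.seed(21)
  b <- rand_boxes(12, seed = 21)
  d <- as_dets(b, runif(12, 0.3, 1))
  hard <- nms_hard(d, iou_threshold = 0)   # suppress any overlap
  soft <- soft_nms(d, sigma = 1e-9, score_threshold = 0.01)
  # the surviving sets coincide (soft decays every overlapping box to ~0)
  key <- function(x) sort(paste(round(x$x1, 6), round(x$y1, 6), x$label))
  expect_equal(key(soft), key(hard))
})

test_that("soft-NMS never increases confidences and never grows the set", {
  set.seed(22)
  for (k in 1:5) {
    b <- rand_boxes(10, seed = 22 + k)
    conf <- runif(10, 0.05, 1)
    d <- as_dets(b, conf)
    out <- soft_nms(d)
    expect_lte(nrow(out), nrow(d))
    for (i in seq_len(nrow(out))) {
      orig <- conf[b$x1 == out$x1[i] & b$y1 == out$y1[i]][1]
      expect_lte(out$confidence[i], orig + 1e-12)
    }
  }
})

test_that("hard NMS is idempotent", {
  set.seed(23)
  d <- as_dets(rand_boxes(15, seed = 23), runif(15))
  once <- nms_hard(d)
  twice <- nms_hard(once)
  expect_equal(nrow(once), nrow(twice))
  expect_equal(sort(once$confidence), sort(twice$confidence))
})

test_that("per-class suppression keeps sprout and not-sprout independent", {
  d <- detections(c(0, 0), c(0, 0), c(10, 10), c(10, 10),
                  c("sprout", "not_sprout"), c(0.9, 0.8))
  out <- soft_nms(d)
  expect_equal(sort(out$confidence), c(0.8, 0.9))  # no cross-class decay
})

test_that("decoding maps all-(-inf) logits to no detections and a hot cell to one box", {
  nc <- 2; rm_ <- 16
  mk <- function(S) array(-1e9, dim = c(S, S, nc + 4 * rm_))
  outs <- list(mk(8), mk(4), mk(2))
  expect_equal(nrow(decode_head_outputs(outs, 0.25)), 0)
  # one hot location on the stride-8 map: cell (3, 5), sprout,
  # ltrb distances all in bin 2 (distance 2 strides = 16 px)
  o <- outs
  o[[1]][3, 5, 1] <- 20                      # sprout logit -> score ~1
  for (s in 1:4) o[[1]][3, 5, nc + (s - 1) * rm_ + 3] <- 30  # bin index 2
  d <- decode_head_outputs(o, 0.25)
  expect_equal(nrow(d), 1)
  expect_equal(d$label, "sprout")
  # centre at ((5-0.5)*8, (3-0.5)*8) = (36, 20), sides 2*8 = 16 px away
  expect_equal(c(d$x1, d$y1, d$x2, d$y2), c(36 - 16, 20 - 16, 36 + 16, 20 + 16),
               tolerance = 1e-6)
  expect_gt(d$confidence, 0.99)
  # mismatched channel count is rejected
  bad <- list(mk(8)[, , 1:10], mk(4), mk(2))
  expect_error(decode_head_outputs(bad, 0.25), "channel")
})
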