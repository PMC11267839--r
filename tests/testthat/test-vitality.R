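# Germination rate, energy, index and replicate aggregation.

test_that("germination rate follows N_t / N x 100", {
  expect_equal(germination_rate(117, 120), 97.5)
  expect_equal(germination_rate(0, 120), 0)
  expect_equal(germination_rate(120, 120), 100)
  expect_error(germination_rate(1, 0), "positive")
  expect_error(germination_rate(5, 4), "\\[0, N\\]")
})

test_that("germination energy takes the last observation at or before 32 h", {
  obs <- function(t, g, n = 120) data.frame(time_h = t, germinated = g,
                                            total = n)
  expect_equal(germination_energy(obs(c(30, 40), c(120, 120))), 100)
  expect_equal(germination_energy(obs(c(32, 40), c(0, 120))), 0)
  # step schedule: 108 of 120 germinated at the 32 h mark
  o <- obs(seq(4, 48, by = 4), c(0, 10, 30, 60, 90, 100, 108, 108, 115, 118,
                                 120, 120))
  expect_equal(germination_energy(o), 90)
  expect_error(germination_energy(obs(c(10, 20), c(5, 10))), "cutoff")
})

test_that("germination index weights early germination more", {
  o <- data.frame(time_h = c(10, 20), germinated = c(10, 30), total = 40)
  expect_equal(germination_index(o), 10 / 10 + 20 / 20)
  expect_equal(germination_index(
    data.frame(time_h = c(10, 20), germinated = c(0, 0), total = 40)), 0)
  expect_error(germination_index(
    data.frame(time_h = c(10, 10), germinated = c(1, 2), total = 4)),
    "strictly increasing")
})

test_that("shifting any germination event earlier never decreases the index", {
  # enumerate small schedules: counts over 4 time points
  times <- c(6, 12, 24, 36)
  set.seed(51)
  for (k in 1:25) {
    g <- sort(sample(0:8, 4, replace = TRUE))
    base <- germination_index(data.frame(time_h = times, germinated = g))
    # shift one germination event one time point earlier
    idx <- which(diff(c(0, g)) > 0)
    if (!length(idx)) next
    i <- idx[sample.int(length(idx), 1)]
    g2 <- g
    if (i == 1) next
    g2[i - 1] <- g2[i - 1] + 1            # one seed germinates a step earlier
    shifted <- germination_index(data.frame(time_h = times, germinated = g2))
    expect_gte(shifted, base - 1e-12)
  }
  # all-at-once early vs split late with equal final count
  early <- data.frame(time_h = c(10, 20), germinated = c(20, 20), total = 20)
  late <- data.frame(time_h = c(10, 20), germinated = c(0, 20), total = 20)
  expect_gt(germination_index(early), germination_index(late))
})

test_that("replicate aggregation: degenerate cases and hand-recomputed windows", {
  mk <- function(rep_, g) data.frame(treatment = "CK", replicate = rep_,
                                     cell = 1L, time_h = seq(4, 48, 4),
                                     germinated = g, total = 20)
  g1 <- cummax(pmin(20, round(seq(0, 22, length.out = 12))))
  obs <- rbind(mk(1, g1), mk(2, g1), mk(3, g1))
  v <- vitality_series(obs, window_hours = 8)
  expect_true(all(v$windows$rate_sd == 0))          # identical replicates
  single <- vitality_series(mk(1, g1), window_hours = 8)
  expect_equal(single$summary$final_rate, 100 * g1[12] / 20)
  # hand loop: windowed mean = mean over replicates of the rate at the last
  # time in the window
  g2 <- cummax(pmin(20, round(seq(0, 26, length.out = 12))))
  obs2 <- rbind(mk(1, g1), mk(2, g2))
  v2 <- vitality_series(obs2, window_hours = 8)
  for (wi in seq_len(nrow(v2$windows))) {
    w_end <- v2$windows$window_end[wi]
    hand <- mean(c(100 * g1[match(w_end, seq(4, 48, 4))] / 20,
                   100 * g2[match(w_end, seq(4, 48, 4))] / 20))
    expect_equal(v2$windows$rate_mean[wi], hand)
  }
})

test_that("vitality indices are invariant to replicate ordering", {
  set.seed(52)
  mk <- function(rep_) {
    g <- cummax(sample(0:20, 12, replace = TRUE))
    data.frame(treatment = "A", replicate = rep_, cell = 1L,
               time_h = seq(4, 48, 4), germinated = g, total = 20)
  }
  reps <- lapply(1:3, mk)
  v1 <- vitality_series(do.call(rbind, reps))
  v2 <- vitality_series(do.call(rbind, reps[c(3, 1, 2)]))
  expect_equal(v1$summary$index, v2$summary$index)
  expect_equal(v1$summary$energy, v2$summary$energy)
})

test_that("detection counts convert to monotone observations with flagging", {
  df <- data.frame(treatment = "CK", replicate = 1L, cell = 1L,
                   time_h = c(4, 8, 12, 16),
                   n_sprout = c(0, 7, 6, 8), n_total = c(20, 20, 20, 20))
  obs <- counts_from_detections(df)
  expect_equal(obs$germinated, c(0, 7, 7, 8))   # dip monotonised
  expect_equal(obs$total, rep(20, 4))
  df2 <- rbind(df, data.frame(treatment = "CK", replicate = 1L, cell = 1L,
                              time_h = 20, n_sprout = 0, n_total = 0))
  obs2 <- counts_from_detections(df2)
  expect_equal(nrow(obs2), 4)                   # zero-box frame excluded
  expect_equal(nrow(attr(obs2, "flagged")), 1)
  # 20 boxes, 5 sprout -> 5/20
  df3 <- data.frame(treatment = "CK", replicate = 1L, cell = 1L, time_h = 4,
                    n_sprout = 5, n_total = 20)
  expect_equal(counts_from_detections(df3)$germinated / 20, 0.25)
})

test_that("treatment grid enumerates the 25 coded combinations", {
  g <- treatment_grid()
  expect_equal(nrow(g), 25)
  expect_setequal(g$treatment[g$nacl == 0], c("CK", "A", "B", "C", "D"))
  expect_true("BT2" %in% g$treatment)
  expect_equal(g$zno[g$treatment == "DT4"], 800)
})
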