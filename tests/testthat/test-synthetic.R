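# Synthetic scene generation: schedules, rendering and on-disk runs.

test_that("schedules are deterministic and respond to the dose design", {
  cfg <- tiny_scene(seed = 61)
  s1 <- sample_schedule(cfg, "CK", seed = 3)
  s2 <- sample_schedule(cfg, "CK", seed = 3)
  expect_identical(s1$times, s2$times)
  expect_error(sample_schedule(cfg, "XT9"), "unknown treatment")
  # high salt lowers the germinated fraction (Monte-Carlo at large n)
  big <- scene_config(cells = 1, seeds_per_cell = 10000, image_size = 64,
                      seed = 62)
  f0 <- mean(is.finite(sample_schedule(big, "CK", seed = 1)$times))
  f4 <- mean(is.finite(sample_schedule(big, "T4", seed = 1)$times))
  expect_gt(f0, f4)
  expect_gt(f0, 0.95)
  # hormesis: moderate ZnO relieves salt stress, 800 mg/L relieves less
  fB <- mean(is.finite(sample_schedule(big, "BT4", seed = 1)$times))
  expect_gt(fB, f4)
  # germination speed without salt: an interior ZnO dose is fastest (the
  # high-dose delay pushes the speed optimum to 200 mg/L) and the highest
  # dose is slower than the untreated control
  meds <- vapply(c("CK", "A", "B", "C", "D"), function(tr)
    sample_schedule(big, tr, seed = 1)$median_time, 1)
  expect_equal(unname(which.min(meds)), 2)   # 200 mg/L
  expect_gt(meds[["D"]], meds[["CK"]])
})

test_that("non-germination probability is non-decreasing in NaCl at fixed ZnO", {
  cfg <- tiny_scene(seed = 63)
  for (z in c("", "A", "B", "C", "D")) {
    codes <- if (z == "") c("CK", "T1", "T2", "T3", "T4")
             else paste0(z, c("", "T1", "T2", "T3", "T4"))
    codes[1] <- if (z == "") "CK" else z
    p <- vapply(codes, function(tr) sample_schedule(cfg, tr)$p_germ, 1)
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("labels flip once from not_sprout to sprout at the scheduled time", {
  cfg <- tiny_scene(seed = 64, cells = 1, image_size = 128, interval_h = 2)
  sch <- sample_schedule(cfg, "CK")
  times <- capture_times(cfg)
  labels <- sapply(times, function(t) {
    fr <- render_frame(cfg, sch, 1, t)
    fr$record$boxes$label
  })
  for (si in seq_len(cfg$seeds_per_cell)) {
    lab <- labels[si, ]
    flips <- sum(diff(lab == "sprout") != 0)
    expect_lte(flips, 1)                         # single 0 -> 1 step
    if (is.finite(sch$times[si]) && sch$times[si] <= max(times)) {
      t_flip <- times[match("sprout", lab)]
      expect_lte(abs(t_flip - sch$times[si]), cfg$interval_h)
    }
  }
  # boundary conditions
  fr0 <- render_frame(cfg, sch, 1, 0)
  expect_true(all(fr0$record$boxes$label == "not_sprout"))
  sch_all <- sch; sch_all$times <- rep(1, length(sch$times))
  fr48 <- render_frame(cfg, sch_all, 1, 46)
  expect_true(all(fr48$record$boxes$label == "sprout"))
  expect_error(render_frame(cfg, sch, 1, 100), "duration")
})

test_that("rendering is deterministic and boxes stay inside the frame", {
  cfg <- tiny_scene(seed = 65, cells = 1, image_size = 128)
  sch <- sample_schedule(cfg, "CK")
  f1 <- render_frame(cfg, sch, 1, 24)
  f2 <- render_frame(cfg, sch, 1, 24)
  expect_identical(f1$image, f2$image)           # pixel-identical
  b <- f1$record$boxes
  expect_true(all(b$x1 >= 0 & b$y1 >= 0 & b$x2 <= 128 & b$y2 <= 128))
  expect_true(all(b$x2 > b$x1 & b$y2 > b$y1))
  # germinated seeds show bright radicle pixels inside their box
  g <- which(b$label == "sprout")
  if (length(g)) {
    bb <- b[g[1], ]
    expect_gt(max(f1$image[bb$y1:bb$y2, bb$x1:bb$x2, 1]), 0.9)
  }
})

test_that("generate_run writes counts, refuses clobbering and parses back", {
  cfg <- scene_config(cells = 1, seeds_per_cell = 4, image_size = 96,
                      interval_h = 0.25, duration_h = 1, seed = 66)
  d <- tempfile()
  man <- generate_run(cfg, d, render = "png")
  expect_equal(nrow(man), 4)                     # 1 cell x 4 timepoints
  expect_equal(length(dir(file.path(d, "annotations"))), 4)
  expect_equal(length(dir(file.path(d, "images"))), 4)
  expect_error(generate_run(cfg, d), "not empty")
  # round trip through the reader: 100% parse success
  recs <- lapply(man$image_id, function(id)
    read_voc_xml(file.path(d, "annotations", paste0(id, ".xml"))))
  expect_equal(length(recs), 4)
  expect_true(all(vapply(recs, function(r) nrow(r$boxes) == 4, TRUE)))
  # manifest determinism under the same seed
  d2 <- tempfile()
  man2 <- generate_run(cfg, d2, render = "none")
  expect_identical(man[names(man2)], man2)
  unlink(c(d, d2), recursive = TRUE)
})

test_that("ground-truth boxes fed to the vitality pipeline recover the schedule", {
  cfg <- tiny_scene(seed = 67, cells = 2, image_size = 128, interval_h = 4,
                    seeds = 6)
  sch <- sample_schedule(cfg, "CK")
  times <- capture_times(cfg)
  rows <- list()
  for (cell in 1:2) for (t in times) {
    rec <- render_frame(cfg, sch, cell, t)$record
    rows[[length(rows) + 1]] <- data.frame(
      treatment = "CK", replicate = 1L, cell = cell, time_h = t,
      n_sprout = sum(rec$boxes$label == "sprout"),
      n_total = nrow(rec$boxes))
  }
  obs <- counts_from_detections(do.call(rbind, rows))
  # expected cumulative counts straight from the schedule
  for (cell in 1:2) {
    idx <- (cell - 1) * 6 + 1:6
    expected <- vapply(times, function(t) sum(sch$times[idx] <= t), 1L)
    got <- obs$germinated[obs$cell == cell]
    expect_equal(got, expected)
  }
})
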