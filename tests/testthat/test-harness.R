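# Run configuration, smoke training mechanics and the end-to-end pipeline.

test_that("run_config defaults match the training recipe and log overrides", {
  rc <- run_config()
  expect_equal(rc$epochs, 100L)
  expect_equal(rc$batch, 16L)
  expect_equal(rc$imgsz, 640L)
  expect_equal(rc$optimizer, "Adam")
  expect_equal(rc$lr, 1e-4)
  expect_equal(rc$weight_decay, 1e-4)
  expect_equal(rc$momentum, 0.937)
  expect_equal(rc$workers, 8L)
  rc2 <- run_config(epochs = 5L, lr = 0.1)
  expect_setequal(attr(rc2, "overrides"), c("epochs", "lr"))
  expect_error(run_config(banana = 1), "unknown run_config")
})

test_that("smoke training is reproducible under a fixed seed", {
  f1 <- train_smoke(n_images = 6, epochs = 2, image_size = 96, seed = 4)
  f2 <- train_smoke(n_images = 6, epochs = 2, image_size = 96, seed = 4)
  expect_equal(f1$loss_trace, f2$loss_trace, tolerance = 1e-12)
  expect_true(all(diff(f1$loss_trace) < 0))
})

test_that("trained objectness rises on seed cells relative to background", {
  fit <- train_smoke(n_images = 10, epochs = 8, image_size = 96, seed = 5,
                     lr = 0.5)
  model <- fit$model
  rec <- fit$frames[[1]]
  sc <- scene_config(cells = 4, seeds_per_cell = 8, image_size = 96, seed = 5)
  sch <- sample_schedule(sc, "CK", seed = 5)
  fr <- render_frame(sc, sch, 1, rec$timestamp_h)
  out <- model_forward(model, fr$image)[[1]]
  score <- stats::plogis(pmax(out[, , 1], out[, , 2]))
  S <- dim(score)[1]
  tgt <- sproutscan:::rasterise_targets(fr$record$boxes, 96, 8, 2, 16)
  pos <- tgt$cls[, , 1] + tgt$cls[, , 2] > 0
  expect_gt(mean(score[pos]), mean(score[!pos]))
})

test_that("oracle pipeline is a perfect identity end to end", {
  rep <- run_pipeline(scene_config(cells = 3, seeds_per_cell = 5,
                                   image_size = 192, interval_h = 4,
                                   duration_h = 48, seed = 8))
  expect_equal(rep$evaluation$map50, 1)
  expect_equal(rep$evaluation$precision, 1)
  expect_equal(rep$evaluation$recall, 1)
  expect_equal(rep$n_images, 3 * 12)
  expect_s3_class(rep$vitality, "vitality_series")
  unlink(rep$out_dir, recursive = TRUE)
})

test_that("simulated treatment grid covers all 25 treatments and both dose laws", {
  cfg <- scene_config(cells = 4, seeds_per_cell = 25, image_size = 64,
                      interval_h = 1, duration_h = 48, seed = 9)
  obs <- simulate_observations(cfg, replicates = 3, cells_per_rep = 4,
                               seed = 9)
  v <- vitality_series(obs)
  expect_equal(nrow(v$summary), 25)
  expect_error(simulate_observations(cfg, treatments = character(0)),
               "empty treatment grid")
  g <- treatment_grid()
  s <- merge(v$summary, g, by = "treatment")
  # monotone NaCl inhibition at ZnO = 0
  r0 <- s[s$zno == 0, ]
  r0 <- r0[order(r0$nacl), ]
  expect_true(all(diff(r0$final_rate) < 0))
  # unimodal ZnO response under strong salt: an interior optimum that beats
  # both the unamended and the highest-dose treatment
  r4 <- s[s$nacl == 120, ]
  r4 <- r4[order(r4$zno), ]
  peak <- which.max(r4$index)
  expect_true(peak > 1 && peak < 5)
  expect_gt(r4$index[peak], r4$index[1])
  expect_gt(r4$index[peak], r4$index[5])
  expect_gt(r4$final_rate[peak], r4$final_rate[1])
})

test_that("checkpoints round-trip with half precision", {
  v <- assemble_variant("PC-YOLOv8", 2, 64)
  m <- instantiate_model(v, 10)
  f16 <- tempfile(fileext = ".ckpt")
  save_checkpoint(m, f16, "fp16")
  back <- load_checkpoint(f16)
  tens <- sproutscan:::model_tensors(m)
  expect_equal(length(back), length(tens))
  nm <- names(tens)[5]
  expect_equal(back[[nm]], tens[[nm]], tolerance = 2e-3)  # fp16 rounding
  unlink(f16)
})
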