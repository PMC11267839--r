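# VOC XML round trips, dish-stratified splitting, temporal filter and the
# photometric augmentation policy.

test_that("VOC XML writer and reader are inverse on randomized records", {
  set.seed(41)
  for (k in 1:5) {
    b <- rand_boxes(sample(1:6, 1), size = 200, seed = 410 + k)
    b[, 1:4] <- round(b[, 1:4])
    b$x2 <- pmax(b$x2, b$x1 + 1); b$y2 <- pmax(b$y2, b$y1 + 1)
    rec <- annotation_record(sprintf("img%03d", k), dish_id = k, cell_id = k,
                             timestamp_h = k * 0.25, boxes = b,
                             width = 256, height = 256)
    f <- tempfile(fileext = ".xml")
    write_voc_xml(rec, f)
    back <- read_voc_xml(f)
    expect_equal(back$image_id, rec$image_id)
    expect_equal(back$dish_id, rec$dish_id)
    expect_equal(back$timestamp_h, rec$timestamp_h)
    expect_equal(back$boxes$x1, rec$boxes$x1)
    expect_equal(back$boxes$x2, rec$boxes$x2)
    expect_equal(back$boxes$label, rec$boxes$label)
  }
})

test_that("labels outside the two-class vocabulary are rejected by name", {
  f <- tempfile(fileext = ".xml")
  writeLines(c("<annotation><filename>x.png</filename>",
               "<source><dish>1</dish><cell>1</cell>",
               "<timestamp_h>1.0</timestamp_h></source>",
               "<size><width>64</width><height>64</height><depth>3</depth></size>",
               "<object><name>seed</name><bndbox><xmin>1</xmin><ymin>1</ymin>",
               "<xmax>5</xmax><ymax>5</ymax></bndbox></object></annotation>"), f)
  expect_error(read_voc_xml(f), "seed")
  expect_error(annotation_record("a", 1, 1, 0.3, rand_boxes(1), 64, 64),
               "multiple of 0.25")
})

test_that("dish split keeps whole dishes together and partitions exhaustively", {
  man <- data.frame(image_id = sprintf("i%03d", 1:160),
                    dish_id = rep(1:16, each = 10),
                    timestamp_h = rep(seq(0.25, 2.5, 0.25), 16))
  sp <- dish_stratified_split(man)
  expect_equal(nrow(sp), 160)
  expect_equal(unname(table(sp$split)[c("train", "test", "val")]),
               c(120, 20, 20), ignore_attr = TRUE)
  cross <- table(sp$dish_id, sp$split)
  expect_true(all(rowSums(cross > 0) == 1))  # no dish in two splits
  expect_warning(dish_stratified_split(man[man$dish_id == 1, ]), "single dish")
  man_bad <- man; man_bad$dish_id[3] <- NA
  expect_error(dish_stratified_split(man_bad), "dish id")
})

test_that("temporal filter obeys its cutoff semantics", {
  man <- data.frame(image_id = sprintf("i%03d", 1:192),
                    dish_id = 1L, timestamp_h = seq(0, 47.75, 0.25))
  expect_equal(nrow(temporal_filter(man, 0)), 192)
  expect_equal(nrow(temporal_filter(man, 12)), 144)
  expect_equal(nrow(temporal_filter(man, 50)), 0)
})

test_that("augmentations are photometric, deterministic and parameterised", {
  set.seed(42)
  img <- array(runif(32 * 32 * 3, 0.2, 0.8), dim = c(32, 32, 3))
  expect_error(augment_image(img, "Rotate"), "unknown augmentation")
  # identity parameters leave the image unchanged
  expect_equal(augment_image(img, "Add", param = 0), img)
  expect_equal(augment_image(img, "Multiply", param = 1), img)
  expect_equal(augment_image(img, "GammaContrast", param = 1), img)
  for (m in c("Add", "Multiply", "GaussianBlur", "CoarsePepper",
              "GammaContrast", "GaussianNoise")) {
    a1 <- augment_image(img, m, seed = 7)
    a2 <- augment_image(img, m, seed = 7)
    expect_identical(a1, a2)           # determinism under a fixed seed
    expect_equal(dim(a1), dim(img))    # geometry untouched
    expect_true(all(a1 >= 0 & a1 <= 1))
  }
})

test_that("default augmentation policy doubles the set; ratio split hits 6:2:2", {
  man <- data.frame(image_id = sprintf("i%04d", 1:2304),
                    dish_id = rep(1:16, each = 144),
                    timestamp_h = rep(seq(12, 47.75, 0.25), 16))
  ds <- build_dataset(man, copies = 1, seed = 5)
  expect_equal(nrow(ds), 4608)
  expect_equal(sum(ds$source == "original"), 2304)
  expect_true(all(ds$method[ds$source == "augmented"] %in%
                    c("Add", "Multiply", "GaussianBlur", "CoarsePepper",
                      "GammaContrast", "GaussianNoise")))
  expect_equal(nrow(build_dataset(man[0, ])), 0)
  sp <- dish_stratified_split(ds, mode = "ratio")
  expect_equal(unname(table(sp$split)[c("train", "test", "val")]),
               c(2764, 922, 922), ignore_attr = TRUE)
})

test_that("per-split class ratios stay near the global ratio on synthetic data", {
  cfg <- tiny_scene(seed = 6, cells = 8, image_size = 128, interval_h = 8)
  d <- tempfile()
  man <- generate_run(cfg, d, render = "none")
  recs <- lapply(man$image_id, function(id)
    read_voc_xml(file.path(d, "annotations", paste0(id, ".xml"))))
  sp <- dish_stratified_split(recs, dish_map = list(train = 1:6, test = 7,
                                                    val = 8))
  frac <- function(ids) {
    rr <- recs[match(ids, vapply(recs, `[[`, "", "image_id"))]
    lab <- unlist(lapply(rr, function(r) r$boxes$label))
    mean(lab == "sprout")
  }
  global <- frac(sp$image_id)
  for (s in unique(sp$split)) {
    expect_lt(abs(frac(sp$image_id[sp$split == s]) - global), 0.05)
  }
  unlink(d, recursive = TRUE)
})
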