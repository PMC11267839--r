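# Variant assembly: shape contracts, ablation monotonicity and
# declarative/runnable consistency.

test_that("unknown variants and degenerate configs are rejected", {
  expect_error(assemble_variant("YOLOv9"), "valid names")
  expect_error(make_pplcnet_backbone(0), "positive")
  expect_error(make_ccfm_neck(c(32, 64), 48), "three entries")
  expect_error(make_ladh_head(0, c(48, 48, 48)), "num_classes")
})

test_that("all six variants expose three detection scales at strides 8/16/32", {
  for (nm in variant_names()) {
    v <- assemble_variant(nm, 2, 640)
    shapes <- variant_out_shapes(v, 640)
    expect_length(shapes, 3)
    expect_equal(vapply(shapes, function(s) s[2], 1), c(80, 40, 20),
                 ignore_attr = TRUE)
    expect_true(all(vapply(shapes, function(s) s[1], 1) > 0))
  }
})

test_that("ablation ladder is monotone in parameters and FLOPs", {
  reps <- lapply(variant_names(), function(nm)
    complexity_report(assemble_variant(nm, 2), 640))
  params <- vapply(reps, `[[`, 1, "params")
  flops <- vapply(reps, `[[`, 1, "flops")
  # P < baseline, PC < P (parameters)
  expect_lt(params[2], params[1])
  expect_lt(params[3], params[2])
  # FLOPs non-increasing along the whole ladder
  expect_true(all(diff(flops) <= 0))
})

test_that("declarative parameter count equals enumerated model weights", {
  for (nm in variant_names()) {
    v <- assemble_variant(nm, 2, 64)
    m <- instantiate_model(v, seed = 1)
    expect_identical(model_params(m), variant_params(v))
  }
})

test_that("runnable forward pass produces finite per-scale maps", {
  set.seed(7)
  x <- array(runif(128 * 128 * 3), dim = c(128, 128, 3))
  for (nm in variant_names()) {
    v <- assemble_variant(nm, 2, 128)
    m <- instantiate_model(v, seed = 2)
    o <- model_forward(m, x)
    expect_equal(vapply(o, function(a) dim(a)[1], 1),
                 c(16, 8, 4), ignore_attr = TRUE)
    expect_true(all(vapply(o, function(a) all(is.finite(a)), TRUE)))
    expect_equal(dim(o[[1]])[3], 2 + 4 * v$reg_max)
  }
})

test_that("CCFM neck maps all-zero inputs to finite outputs", {
  neck <- make_ccfm_neck(c(8L, 8L, 8L), 8L)
  graph <- c(list(
    gnode("p3", "in", spec_identity(8)),
    gnode("p4", "p3", spec_conv(8, 8, 3, 2, act = "none")),
    gnode("p5", "p4", spec_conv(8, 8, 3, 2, act = "none"))), neck$nodes)
  v <- structure(list(name = "test", num_classes = 2, input_size = 32,
                      graph = graph, outputs = neck$outputs,
                      strides = c(1, 2, 4), reg_max = 16),
                 class = "variant_spec")
  m <- instantiate_model(v, 3)
  o <- model_forward(m, array(0, dim = c(32, 32, 8)))
  expect_true(all(vapply(o, function(a) all(is.finite(a)), TRUE)))
  expect_equal(vapply(o, function(a) dim(a)[3], 1), rep(8, 3),
               ignore_attr = TRUE)
})

test_that("LADH head obeys the output-channel contract", {
  h1 <- make_ladh_head(1, c(48, 48, 48))
  expect_equal(h1[[1]]$children[[1]]$out_channels, 1)   # cls channels = nc
  h2 <- make_ladh_head(2, c(48, 48, 48))
  expect_equal(h2[[1]]$out_channels, 2 + 4 * 16)
  # regression branch deeper than classification branch (asymmetric pair)
  expect_gt(length(h2[[1]]$children[[2]]$children),
            length(h2[[1]]$children[[1]]$children))
})

test_that("focal modulation block preserves shape and channels", {
  s <- spec_focal(12, 8)
  set.seed(5)
  w <- init_weights(s)
  x <- array(rnorm(10 * 10 * 12), dim = c(10, 10, 12))
  y <- spec_forward(s, w, x)
  expect_equal(dim(y), dim(x))
  # constant input: away from the zero-padded borders every context level is
  # constant, so the interior output is constant and the global-average level
  # equals that interior constant per channel
  xc <- array(1, dim = c(20, 20, 12))
  yc <- spec_forward(s, w, xc)
  interior <- yc[8:13, 8:13, 1]
  expect_lt(stats::sd(interior), 1e-10)
})

test_that("variant YAML export round-trips the graph skeleton", {
  v <- assemble_variant("PC-YOLOv8", 2)
  f <- tempfile(fileext = ".yaml")
  write_variant_yaml(v, f)
  y <- yaml::read_yaml(f)
  expect_equal(y$name, "PC-YOLOv8")
  expect_equal(length(y$graph), length(v$graph))
  expect_equal(y$num_classes, 2)
})
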