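# ---------------------------------------------------------------------------
# Synthetic dish-cell imagery with per-seed germination schedules and VOC
# ground truth, emulating a 16-cell germination dish photographed cell by
# cell every 15 minutes for 48 hours.  Seeds are dark ellipses on a textured
# filter-paper background; a germinated seed grows a white radicle and its
# label flips (once) from not_sprout to sprout.
# ---------------------------------------------------------------------------

#' Scene configuration for a synthetic germination run
#'
#' @param cells number of dish cells imaged per timepoint (default 16; cell
#'   ids double as the dish ids used for stratified splitting)
#' @param seeds_per_cell seeds sown per cell (default 20, i.e. 320 per run)
#' @param image_size square frame side in pixels
#' @param interval_h capture interval in hours (default 0.25 = 15 min)
#' @param duration_h experiment duration (default 48; frames are captured at
#'   0, interval, ..., duration - interval)
#' @param seed RNG seed fixing seed positions and schedules
#' @return a `scene_config`
#' @export
scene_config <- function(cells = 16L, seeds_per_cell = 20L, image_size = 640L,
                         interval_h = 0.25, duration_h = 48, seed = 1L) {
  stopifnot(cells >= 1, seeds_per_cell >= 1, image_size >= 64,
            interval_h > 0, duration_h > 0)
  structure(list(cells = as.integer(cells),
                 seeds_per_cell = as.integer(seeds_per_cell),
                 image_size = as.integer(image_size),
                 interval_h = interval_h, duration_h = duration_h,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Capture times of a run
#'
#' Frame timestamps in hours: 0, interval, ..., duration - interval (the
#' default 0.25 h interval over 48 h gives 192 timepoints).
#' @param config a `scene_config`
#' @return numeric vector of hours
#' @export
capture_times <- function(config) {
  seq(0, config$duration_h - config$interval_h, by = config$interval_h)
}

# Dose-response parameters of the schedule family: log-normal germination
# times whose median is delayed by NaCl and modulated by a unimodal
# (hormesis) ZnO factor; per-seed Bernoulli non-germination with probability
# increasing in NaCl and relieved at moderate ZnO.
schedule_params <- function() {
  list(t0 = 20,          # baseline median germination time (h), unstressed
       sigma_log = 0.25, # log-time spread
       salt_delay = 0.5, # log-median shift at 120 mmol/L NaCl
       zno_speed = 0.3,  # log-median speed-up at the ZnO optimum
       zno_slow = 0.3,   # log-median slow-down at 800 mg/L
       zno_opt = 400,    # hormesis optimum (mg/L)
       base_logit = stats::qlogis(0.975),  # unstressed germination prob.
       salt_logit = 4.28,                  # logit drop at full salt stress
       relief_max = 0.5)                   # max stress relief from ZnO
}

hormesis_factor <- function(zno, opt, h) {
  ifelse(zno <= 0, 0, h * (zno / opt) * exp(1 - zno / opt))
}

#' Sample a per-seed germination schedule
#'
#' @param config a `scene_config`
#' @param treatment treatment code from [treatment_grid()] (e.g. "CK", "A",
#'   "BT2") or a list/row with `nacl` and `zno`
#' @param seed RNG seed (defaults to the scene seed)
#' @return a `germination_schedule`: per-seed germination times in hours
#'   (`Inf` = never germinates) for `cells * seeds_per_cell` seeds, plus the
#'   treatment covariates
#' @export
sample_schedule <- function(config, treatment = "CK", seed = config$seed) {
  grid <- treatment_grid()
  if (is.character(treatment)) {
    row <- grid[grid$treatment == treatment, ]
    if (nrow(row) != 1)
      stop("unknown treatment '", treatment, "'; valid codes: ",
           paste(grid$treatment, collapse = ", "))
  } else row <- as.data.frame(treatment)
  p <- schedule_params()
  s <- row$nacl / 120
  relief <- hormesis_factor(row$zno, p$zno_opt, p$relief_max)
  p_germ <- stats::plogis(p$base_logit - p$salt_logit * s * (1 - relief))
  log_med <- log(p$t0) + p$salt_delay * s - p$zno_speed * relief +
    p$zno_slow * (row$zno / 800)^2
  n <- config$cells * config$seeds_per_cell
  set.seed(seed)
  germinates <- stats::runif(n) < p_germ
  times <- exp(stats::rnorm(n, log_med, p$sigma_log))
  times[!germinates] <- Inf
  structure(list(times = times, treatment = row$treatment %||% "custom",
                 nacl = row$nacl, zno = row$zno, p_germ = p_germ,
                 median_time = exp(log_med)),
            class = "germination_schedule")
}

# Deterministic seed layout for one cell: non-overlapping ellipse centres
# with a minimum separation, fully inside the frame.
cell_layout <- function(config, cell_id) {
  set.seed(config$seed * 1000L + cell_id)
  S <- config$image_size
  r_seed <- round(S * 0.022)            # seed semi-major axis (px)
  margin <- 4 * r_seed
  min_dist <- 3.2 * r_seed
  n <- config$seeds_per_cell
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0
  while (length(xs) < n && tries < 20000) {
    tries <- tries + 1
    x <- stats::runif(1, margin, S - margin)
    y <- stats::runif(1, margin, S - margin)
    if (!length(xs) || all((xs - x)^2 + (ys - y)^2 >= min_dist^2)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  if (length(xs) < n)
    stop("could not place ", n, " non-overlapping seeds; enlarge the frame")
  data.frame(x = xs, y = ys,
             a = r_seed * stats::runif(n, 0.9, 1.1),
             b = r_seed * stats::runif(n, 0.62, 0.78),
             theta = stats::runif(n, 0, pi),
             dir = stats::runif(n, 0, 2 * pi),
             shade = stats::runif(n, 0.22, 0.38))
}

radicle_points <- function(seed_row, t_since, S) {
  # white radicle growing from the seed tip; reaches full length in ~12 h
  len <- min(34, 4 + 30 * t_since / 12) * S / 640
  steps <- seq(0, 1, length.out = max(6, round(len / 1.5)))
  bend <- 0.35
  ang <- seed_row$dir + bend * steps
  x0 <- seed_row$x + cos(seed_row$dir) * seed_row$a * 0.9
  y0 <- seed_row$y + sin(seed_row$dir) * seed_row$a * 0.9
  data.frame(x = x0 + cumsum(c(0, diff(steps)) * len * cos(ang)),
             y = y0 + cumsum(c(0, diff(steps)) * len * sin(ang)))
}

#' Render one synthetic frame with its ground truth
#'
#' @param config a `scene_config`
#' @param schedule a `germination_schedule` (from [sample_schedule()])
#' @param cell_id cell to render (1-based)
#' @param t capture time in hours (within the run duration)
#' @param image_id identifier for the annotation record
#' @return list with `image` (H, W, 3 array in `[0, 1]`) and `record`
#'   (an `annotation_record`)
#' @export
render_frame <- function(config, schedule, cell_id, t,
                         image_id = sprintf("c%02d_t%05.2f", cell_id, t)) {
  if (t < 0 || t > config$duration_h)
    stop("t outside the run duration")
  S <- config$image_size
  lay <- cell_layout(config, cell_id)
  idx0 <- (cell_id - 1L) * config$seeds_per_cell
  times <- schedule$times[idx0 + seq_len(config$seeds_per_cell)]

  # filter-paper texture: smooth low-amplitude noise (deterministic)
  set.seed(config$seed * 7919L + cell_id)
  coarse <- matrix(stats::runif(17 * 17, -1, 1), 17, 17)
  gx <- seq(1, 17, length.out = S)
  fx <- floor(gx); cx <- pmin(fx + 1, 17); wx <- gx - fx
  bg_rows <- coarse[fx, ] * (1 - wx) + coarse[cx, ] * wx
  bg <- bg_rows[, fx] * rep(1 - wx, each = S) + bg_rows[, cx] * rep(wx, each = S)
  img <- 0.82 + 0.05 * bg + matrix(stats::rnorm(S * S, 0, 0.01), S, S)

  boxes <- data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), label = character(0),
                      stringsAsFactors = FALSE)
  xs <- matrix(rep(seq_len(S), each = 1), nrow = 1)
  for (i in seq_len(nrow(lay))) {
    sd_ <- lay[i, ]
    germ <- t >= times[i]
    # ellipse raster in a local window
    r <- ceiling(sd_$a) + 2L
    xr <- max(1L, floor(sd_$x - r)):min(S, ceiling(sd_$x + r))
    yr <- max(1L, floor(sd_$y - r)):min(S, ceiling(sd_$y + r))
    dx <- outer(rep(1, length(yr)), xr - sd_$x)
    dy <- outer(yr - sd_$y, rep(1, length(xr)))
    u <- dx * cos(sd_$theta) + dy * sin(sd_$theta)
    v <- -dx * sin(sd_$theta) + dy * cos(sd_$theta)
    mask <- (u / sd_$a)^2 + (v / sd_$b)^2 <= 1
    win <- img[yr, xr]
    win[mask] <- sd_$shade + 0.03 * bg[yr, xr][mask]
    img[yr, xr] <- win
    x1 <- sd_$x - sd_$a - 2; x2 <- sd_$x + sd_$a + 2
    y1 <- sd_$y - sd_$a - 2; y2 <- sd_$y + sd_$a + 2
    if (germ) {
      pts <- radicle_points(sd_, t - times[i], S)
      rw <- max(1L, round(1.5 * S / 640))
      for (k in seq_len(nrow(pts))) {
        px <- round(pts$x[k]); py <- round(pts$y[k])
        xr2 <- max(1L, px - rw):min(S, px + rw)
        yr2 <- max(1L, py - rw):min(S, py + rw)
        img[yr2, xr2] <- 0.97
      }
      x1 <- min(x1, min(pts$x) - rw); x2 <- max(x2, max(pts$x) + rw)
      y1 <- min(y1, min(pts$y) - rw); y2 <- max(y2, max(pts$y) + rw)
    }
    boxes <- rbind(boxes, data.frame(
      x1 = max(0, floor(x1)), y1 = max(0, floor(y1)),
      x2 = min(S, ceiling(x2)), y2 = min(S, ceiling(y2)),
      label = if (germ) "sprout" else "not_sprout",
      stringsAsFactors = FALSE))
  }
  img <- pmin(pmax(img, 0), 1)
  rgb <- array(0, dim = c(S, S, 3))
  rgb[, , 1] <- img; rgb[, , 2] <- img * 0.98; rgb[, , 3] <- img * 0.92
  rec <- annotation_record(image_id, dish_id = cell_id, cell_id = cell_id,
                           timestamp_h = t, boxes = boxes, width = S,
                           height = S)
  list(image = rgb, record = rec)
}

#' Generate a full synthetic run on disk
#'
#' One frame per cell per capture time: VOC XML ground truth, a manifest CSV
#' (`image, dish, cell, timestamp_h, treatment`) and, when `render = "png"`,
#' the rasterised frames.  The default configuration (16 cells, 15-minute
#' interval, 48 h) yields 16 x 192 = 3072 frames.  Annotation-only mode
#' (`render = "none"`) writes the same records and manifest without pixels;
#' the frames can be rasterised later with [render_frame()].
#'
#' @param config a `scene_config`
#' @param out_dir output directory (must be empty or absent unless `force`)
#' @param treatment treatment code applied to the whole run
#' @param render "png" or "none"
#' @param force overwrite a non-empty directory
#' @return invisibly, the manifest data.frame (one row per frame)
#' @export
generate_run <- function(config, out_dir, treatment = "CK",
                         render = c("png", "none"), force = FALSE) {
  render <- match.arg(render)
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force)
    stop("output directory is not empty (use force = TRUE to overwrite)")
  dir.create(file.path(out_dir, "annotations"), recursive = TRUE,
             showWarnings = FALSE)
  if (render == "png")
    dir.create(file.path(out_dir, "images"), showWarnings = FALSE)
  schedule <- sample_schedule(config, treatment)
  times <- capture_times(config)
  rows <- vector("list", config$cells * length(times))
  k <- 0L
  for (cell in seq_len(config$cells)) {
    for (t in times) {
      k <- k + 1L
      id <- sprintf("d%02d_t%06.2f", cell, t)
      fr <- render_frame(config, schedule, cell, t, image_id = id)
      write_voc_xml(fr$record,
                    file.path(out_dir, "annotations", paste0(id, ".xml")))
      if (render == "png")
        png::writePNG(fr$image,
                      file.path(out_dir, "images", paste0(id, ".png")))
      rows[[k]] <- data.frame(image_id = id, dish_id = cell, cell_id = cell,
                              timestamp_h = t, treatment = treatment,
                              n_sprout = sum(fr$record$boxes$label == "sprout"),
                              n_total = nrow(fr$record$boxes),
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
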