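# ---------------------------------------------------------------------------
# Germination vitality indices over the NaCl x ZnO NPs treatment grid:
# germination rate (cumulative fraction), germination energy (fraction by the
# 32 h cutoff) and germination index (sum of newly-germinated counts divided
# by elapsed culture time), with replicate aggregation in time windows.
# ---------------------------------------------------------------------------

#' The 5 x 5 treatment grid
#'
#' NaCl 0/30/60/90/120 mmol/L crossed with ZnO NPs 0/200/400/600/800 mg/L,
#' with the conventional treatment codes (CK, A-D for ZnO; T1-T4 for NaCl).
#' @return data.frame with columns treatment, nacl, zno
#' @export
treatment_grid <- function() {
  nacl <- c(0, 30, 60, 90, 120)
  zno <- c(0, 200, 400, 600, 800)
  nacl_code <- c("", "T1", "T2", "T3", "T4")
  zno_code <- c("CK", "A", "B", "C", "D")
  g <- expand.grid(nacl = nacl, zno = zno, KEEP.OUT.ATTRS = FALSE)
  code <- mapply(function(n, z) {
    nz <- zno_code[match(z, zno)]
    nn <- nacl_code[match(n, nacl)]
    if (nn == "") nz else if (nz == "CK") nn else paste0(nz, nn)
  }, g$nacl, g$zno)
  data.frame(treatment = code, nacl = g$nacl, zno = g$zno,
             stringsAsFactors = FALSE)
}

#' Germination rate
#'
#' Cumulative germinated fraction, `N_t / N * 100` per cent.
#' @param n_t cumulative germinated count(s) at time t
#' @param n total number of tested seeds (> 0)
#' @return percentage(s)
#' @export
germination_rate <- function(n_t, n) {
  if (any(n <= 0)) stop("total seed count N must be positive")
  if (any(n_t < 0 | n_t > n)) stop("N_t must lie in [0, N]")
  100 * n_t / n
}

#' Germination energy (germination potential)
#'
#' Fraction of seeds germinated within the first `cutoff_hours` (32 h by
#' default), `N_32 / N * 100` per cent, taken at the last observation at or
#' before the cutoff.
#'
#' @param obs observation data.frame with columns `time_h` and cumulative
#'   `germinated` for one cell, and `total`
#' @param cutoff_hours energy cutoff
#' @return percentage
#' @export
germination_energy <- function(obs, cutoff_hours = 32) {
  if (max(obs$time_h) < cutoff_hours)
    stop("series ends before the ", cutoff_hours, " h cutoff")
  at <- obs[obs$time_h <= cutoff_hours, , drop = FALSE]
  n32 <- if (nrow(at)) at$germinated[which.max(at$time_h)] else 0
  germination_rate(n32, obs$total[1])
}

#' Germination index
#'
#' `sum_t G_t / D_t` where `G_t` is the number of seeds newly germinated in
#' the interval ending at culture time `D_t` (hours since sowing).  Earlier
#' germination weighs more; the index of a schedule never decreases when any
#' germination event is shifted earlier.
#'
#' @param obs observation data.frame with strictly increasing `time_h` and
#'   cumulative `germinated`
#' @return index value (non-negative)
#' @export
germination_index <- function(obs) {
  t <- obs$time_h
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  g <- diff(c(0, obs$germinated))
  if (any(g < 0)) stop("cumulative germinated count must be non-decreasing")
  if (any(t == 0 & g > 0)) stop("germination event at culture time zero")
  keep <- g > 0
  sum(g[keep] / t[keep])
}

#' Per-treatment vitality series with replicate aggregation
#'
#' Computes rate/energy/index trajectories per replicate and aggregates them
#' across replicates within consecutive time windows (default 3.75 h, i.e.
#' 15 capture intervals), reporting the windowed mean and standard deviation
#' of the germination rate plus the final-window summaries.
#'
#' @param obs observation data.frame with columns `treatment`, `replicate`,
#'   `cell`, `time_h`, `germinated` (cumulative per cell), `total`
#' @param window_hours aggregation window width
#' @param energy_cutoff_hours cutoff for germination energy
#' @return a `vitality_series` list: `windows` (per-treatment windowed
#'   statistics), `summary` (one row per treatment), `replicates`
#' @export
vitality_series <- function(obs, window_hours = 3.75,
                            energy_cutoff_hours = 32) {
  stopifnot(all(c("treatment", "replicate", "time_h", "germinated",
                  "total") %in% names(obs)))
  if (!"cell" %in% names(obs)) obs$cell <- 1L
  # per replicate (pooled over its cells): cumulative counts over time
  rep_series <- do.call(rbind, lapply(
    split(obs, list(obs$treatment, obs$replicate), drop = TRUE),
    function(d) {
      tot <- sum(vapply(split(d, d$cell), function(x) x$total[1], 1))
      agg <- stats::aggregate(germinated ~ time_h, data = d, FUN = sum)
      agg <- agg[order(agg$time_h), ]
      data.frame(treatment = d$treatment[1], replicate = d$replicate[1],
                 time_h = agg$time_h, germinated = agg$germinated,
                 total = tot, rate = germination_rate(agg$germinated, tot),
                 stringsAsFactors = FALSE)
    }))
  rownames(rep_series) <- NULL
  # replicate totals may differ (flagged frames excluded): weighted mean rate
  win <- do.call(rbind, lapply(split(rep_series, rep_series$treatment),
    function(d) {
      wid <- ceiling(d$time_h / window_hours - 1e-9)
      do.call(rbind, lapply(split(d, wid), function(x) {
        per_rep <- vapply(split(x, x$replicate), function(r)
          r$rate[which.max(r$time_h)], 1)
        data.frame(treatment = x$treatment[1],
                   window_start = (max(x$time_h[1] %/% window_hours, 0)) * 0 +
                     min(x$time_h),
                   window_end = max(x$time_h),
                   rate_mean = mean(per_rep),
                   rate_sd = stats::sd(per_rep),
                   n_rep = length(per_rep), stringsAsFactors = FALSE)
      }))
    }))
  rownames(win) <- NULL
  summary <- do.call(rbind, lapply(split(rep_series, rep_series$treatment),
    function(d) {
      reps <- split(d, d$replicate)
      energy <- vapply(reps, function(r)
        germination_energy(r, energy_cutoff_hours), 1)
      index <- vapply(reps, germination_index, 1)
      final_rate <- vapply(reps, function(r) r$rate[which.max(r$time_h)], 1)
      data.frame(treatment = d$treatment[1],
                 final_rate = mean(final_rate),
                 final_rate_sd = stats::sd(final_rate),
                 energy = mean(energy), energy_sd = stats::sd(energy),
                 index = mean(index), index_sd = stats::sd(index),
                 n_rep = length(reps), stringsAsFactors = FALSE)
    }))
  rownames(summary) <- NULL
  structure(list(windows = win, summary = summary, replicates = rep_series,
                 window_hours = window_hours,
                 energy_cutoff_hours = energy_cutoff_hours),
            class = "vitality_series")
}

#' @export
print.vitality_series <- function(x, ...) {
  cat(sprintf("vitality series: %d treatment(s), %.2f h windows, energy cutoff %g h\n",
              nrow(x$summary), x$window_hours, x$energy_cutoff_hours))
  print(x$summary, digits = 4)
  invisible(x)
}

#' @export
plot.vitality_series <- function(x, treatments = NULL, ...) {
  d <- x$replicates
  if (!is.null(treatments)) d <- d[d$treatment %in% treatments, ]
  trs <- unique(d$treatment)
  cols <- grDevices::hcl.colors(max(3, length(trs)), "Dark 3")
  graphics::plot(NULL, xlim = range(d$time_h), ylim = c(0, 100),
                 xlab = "culture time (h)", ylab = "germination rate (%)", ...)
  for (i in seq_along(trs)) {
    di <- d[d$treatment == trs[i], ]
    for (r in unique(di$replicate)) {
      dr <- di[di$replicate == r, ]
      graphics::lines(dr$time_h, dr$rate, col = cols[i], lwd = 1)
    }
  }
  graphics::legend("topleft", legend = trs, col = cols[seq_along(trs)],
                   lwd = 2, bty = "n", cex = 0.8)
  invisible(x)
}

#' Germination observations from per-image detections
#'
#' Bridges detector output to the vitality indices: per image, `N` is the
#' total box count (sprout + not-sprout) and the germinated count is the
#' sprout count.  Because detection counts can dip transiently, the
#' cumulative germinated count is monotonised by a running maximum over
#' time within each cell.  Images with zero boxes are flagged and excluded.
#'
#' @param det_frames data.frame with one row per image: `treatment`,
#'   `replicate`, `cell`, `time_h`, `n_sprout`, `n_total`
#' @return observation data.frame as consumed by [vitality_series()], with
#'   attribute `flagged` (excluded zero-box frames)
#' @export
counts_from_detections <- function(det_frames) {
  flagged <- det_frames[det_frames$n_total == 0, , drop = FALSE]
  d <- det_frames[det_frames$n_total > 0, , drop = FALSE]
  out <- do.call(rbind, lapply(
    split(d, list(d$treatment, d$replicate, d$cell), drop = TRUE),
    function(x) {
      x <- x[order(x$time_h), ]
      data.frame(treatment = x$treatment[1], replicate = x$replicate[1],
                 cell = x$cell[1], time_h = x$time_h,
                 germinated = cummax(x$n_sprout),
                 total = max(x$n_total), stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  attr(out, "flagged") <- flagged
  out
}
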