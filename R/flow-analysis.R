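#' ROI-mean velocity waveform
#'
#' @param vel A [velocity_series()].
#' @param roi A [roi_mask()] on the same grid.
#' @return A [flow_waveform()] of the per-frame ROI-mean velocity (cm/s),
#'   with times in seconds.
#' @export
roi_mean_waveform <- function(vel, roi) {
  if (!same_grid(vel$grid, roi$grid)) {
    stop_validation("velocity series and ROI must share one grid")
  }
  sel <- as.vector(roi$mask)
  if (!any(sel)) stop_validation("empty ROI")
  flow_waveform(vel$frame_times_ms / 1000,
                colMeans(vel$data[sel, , drop = FALSE]),
                quantity = "mean_velocity")
}

#' Segment a waveform into cardiac cycles
#'
#' Detects cycle starts at upward crossings of a threshold (a fraction of
#' the global maximum) separated by at least a refractory period, and
#' returns half-open frame intervals `[start, end)` between consecutive
#' starts. The trailing partial cycle is discarded; cycles spanning fewer
#' than 3 frames are dropped.
#'
#' @param wave A [flow_waveform()].
#' @param min_period_s Minimum allowed cycle duration (refractory period).
#' @param threshold_frac Crossing threshold as a fraction of the global max.
#' @return A tibble of class `beat_segmentation` with columns `cycle`,
#'   `start`, `end` (1-based frame indices, end exclusive), `t_start_s`,
#'   `t_end_s`, `duration_s`. Empty (zero rows) when no crossings exist.
#' @export
segment_beats <- function(wave, min_period_s = 0.4, threshold_frac = 0.3) {
  v <- wave$value; t <- wave$time_s
  if (length(v) < 3L) stop_validation("waveform must have at least 3 samples")
  thr <- threshold_frac * max(v)
  up <- which(v[-1] >= thr & v[-length(v)] < thr) + 1L
  starts <- integer(0)
  last_t <- -Inf
  for (i in up) {
    if (t[i] - last_t >= min_period_s) {
      starts <- c(starts, i)
      last_t <- t[i]
    }
  }
  if (length(starts) < 2L) {
    seg <- tibble(cycle = integer(0), start = integer(0), end = integer(0),
                  t_start_s = numeric(0), t_end_s = numeric(0),
                  duration_s = numeric(0))
  } else {
    s <- head(starts, -1L); e <- tail(starts, -1L)
    keep <- (e - s) >= 3L
    s <- s[keep]; e <- e[keep]
    seg <- tibble(cycle = seq_along(s), start = s, end = e,
                  t_start_s = t[s], t_end_s = t[e],
                  duration_s = t[e] - t[s])
  }
  class(seg) <- c("beat_segmentation", class(seg))
  attr(seg, "n_frames") <- length(v)
  seg
}

#' Average segmented cycles into one synthetic cardiac cycle
#'
#' Each cycle is resampled by linear interpolation onto `n_points` uniformly
#' spaced points in normalised cycle time, then averaged pointwise; cycles
#' of different durations are thereby aligned before averaging. The output
#' spans the mean cycle duration.
#'
#' @param wave A [flow_waveform()].
#' @param seg A nonempty `beat_segmentation` from [segment_beats()].
#' @param n_points Samples of the synthetic cycle.
#' @return A [flow_waveform()] of one averaged cycle.
#' @export
average_cycles <- function(wave, seg, n_points = 64L) {
  if (nrow(seg) == 0L) stop_validation("beat segmentation is empty")
  u <- seq(0, 1, length.out = n_points)
  curves <- list()
  for (i in seq_len(nrow(seg))) {
    if (seg$end[i] - seg$start[i] < 2L) {
      warn(sprintf("cycle %d shorter than 2 frames; skipped", seg$cycle[i]))
      next
    }
    tt <- seg$t_start_s[i] + u * (seg$t_end_s[i] - seg$t_start_s[i])
    curves[[length(curves) + 1L]] <-
      approx(wave$time_s, wave$value, xout = tt, rule = 2)$y
  }
  if (!length(curves)) stop_validation("no usable cycles to average")
  avg <- Reduce(`+`, curves) / length(curves)
  dur <- mean(seg$duration_s)
  flow_waveform(u * dur, avg, quantity = waveform_quantity(wave),
                period_s = dur)
}

#' Peak velocity, per cycle or overall
#'
#' The maximum of the waveform within each cardiac cycle (or over the whole
#' record when no segmentation is given).
#'
#' @param wave A [flow_waveform()].
#' @param seg Optional `beat_segmentation`; `NULL` uses the entire record.
#' @return A scalar (no segmentation) or a tibble `cycle`, `peak` (cm/s),
#'   `t_peak_s`.
#' @export
peak_velocity <- function(wave, seg = NULL) {
  if (is.null(seg)) return(max(wave$value))
  if (nrow(seg) == 0L) stop_validation("beat segmentation is empty")
  out <- lapply(seq_len(nrow(seg)), function(i) {
    idx <- seg$start[i]:(seg$end[i] - 1L)
    j <- idx[which.max(wave$value[idx])]
    tibble(cycle = seg$cycle[i], peak = wave$value[j], t_peak_s = wave$time_s[j])
  })
  dplyr::bind_rows(out)
}

#' Stroke volume over a cardiac cycle
#'
#' Integrates the volumetric flow through the ROI over one cycle:
#' `sum over frames of [sum over ROI pixels of v (cm/s)] * pixel_area (cm^2)
#' * dt (s)`, in mL. The ROI area is static (no per-frame lumen tracking).
#'
#' @param vel A [velocity_series()].
#' @param roi A [roi_mask()] of the vessel lumen.
#' @param cycle Either a length-2 vector `c(start, end)` of 1-based frame
#'   indices (end exclusive) or a `beat_segmentation` (one volume per row).
#' @return Stroke volume in mL (scalar, or tibble `cycle`, `volume_ml`).
#' @export
stroke_volume <- function(vel, roi, cycle) {
  if (!same_grid(vel$grid, roi$grid)) {
    stop_validation("velocity series and ROI must share one grid")
  }
  if (inherits(cycle, "beat_segmentation")) {
    seg <- cycle
    return(dplyr::bind_rows(lapply(seq_len(nrow(seg)), function(i) {
      tibble(cycle = seg$cycle[i],
             volume_ml = stroke_volume(vel, roi, c(seg$start[i], seg$end[i])))
    })))
  }
  start <- cycle[1]; end <- cycle[2]
  if (start < 1L || end > ncol(vel$data) + 1L || end <= start) {
    stop_validation("cycle interval outside the series")
  }
  dt_s <- median(diff(vel$frame_times_ms)) / 1000
  area_cm2 <- pixel_area(vel$grid, "cm2")
  sel <- as.vector(roi$mask)
  frames <- start:(end - 1L)
  flow_ml_s <- colSums(vel$data[sel, frames, drop = FALSE]) * area_cm2
  sum(flow_ml_s) * dt_s
}

#' Fold a waveform into one assumed cardiac cycle
#'
#' Desk-scale surrogate for retrospective ECG gating: time stamps are
#' reduced modulo the assumed period and samples are bin-averaged into a
#' single cycle. For truly periodic flow this reproduces one cycle; for
#' aperiodic flow (e.g. alternating bells) the folded cycle averages
#' unrelated beats and reports erroneous peak flow.
#'
#' @param wave A [flow_waveform()] covering at least one assumed period.
#' @param assumed_period_s Assumed cardiac period in seconds.
#' @param n_bins Number of phase bins; defaults to the assumed period over
#'   the median sampling interval.
#' @return A [flow_waveform()] of the folded cycle.
#' @export
fold_to_cycle <- function(wave, assumed_period_s, n_bins = NULL) {
  if (diff(range(wave$time_s)) < assumed_period_s) {
    stop_validation("record shorter than the assumed period")
  }
  if (is.null(n_bins)) {
    n_bins <- max(3L, round(assumed_period_s / median(diff(wave$time_s))))
  }
  phase <- (wave$time_s %% assumed_period_s) / assumed_period_s
  # epsilon guards samples sitting exactly on bin edges against FP jitter
  bin <- pmin(floor(phase * n_bins + 1e-9), n_bins - 1L)
  means <- vapply(split(wave$value, factor(bin, levels = 0:(n_bins - 1L))),
                  function(v) if (length(v)) mean(v) else NA_real_, numeric(1))
  centres <- (seq_len(n_bins) - 0.5) / n_bins * assumed_period_s
  keep <- !is.na(means)
  flow_waveform(centres[keep], means[keep], quantity = waveform_quantity(wave),
                period_s = assumed_period_s)
}

#' Signal-to-noise ratio of a magnitude frame
#'
#' Mean magnitude over the ROI divided by the standard deviation of the
#' magnitude over a background (noise-only) region.
#'
#' @param series An [image_series()].
#' @param frame Frame index.
#' @param roi Signal [roi_mask()].
#' @param background Background [roi_mask()], disjoint from `roi`.
#' @return The SNR (scalar); `Inf` with a warning if the background is
#'   degenerate (zero variance).
#' @export
snr <- function(series, frame, roi, background) {
  if (any(roi$mask & background$mask)) {
    stop_validation("ROI and background masks must be disjoint")
  }
  img <- Mod(series_frame(series, frame))
  s <- mean(img[roi$mask])
  n <- sd(img[background$mask])
  if (n == 0) {
    warn("background standard deviation is zero; SNR is degenerate")
    return(Inf)
  }
  s / n
}

#' Velocity-to-noise ratio of a velocity frame
#'
#' Mean velocity over the ROI divided by the standard deviation of the
#' velocity over a static-tissue region.
#'
#' @param vel A [velocity_series()].
#' @param frame Frame index.
#' @param roi Vessel [roi_mask()].
#' @param static Static-tissue [roi_mask()], disjoint from `roi`.
#' @return The VNR (scalar); `Inf` with a warning when degenerate.
#' @export
vnr <- function(vel, frame, roi, static) {
  if (any(roi$mask & static$mask)) {
    stop_validation("ROI and static masks must be disjoint")
  }
  img <- series_frame(vel, frame)
  s <- mean(img[roi$mask])
  n <- sd(img[static$mask])
  if (n == 0) {
    warn("static-tissue standard deviation is zero; VNR is degenerate")
    return(Inf)
  }
  s / n
}

#' Bland-Altman agreement analysis with paired t-test
#'
#' For paired measurements `a` and `b` (e.g. per-subject peak velocities
#' from two methods): differences `d = a - b`, bias `mean(d)`, limits of
#' agreement `bias +- 1.96 * sd(d)`, Pearson correlation of `a` and `b`,
#' and the paired Student t statistic `bias / (sd(d)/sqrt(n))` with a
#' two-sided p-value on `n - 1` degrees of freedom.
#'
#' @param a,b Numeric vectors of equal length `n >= 2`.
#' @return An object of class `bland_altman`; see also [tidy()] and
#'   [glance()] methods and `autoplot()`.
#' @export
bland_altman <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop_validation("`a` and `b` must have equal length")
  n <- length(a)
  if (n < 2L) stop_validation("need at least 2 paired values")
  d <- a - b
  bias <- mean(d)
  sdd <- sd(d)
  r <- if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)
  if (sdd == 0) {
    t_stat <- if (bias == 0) NA_real_ else Inf * sign(bias)
    p <- if (bias == 0) NA_real_ else 0
  } else {
    t_stat <- bias / (sdd / sqrt(n))
    p <- 2 * pt(-abs(t_stat), df = n - 1)
  }
  structure(list(bias = bias, sd_diff = sdd,
                 loa_lower = bias - 1.96 * sdd, loa_upper = bias + 1.96 * sdd,
                 pearson_r = r, t_stat = t_stat, p_value = p, n = n,
                 data = tibble(a = a, b = b, mean = (a + b) / 2, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d\n  bias %.4g [LoA %.4g, %.4g]\n", x$n,
              x$bias, x$loa_lower, x$loa_upper))
  cat(sprintf("  Pearson r = %.3f, paired t = %.3f (p = %.3g)\n",
              x$pearson_r, x$t_stat, x$p_value))
  invisible(x)
}

#' @describeIn bland_altman Estimates as a tidy tibble (bias, limits of
#'   agreement, correlation, t statistic).
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.bland_altman <- function(x, ...) {
  tibble(term = c("bias", "loa_lower", "loa_upper", "sd_diff", "pearson_r",
                  "t_statistic", "p_value"),
         estimate = c(x$bias, x$loa_lower, x$loa_upper, x$sd_diff,
                      x$pearson_r, x$t_stat, x$p_value))
}

#' @describeIn bland_altman One-row model summary.
#' @exportS3Method generics::glance
glance.bland_altman <- function(x, ...) {
  tibble(bias = x$bias, loa_lower = x$loa_lower, loa_upper = x$loa_upper,
         pearson_r = x$pearson_r, t_statistic = x$t_stat,
         p_value = x$p_value, n = x$n)
}
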