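#' Pulsatile waveform specification
#'
#' Two programmable-pump style waveforms plus a custom pass-through:
#' * kind `"I"` — periodic (default 2 s period): a 1 s raised-cosine
#'   ("bell") lobe rising from the baseline to `peak`, followed by constant
#'   baseline flow for the remainder of the period.
#' * kind `"II"` — default 4 s period containing two different 1 s bells
#'   (the second with peak `second_peak_ratio * peak`) separated by
#'   constant baseline segments; an aperiodic-looking flow for any gating
#'   scheme that assumes a shorter cycle.
#' * kind `"custom"` — user-supplied samples.
#'
#' @param kind `"I"`, `"II"` or `"custom"`.
#' @param period_s Repetition period in seconds (> 0). Defaults to 2 for
#'   kind I and 4 for kind II.
#' @param peak_cm_s Peak (centreline) velocity of the first bell, cm/s.
#' @param baseline_cm_s Constant-flow velocity between bells, cm/s.
#' @param dt_s Sample interval in seconds.
#' @param second_peak_ratio Kind II only: second-bell peak as a fraction of
#'   the first.
#' @param samples Kind `"custom"` only: a [flow_waveform()] to pass through.
#' @return An object of class `waveform_spec`.
#' @export
waveform_spec <- function(kind = c("I", "II", "custom"),
                          period_s = NULL, peak_cm_s = 80,
                          baseline_cm_s = 10, dt_s = 0.02,
                          second_peak_ratio = 0.6, samples = NULL) {
  kind <- match.arg(kind)
  if (is.null(period_s)) period_s <- switch(kind, I = 2, II = 4, custom = NA_real_)
  if (kind != "custom") {
    if (!is.finite(period_s) || period_s <= 0) {
      stop_validation("`period_s` must be > 0")
    }
    if (period_s < 1) stop_validation("the 1 s bell does not fit a period < 1 s")
    if (dt_s <= 0) stop_validation("`dt_s` must be > 0")
  } else if (is.null(samples)) {
    stop_validation("kind 'custom' requires `samples`")
  }
  structure(list(kind = kind, period_s = period_s, peak_cm_s = peak_cm_s,
                 baseline_cm_s = baseline_cm_s, dt_s = dt_s,
                 second_peak_ratio = second_peak_ratio, samples = samples),
            class = "waveform_spec")
}

# analytic waveform value at times t (seconds)
waveform_value <- function(spec, t_s) {
  tt <- t_s %% spec$period_s
  base <- spec$baseline_cm_s
  v <- rep(base, length(tt))
  in_bell1 <- tt < 1
  v[in_bell1] <- base + (spec$peak_cm_s - base) * sin(pi * tt[in_bell1])^2
  if (spec$kind == "II") {
    t2 <- spec$period_s / 2
    in_bell2 <- tt >= t2 & tt < t2 + 1
    peak2 <- spec$second_peak_ratio * spec$peak_cm_s
    v[in_bell2] <- base + (peak2 - base) * sin(pi * (tt[in_bell2] - t2))^2
  }
  v
}

#' Generate a pulsatile flow waveform
#'
#' Samples the specified waveform on a regular time grid. The raised-cosine
#' bell reaches exactly `peak_cm_s` at its midpoint whenever the sampling
#' grid contains it (the default 0.02 s grid does).
#'
#' @param spec A [waveform_spec()].
#' @param duration_s Length of the generated record in seconds; defaults to
#'   one period.
#' @return A [flow_waveform()] carrying the period as an attribute.
#' @export
make_waveform <- function(spec, duration_s = NULL) {
  stopifnot(inherits(spec, "waveform_spec"))
  if (spec$kind == "custom") return(spec$samples)
  if (is.null(duration_s)) duration_s <- spec$period_s
  t <- seq(0, duration_s - spec$dt_s / 2, by = spec$dt_s)
  flow_waveform(t, waveform_value(spec, t), quantity = "mean_velocity",
                period_s = spec$period_s)
}

# periodic linear interpolation of a sampled waveform
waveform_at <- function(w, t_s) {
  period <- waveform_period(w)
  ts <- w$time_s; vs <- w$value
  if (is.finite(period)) {
    t_s <- t_s %% period
    if (ts[length(ts)] < ts[1] + period) {
      # close the period for interpolation beyond the last sample
      ts <- c(ts, ts[1] + period)
      vs <- c(vs, vs[1])
    }
  }
  approx(ts, vs, xout = t_s, rule = 2)$y
}

#' Digital flow-phantom geometry
#'
#' A circular vessel (through-plane flow) embedded in a static-tissue
#' ellipse, mimicking a plastic tube plugged into a water container.
#'
#' @param grid A [grid2d()].
#' @param center_px Vessel centre in 1-based pixel coordinates `c(x, y)`;
#'   defaults to the grid centre.
#' @param radius_mm Vessel radius in mm (> 0); the default 7.5 corresponds
#'   to a 15-mm-diameter tube.
#' @param tissue_semiaxes_mm Semi-axes of the surrounding static-tissue
#'   ellipse in mm; defaults to 80% of the half field of view.
#' @param tissue_center_px Centre of the tissue ellipse; defaults to the
#'   vessel centre.
#' @return An object of class `phantom_geometry`.
#' @export
phantom_geometry <- function(grid, center_px = NULL, radius_mm = 7.5,
                             tissue_semiaxes_mm = NULL,
                             tissue_center_px = NULL) {
  stopifnot(inherits(grid, "grid2d"))
  if (radius_mm <= 0) stop_validation("`radius_mm` must be > 0")
  if (is.null(center_px)) center_px <- c((grid$nx + 1) / 2, (grid$ny + 1) / 2)
  if (is.null(tissue_center_px)) tissue_center_px <- center_px
  if (is.null(tissue_semiaxes_mm)) {
    tissue_semiaxes_mm <- 0.8 * c(grid$nx * grid$pixel_mm[1],
                                  grid$ny * grid$pixel_mm[2]) / 2
  }
  r_px <- radius_mm / grid$pixel_mm
  if (center_px[1] - r_px[1] < 1 || center_px[1] + r_px[1] > grid$nx ||
      center_px[2] - r_px[2] < 1 || center_px[2] + r_px[2] > grid$ny) {
    stop_validation("vessel must lie entirely inside the grid")
  }
  structure(list(grid = grid, center_px = center_px, radius_mm = radius_mm,
                 tissue_semiaxes_mm = tissue_semiaxes_mm,
                 tissue_center_px = tissue_center_px),
            class = "phantom_geometry")
}

# squared normalised radial distance from the vessel centre (1 at the wall)
vessel_dist2 <- function(geometry) {
  g <- geometry$grid
  x_mm <- (seq_len(g$nx) - geometry$center_px[1]) * g$pixel_mm[1]
  y_mm <- (seq_len(g$ny) - geometry$center_px[2]) * g$pixel_mm[2]
  outer(x_mm^2, y_mm^2, `+`) / geometry$radius_mm^2
}

#' Vessel / static-tissue / background masks of a phantom
#'
#' @param geometry A [phantom_geometry()].
#' @return A [roi_mask()].
#' @export
vessel_mask <- function(geometry) {
  roi_mask(vessel_dist2(geometry) < 1, geometry$grid)
}

tissue_ellipse <- function(geometry) {
  g <- geometry$grid
  x_mm <- (seq_len(g$nx) - geometry$tissue_center_px[1]) * g$pixel_mm[1]
  y_mm <- (seq_len(g$ny) - geometry$tissue_center_px[2]) * g$pixel_mm[2]
  outer((x_mm / geometry$tissue_semiaxes_mm[1])^2,
        (y_mm / geometry$tissue_semiaxes_mm[2])^2, `+`) < 1
}

#' @rdname vessel_mask
#' @param erode_px Shrink the static mask this many pixels away from the
#'   vessel wall and tissue edge (guards against partial-volume pixels).
#' @export
static_tissue_mask <- function(geometry, erode_px = 2) {
  g <- geometry$grid
  pad <- erode_px * max(g$pixel_mm)
  shrunk <- geometry
  shrunk$radius_mm <- geometry$radius_mm + pad
  shrunk$tissue_semiaxes_mm <- pmax(geometry$tissue_semiaxes_mm - pad, 1e-6)
  roi_mask(tissue_ellipse(shrunk) & !(vessel_dist2(shrunk) < 1), g)
}

#' @rdname vessel_mask
#' @param box_px Side length of the corner background box in pixels.
#' @export
background_mask <- function(geometry, box_px = 8) {
  g <- geometry$grid
  m <- matrix(FALSE, g$nx, g$ny)
  m[seq_len(min(box_px, g$nx %/% 4)), seq_len(min(box_px, g$ny %/% 4))] <- TRUE
  roi_mask(m & !tissue_ellipse(geometry) & !(vessel_dist2(geometry) < 1), g)
}

#' Render the ground-truth flow-compensated and flow-encoded series
#'
#' Builds the noiseless discrete image model: magnitude 1 inside the vessel
#' and static tissue, 0 elsewhere; the flow-compensated series (v = 1) has
#' zero phase; the flow-encoded series (v = 2) carries phase
#' `pi * v_true(r, t) / VENC` inside the vessel, where the true velocity is
#' either spatially uniform (`"plug"`) or a paraboloid with centreline equal
#' to the waveform value (`"parabolic"`). An optional polynomial phase
#' offset emulates eddy-current background phase on the encoded series.
#'
#' @param geometry A [phantom_geometry()].
#' @param waveform A [flow_waveform()]; extended periodically via its
#'   period attribute.
#' @param frame_times_ms Frame times at which to render, ms.
#' @param venc_cm_s Encoding velocity; waveform values beyond it trigger an
#'   aliasing warning, not an error.
#' @param profile `"plug"` or `"parabolic"` through-plane velocity profile.
#' @param tissue_contrast Magnitude of static tissue relative to the vessel.
#' @param eddy_coeffs Optional numeric vector `c(c0, cx, cy, cxx, cxy, cyy)`
#'   (shorter vectors allowed) of a background phase polynomial in
#'   normalised coordinates, added to the encoded phase over the whole
#'   support.
#' @return A list of two [image_series()]: `[[1]]` flow-compensated,
#'   `[[2]]` flow-encoded.
#' @export
render_truth <- function(geometry, waveform, frame_times_ms, venc_cm_s,
                         profile = c("plug", "parabolic"),
                         tissue_contrast = 1, eddy_coeffs = NULL) {
  profile <- match.arg(profile)
  g <- geometry$grid
  d2 <- vessel_dist2(geometry)
  vessel <- d2 < 1
  support <- vessel | tissue_ellipse(geometry)
  mag <- matrix(0, g$nx, g$ny)
  mag[tissue_ellipse(geometry)] <- tissue_contrast
  mag[vessel] <- 1
  vals <- waveform_at(waveform, frame_times_ms / 1000)
  if (any(abs(vals) > venc_cm_s)) {
    warn("waveform exceeds VENC: velocities will alias in the encoded phase")
  }
  eddy <- matrix(0, g$nx, g$ny)
  if (!is.null(eddy_coeffs)) {
    eddy <- poly2d_surface(g, eddy_coeffs)
  }
  n <- n_voxels(g); m <- length(frame_times_ms)
  comp <- matrix(complex(real = rep(as.vector(mag), m)), n, m)
  shape <- if (profile == "plug") vessel * 1 else pmax(1 - d2, 0) * vessel
  enc <- matrix(0i, n, m)
  for (j in seq_len(m)) {
    ph <- pi * vals[j] * shape / venc_cm_s + eddy * support
    enc[, j] <- as.vector(mag * exp(1i * ph))
  }
  list(image_series(comp, frame_times_ms, g, venc_cm_s),
       image_series(enc, frame_times_ms, g, venc_cm_s))
}

# 2-D polynomial surface over normalised [-1, 1] coordinates; coefficient
# order: 1, x, y, x^2, x*y, y^2 (truncated to length(coeffs))
poly2d_surface <- function(grid, coeffs) {
  x <- seq(-1, 1, length.out = grid$nx)
  y <- seq(-1, 1, length.out = grid$ny)
  xx <- matrix(x, grid$nx, grid$ny)
  yy <- matrix(y, grid$nx, grid$ny, byrow = TRUE)
  terms <- list(1 + 0 * xx, xx, yy, xx^2, xx * yy, yy^2)
  s <- matrix(0, grid$nx, grid$ny)
  for (i in seq_along(coeffs)) s <- s + coeffs[i] * terms[[i]]
  s
}

#' Smooth synthetic coil sensitivity maps
#'
#' Gaussian-bump coil magnitudes centred at points around the field of
#' view with slowly varying phase, RSS-normalised to 1 everywhere (the
#' support is the full grid). Deterministic for a fixed seed.
#'
#' @param nc Number of coils, >= 1.
#' @param grid A [grid2d()].
#' @param seed Integer seed for the small random placement/phase jitter.
#' @return A [sensitivity_maps()] object.
#' @export
make_sensitivities <- function(nc, grid, seed = 1L) {
  nc <- as.integer(nc)
  if (nc < 1L) stop_validation("`nc` must be >= 1")
  g <- grid
  maps <- withr::with_seed(as.integer(seed), {
    x <- seq(-1, 1, length.out = g$nx)
    y <- seq(-1, 1, length.out = g$ny)
    xx <- matrix(x, g$nx, g$ny)
    yy <- matrix(y, g$nx, g$ny, byrow = TRUE)
    a <- array(0i, c(g$nx, g$ny, nc))
    ang <- 2 * pi * (seq_len(nc) - 1) / nc + rnorm(nc, sd = 0.1)
    sigma <- 0.9
    for (i in seq_len(nc)) {
      cx <- 1.1 * cos(ang[i]); cy <- 1.1 * sin(ang[i])
      magn <- exp(-((xx - cx)^2 + (yy - cy)^2) / (2 * sigma^2)) + 0.05
      ph <- rnorm(1, sd = 0.5) + 0.7 * rnorm(1) * xx + 0.7 * rnorm(1) * yy +
        0.2 * rnorm(1) * xx * yy
      a[, , i] <- magn * exp(1i * ph)
    }
    a
  })
  rss <- sqrt(apply(Mod(maps)^2, c(1, 2), sum))
  for (i in seq_len(nc)) maps[, , i] <- maps[, , i] / rss
  sensitivity_maps(maps, matrix(TRUE, g$nx, g$ny), g)
}

#' Simulate the multi-coil (k,t)-space acquisition
#'
#' The forward model: for every slot of the sampling pattern, the scheduled
#' ky line of the centred unitary 2-D FFT of `S_i * rho_v` — evaluated at
#' the truth frame nearest the slot's time stamp — is recorded for every
#' coil, plus i.i.d. complex Gaussian noise. `noise_sd` is the standard
#' deviation per complex sample; the real and imaginary parts each receive
#' `noise_sd / sqrt(2)`.
#'
#' @param truth List of per-encoding [image_series()] (from [render_truth()]).
#' @param sens A [sensitivity_maps()] object.
#' @param pattern A `sampling_pattern` (its encodings must not exceed
#'   `length(truth)` and its ky indices must fit the grid).
#' @param noise_sd Complex-sample noise standard deviation.
#' @param seed Integer seed for the noise draw.
#' @return A [kt_samples()] container.
#' @export
acquire <- function(truth, sens, pattern, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(sens, "sensitivity_maps"))
  g <- truth[[1]]$grid
  nv <- length(truth)
  if (any(pattern$encoding > nv)) {
    stop_validation("pattern references an encoding not present in `truth`")
  }
  if (any(pattern$ky >= g$ny | pattern$ky < 0)) {
    stop_validation("pattern references ky outside [0, ny)")
  }
  nc <- sens$nc
  ft <- truth[[1]]$frame_times_ms
  # nearest truth frame per slot
  frame_idx <- vapply(pattern$t_ms, function(t) which.min(abs(ft - t)), integer(1))
  key <- paste(pattern$encoding, frame_idx)
  groups <- split(seq_len(nrow(pattern)), key)
  nx <- g$nx
  n_slots <- nrow(pattern)
  sig <- array(0i, c(nx, n_slots, nc))
  for (idx in groups) {
    v <- pattern$encoding[idx[1]]
    m <- frame_idx[idx[1]]
    img <- matrix(truth[[v]]$data[, m], nx, g$ny)
    for (i in seq_len(nc)) {
      k <- ft2c(sens$maps[, , i] * img)
      sig[, idx, i] <- k[, pattern$ky[idx] + 1L]
    }
  }
  if (noise_sd > 0) {
    sig <- sig + withr::with_seed(as.integer(seed), {
      n <- length(sig)
      complex(real = rnorm(n, sd = noise_sd / sqrt(2)),
              imaginary = rnorm(n, sd = noise_sd / sqrt(2)))
    })
  }
  # one row per (slot, coil), slot-major so time stays nondecreasing
  lines <- tibble(
    encoding = rep(pattern$encoding, each = nc),
    coil = rep(seq_len(nc), times = n_slots),
    ky = rep(pattern$ky, each = nc),
    t_ms = rep(pattern$t_ms, each = nc),
    role = rep(pattern$role, each = nc),
    signal = lapply(seq_len(n_slots * nc), function(j) {
      s <- (j - 1L) %/% nc + 1L
      i <- (j - 1L) %% nc + 1L
      sig[, s, i]
    })
  )
  kt_samples(lines, g, nv = nv, nc = nc,
             tr_ms = pattern_attr(pattern, "tr_ms"),
             venc_cm_s = truth[[1]]$venc_cm_s,
             frame_ms = pattern_attr(pattern, "frame_ms"))
}
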