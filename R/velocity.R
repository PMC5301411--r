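#' Phase difference between flow-encoded and flow-compensated series
#'
#' Computes the wrapped phase difference per voxel and frame via the
#' complex product `angle(rho_v * conj(rho_1))` — never by subtracting
#' angles, which double-wraps. Voxels where both magnitudes fall below a
#' relative floor are flagged in a `low_signal` channel (their phase is
#' noise-dominated).
#'
#' @param encoded Flow-encoded [image_series()].
#' @param compensated Flow-compensated [image_series()] on the same grid
#'   and frame times.
#' @param mag_floor Relative magnitude floor for the low-signal flag.
#' @return A [phase_series()] with values in `(-pi, pi]`.
#' @export
phase_difference <- function(encoded, compensated, mag_floor = 0.05) {
  if (!same_grid(encoded$grid, compensated$grid) ||
      ncol(encoded$data) != ncol(compensated$data)) {
    stop_validation("encoded and compensated series must share grid and frames")
  }
  if (max(abs(encoded$frame_times_ms - compensated$frame_times_ms)) > 1e-9) {
    stop_validation("encoded and compensated series must share frame times")
  }
  prod <- encoded$data * Conj(compensated$data)
  pd <- Arg(prod)
  floor_val <- mag_floor * max(Mod(encoded$data), Mod(compensated$data))
  low <- Mod(encoded$data) < floor_val & Mod(compensated$data) < floor_val
  phase_series(pd, encoded$frame_times_ms, encoded$grid, low_signal = low)
}

wrap_phase <- function(x) Arg(exp(1i * x))

#' Polynomial background-phase (eddy-current) correction
#'
#' Eddy currents leave a smooth spatial phase offset that biases velocities.
#' The correction fits a 2-D polynomial (order 0-2) to the temporal-mean
#' phase difference over automatically detected static tissue — voxels with
#' sufficient magnitude and small temporal phase variation — and subtracts
#' the fitted surface from every frame.
#'
#' @param phase A [phase_series()] (phase differences).
#' @param magnitude The matching magnitude [image_series()] used to find
#'   static tissue.
#' @param order Polynomial order: 0 (constant), 1 (planar) or 2.
#' @param mag_threshold Relative magnitude threshold for static tissue.
#' @param std_threshold Maximum temporal phase standard deviation (rad) for
#'   static tissue.
#' @return A list of class `phase_correction`: `$phase` (corrected
#'   [phase_series()]), `$static_mask` ([roi_mask()]), `$coefficients`
#'   (named vector, terms `1, x, y, x^2, x*y, y^2` in normalised
#'   coordinates) and `$surface` (the fitted offset map).
#' @export
background_phase_correction <- function(phase, magnitude, order = 2,
                                        mag_threshold = 0.1,
                                        std_threshold = 0.1) {
  if (!order %in% 0:2) stop_validation("`order` must be 0, 1 or 2")
  g <- phase$grid
  mag_mean <- rowMeans(Mod(magnitude$data))
  if (ncol(phase$data) > 1L) {
    pd_sd <- apply(phase$data, 1, sd)
  } else {
    pd_sd <- rep(0, nrow(phase$data))
  }
  static <- mag_mean > mag_threshold * max(mag_mean) & pd_sd < std_threshold
  n_terms <- c(1L, 3L, 6L)[order + 1L]
  if (sum(static) < n_terms) {
    stop_validation(sprintf(
      "static-tissue mask (%d px) smaller than the %d polynomial coefficients",
      sum(static), n_terms))
  }
  x <- rep(seq(-1, 1, length.out = g$nx), times = g$ny)
  y <- rep(seq(-1, 1, length.out = g$ny), each = g$nx)
  design <- cbind(1, x, y, x^2, x * y, y^2)[, seq_len(n_terms), drop = FALSE]
  target <- rowMeans(phase$data)[static]
  beta <- qr.solve(design[static, , drop = FALSE], target)
  surface <- as.vector(design %*% beta)
  corrected <- wrap_phase(phase$data - surface)
  # Arg() returns values in [-pi, pi]; fold -pi onto +pi to keep (-pi, pi]
  corrected[corrected == -pi] <- pi
  names(beta) <- c("1", "x", "y", "x^2", "x*y", "y^2")[seq_len(n_terms)]
  structure(list(
    phase = phase_series(corrected, phase$frame_times_ms, g,
                         low_signal = phase$low_signal),
    static_mask = roi_mask(matrix(static, g$nx, g$ny), g),
    coefficients = beta,
    surface = matrix(surface, g$nx, g$ny)),
    class = "phase_correction")
}

#' @export
print.phase_correction <- function(x, ...) {
  cat("<phase_correction> coefficients:\n")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' @describeIn background_phase_correction Fitted polynomial coefficients as
#'   a tibble.
#' @param x A `phase_correction` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.phase_correction <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' Convert phase differences to velocity maps
#'
#' `V(r, t) = delta_phi(r, t) / pi * VENC`. Because the wrapped phase lies
#' in `(-pi, pi]`, the output is bounded by VENC by construction; true
#' velocities beyond VENC alias (a planted `1.5 * VENC` recovers
#' `-0.5 * VENC`).
#'
#' @param phase A [phase_series()].
#' @param venc_cm_s Encoding velocity in cm/s (> 0).
#' @return A [velocity_series()].
#' @export
to_velocity <- function(phase, venc_cm_s) {
  if (venc_cm_s <= 0) stop_validation("`venc_cm_s` must be > 0")
  velocity_series(phase$data / pi * venc_cm_s, phase$frame_times_ms,
                  phase$grid, venc_cm_s)
}
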