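#' Raw (k,t)-space samples
#'
#' The raw input of reconstruction: one record per acquired phase-encode
#' line, carrying its velocity encoding (1 = flow-compensated, 2..Nv =
#' flow-encoded), receiver coil, 0-based ky index, acquisition time stamp,
#' role (`"training"` lines from central k-space at high temporal rate,
#' `"imaging"` lines from the outer region), and the complex readout vector
#' of length `nx`.
#'
#' @param lines A data frame with columns `encoding`, `coil`, `ky`, `t_ms`,
#'   `role` and a list-column `signal` of complex vectors of length
#'   `grid$nx`, ordered by acquisition time.
#' @param grid A [grid2d()].
#' @param nv Number of velocity encodings (>= 1; 2 for one-directional flow
#'   encoding: flow-compensated plus one flow-encoded).
#' @param nc Number of receiver coils.
#' @param tr_ms Repetition time in ms (one line per TR).
#' @param venc_cm_s Encoding velocity VENC in cm/s (phase difference of pi
#'   maps to VENC).
#' @param frame_ms Optional reconstruction frame period in ms; defaults to
#'   the nominal `2 * nv * tr_ms` of the interleaved scheme.
#' @return An object of class `kt_samples`; `$lines` is a tibble.
#' @seealso [read_kt()], [write_kt()], [acquire()], [reconstruct()]
#' @export
kt_samples <- function(lines, grid, nv, nc, tr_ms, venc_cm_s,
                       frame_ms = NULL) {
  stopifnot(inherits(grid, "grid2d"))
  lines <- as_tibble(lines)
  need <- c("encoding", "coil", "ky", "t_ms", "role", "signal")
  missing_cols <- setdiff(need, names(lines))
  if (length(missing_cols)) {
    stop_format(paste0("`lines` is missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  nv <- as.integer(nv); nc <- as.integer(nc)
  tr_ms <- as.numeric(tr_ms); venc_cm_s <- as.numeric(venc_cm_s)
  if (nv < 1L || nc < 1L) stop_validation("`nv` and `nc` must be >= 1")
  if (!is.finite(tr_ms) || tr_ms <= 0) stop_validation("`tr_ms` must be > 0")
  if (!is.finite(venc_cm_s) || venc_cm_s <= 0) {
    stop_validation("`venc_cm_s` must be > 0")
  }
  if (is.null(frame_ms)) frame_ms <- 2 * nv * tr_ms
  x <- structure(
    list(lines = lines, grid = grid, nv = nv, nc = nc,
         tr_ms = tr_ms, venc_cm_s = venc_cm_s, frame_ms = as.numeric(frame_ms)),
    class = "kt_samples")
  validate_kt_samples(x)
}

#' Validate a `kt_samples` object
#'
#' Checks the structural invariants of the raw container: time stamps
#' nondecreasing in acquisition order, ky indices inside the grid, no
#' duplicated (encoding, coil, ky, t) record, and an identical
#' (encoding, ky, t, role) line set for every coil.
#'
#' @param x A `kt_samples` object.
#' @return `x`, invisibly unchanged, or an error describing the first
#'   violated invariant (with the offending line index where applicable).
#' @export
validate_kt_samples <- function(x) {
  ln <- x$lines
  if (nrow(ln) == 0L) stop_validation("kt_samples contains no lines")
  if (!all(ln$encoding %in% seq_len(x$nv))) {
    bad <- which(!ln$encoding %in% seq_len(x$nv))[1]
    stop_validation(sprintf("line %d: encoding outside 1..Nv", bad))
  }
  if (!all(ln$coil %in% seq_len(x$nc))) {
    bad <- which(!ln$coil %in% seq_len(x$nc))[1]
    stop_validation(sprintf("line %d: coil outside 1..Nc", bad))
  }
  if (any(ln$ky < 0L | ln$ky >= x$grid$ny)) {
    bad <- which(ln$ky < 0L | ln$ky >= x$grid$ny)[1]
    stop_validation(sprintf("line %d: ky index %d outside [0, ny)", bad, ln$ky[bad]))
  }
  if (is.unsorted(ln$t_ms)) {
    bad <- which(diff(ln$t_ms) < 0)[1] + 1L
    stop_validation(sprintf("line %d: time stamps not nondecreasing", bad))
  }
  if (!all(ln$role %in% c("training", "imaging"))) {
    bad <- which(!ln$role %in% c("training", "imaging"))[1]
    stop_validation(sprintf("line %d: role must be 'training' or 'imaging'", bad))
  }
  key <- paste(ln$encoding, ln$coil, ln$ky, ln$t_ms)
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))[1]
    stop_validation(sprintf("line %d: duplicate (encoding, coil, ky, t) record", bad))
  }
  coil_key <- split(paste(ln$encoding, ln$ky, ln$t_ms, ln$role), ln$coil)
  coil_key <- lapply(coil_key, sort)
  if (length(unique(coil_key)) != 1L) {
    stop_validation("coils do not share an identical (encoding, ky, t, role) line set")
  }
  nx <- x$grid$nx
  len_ok <- vapply(ln$signal, function(s) is.complex(s) && length(s) == nx,
                   logical(1))
  if (!all(len_ok)) {
    bad <- which(!len_ok)[1]
    stop_validation(sprintf("line %d: signal must be a complex vector of length nx", bad))
  }
  invisible(x)
}

#' @export
print.kt_samples <- function(x, ...) {
  cat(sprintf(
    "<kt_samples> %d lines | Nv = %d, Nc = %d | grid %dx%d | TR %.3g ms | VENC %g cm/s\n",
    nrow(x$lines), x$nv, x$nc, x$grid$nx, x$grid$ny, x$tr_ms, x$venc_cm_s))
  cat(sprintf("  training lines: %d, imaging lines: %d, span %.1f ms\n",
              sum(x$lines$role == "training"), sum(x$lines$role == "imaging"),
              diff(range(x$lines$t_ms))))
  invisible(x)
}

#' Complex dynamic image series
#'
#' One velocity encoding's image sequence rho_v(r, t) on a fixed grid, held
#' as its Casorati matrix: voxels (column-major over the grid) by frames.
#'
#' @param data Complex matrix of shape `(nx*ny) x M`.
#' @param frame_times_ms Strictly increasing frame times in ms, length `M`.
#' @param grid A [grid2d()].
#' @param venc_cm_s VENC carried along for velocity mapping (may be `NA`).
#' @return An object of class `image_series`.
#' @export
image_series <- function(data, frame_times_ms, grid, venc_cm_s = NA_real_) {
  stopifnot(inherits(grid, "grid2d"))
  data <- as.matrix(data)
  if (!is.complex(data)) data <- data + 0i
  if (nrow(data) != n_voxels(grid)) {
    stop_validation("`data` must have nx*ny rows (column-major voxels)")
  }
  frame_times_ms <- as.numeric(frame_times_ms)
  if (ncol(data) != length(frame_times_ms)) {
    stop_validation("frame count of `data` must match `frame_times_ms`")
  }
  if (length(frame_times_ms) > 1L && any(diff(frame_times_ms) <= 0)) {
    stop_validation("`frame_times_ms` must be strictly increasing")
  }
  if (!all(is.finite(Re(data))) || !all(is.finite(Im(data)))) {
    stop_validation("image series contains non-finite values")
  }
  structure(list(data = data, frame_times_ms = frame_times_ms, grid = grid,
                 venc_cm_s = as.numeric(venc_cm_s)),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  cat(sprintf("<image_series> %dx%d grid, %d frames (%.1f..%.1f ms)\n",
              x$grid$nx, x$grid$ny, ncol(x$data),
              min(x$frame_times_ms), max(x$frame_times_ms)))
  invisible(x)
}

#' Extract one frame of a series as an image matrix
#'
#' @param x An `image_series`, `velocity_series` or `phase_series`.
#' @param m Frame index (1-based).
#' @return An `nx x ny` matrix.
#' @export
series_frame <- function(x, m) {
  stopifnot(m >= 1, m <= ncol(x$data))
  matrix(x$data[, m], x$grid$nx, x$grid$ny)
}

#' Coil sensitivity maps
#'
#' @param maps Complex array `(nx, ny, Nc)` of per-coil sensitivities.
#' @param support Logical `nx x ny` mask; maps are RSS-normalised to 1 on
#'   the support and zero outside it.
#' @param grid A [grid2d()].
#' @return An object of class `sensitivity_maps`.
#' @export
sensitivity_maps <- function(maps, support, grid) {
  stopifnot(inherits(grid, "grid2d"))
  d <- dim(maps)
  if (length(d) == 2L) {
    maps <- array(maps, c(d, 1L))
    d <- dim(maps)
  }
  if (d[1] != grid$nx || d[2] != grid$ny) {
    stop_validation("sensitivity maps do not match the grid")
  }
  support <- array(as.logical(support), c(grid$nx, grid$ny))
  rss <- sqrt(apply(Mod(maps)^2, c(1, 2), sum))
  if (any(abs(rss[support] - 1) > 1e-6)) {
    stop_validation("root-sum-of-squares of sensitivities must be 1 (+-1e-6) on the support")
  }
  if (any(rss[!support] != 0)) {
    stop_validation("sensitivities must be exactly zero outside the support")
  }
  structure(list(maps = maps, support = support, grid = grid, nc = d[3]),
            class = "sensitivity_maps")
}

#' @export
print.sensitivity_maps <- function(x, ...) {
  cat(sprintf("<sensitivity_maps> %d coils on %dx%d grid, support %d px\n",
              x$nc, x$grid$nx, x$grid$ny, sum(x$support)))
  invisible(x)
}

#' Temporal subspace (the V factor of C = UV)
#'
#' @param v In joint mode a complex `L x (Nv*M)` matrix with orthonormal
#'   rows spanning the temporal subspace of the joint Casorati matrix
#'   `[C_1, ..., C_Nv]`; in separate mode a list of per-encoding `L x M`
#'   matrices.
#' @param mode `"joint"` or `"separate"`.
#' @param frame_times_ms Frame times (length M) of the underlying series.
#' @param nv Number of encodings.
#' @return An object of class `temporal_subspace`.
#' @export
temporal_subspace <- function(v, mode = c("joint", "separate"),
                              frame_times_ms, nv = 2L) {
  mode <- match.arg(mode)
  frame_times_ms <- as.numeric(frame_times_ms)
  m <- length(frame_times_ms)
  check_orth <- function(vv, what) {
    if (!is.complex(vv)) vv <- vv + 0i
    g <- vv %*% Conj(t(vv))
    if (max(Mod(g - diag(nrow(vv)))) > 1e-8) {
      stop_validation(paste0(what, ": rows of V must be orthonormal (V V^H = I +-1e-8)"))
    }
    vv
  }
  if (mode == "joint") {
    v <- check_orth(as.matrix(v), "joint subspace")
    if (ncol(v) != nv * m) {
      stop_validation("joint V must have Nv*M columns")
    }
    if (nrow(v) > ncol(v)) stop_validation("L must be <= Nv*M")
  } else {
    if (!is.list(v)) stop_validation("separate mode expects a list of per-encoding V matrices")
    v <- lapply(seq_along(v), function(i) {
      vi <- check_orth(as.matrix(v[[i]]), sprintf("encoding %d subspace", i))
      if (ncol(vi) != m) stop_validation("per-encoding V must have M columns")
      if (nrow(vi) > m) stop_validation("L must be <= M")
      vi
    })
    nv <- length(v)
  }
  structure(list(v = v, mode = mode, frame_times_ms = frame_times_ms,
                 nv = as.integer(nv),
                 L = if (mode == "joint") nrow(v) else nrow(v[[1]])),
            class = "temporal_subspace")
}

#' @export
print.temporal_subspace <- function(x, ...) {
  cat(sprintf("<temporal_subspace> mode %s, L = %d, M = %d, Nv = %d\n",
              x$mode, x$L, length(x$frame_times_ms), x$nv))
  invisible(x)
}

#' Spatial subspace (the U factor of C = UV)
#'
#' @param u In joint mode a complex `N x L` matrix (N = nx*ny voxels,
#'   column-major); in separate mode a list of per-encoding `N x L` matrices.
#' @param grid A [grid2d()].
#' @param mode `"joint"` or `"separate"`.
#' @return An object of class `spatial_subspace`.
#' @export
spatial_subspace <- function(u, grid, mode = c("joint", "separate")) {
  mode <- match.arg(mode)
  stopifnot(inherits(grid, "grid2d"))
  check <- function(ui) {
    ui <- as.matrix(ui)
    if (!is.complex(ui)) ui <- ui + 0i
    if (nrow(ui) != n_voxels(grid)) stop_validation("U must have nx*ny rows")
    if (!all(is.finite(Re(ui))) || !all(is.finite(Im(ui)))) {
      stop_validation("U contains non-finite values")
    }
    ui
  }
  u <- if (mode == "joint") check(u) else lapply(u, check)
  structure(list(u = u, grid = grid, mode = mode,
                 L = if (mode == "joint") ncol(u) else ncol(u[[1]])),
            class = "spatial_subspace")
}

#' Real-valued velocity map series
#'
#' @param data Real matrix `(nx*ny) x M` of velocities in cm/s, bounded by
#'   the encoding velocity.
#' @param frame_times_ms Strictly increasing frame times, ms.
#' @param grid A [grid2d()].
#' @param venc_cm_s Encoding velocity; `abs(data) <= venc` must hold.
#' @return An object of class `velocity_series`.
#' @export
velocity_series <- function(data, frame_times_ms, grid, venc_cm_s) {
  stopifnot(inherits(grid, "grid2d"))
  data <- as.matrix(data)
  if (!is.numeric(data)) stop_validation("velocity data must be real-valued")
  if (nrow(data) != n_voxels(grid)) stop_validation("`data` must have nx*ny rows")
  frame_times_ms <- as.numeric(frame_times_ms)
  if (ncol(data) != length(frame_times_ms)) {
    stop_validation("frame count must match `frame_times_ms`")
  }
  if (length(frame_times_ms) > 1L && any(diff(frame_times_ms) <= 0)) {
    stop_validation("`frame_times_ms` must be strictly increasing")
  }
  if (!all(is.finite(data))) stop_validation("velocity series contains non-finite values")
  venc_cm_s <- as.numeric(venc_cm_s)
  if (any(abs(data) > venc_cm_s * (1 + 1e-12) + 1e-12)) {
    stop_validation("velocity magnitudes must not exceed VENC")
  }
  structure(list(data = data, frame_times_ms = frame_times_ms, grid = grid,
                 venc_cm_s = venc_cm_s),
            class = "velocity_series")
}

#' @export
print.velocity_series <- function(x, ...) {
  cat(sprintf("<velocity_series> %dx%d grid, %d frames, VENC %g cm/s, range [%.2f, %.2f]\n",
              x$grid$nx, x$grid$ny, ncol(x$data), x$venc_cm_s,
              min(x$data), max(x$data)))
  invisible(x)
}

#' Phase-difference map series (radians)
#'
#' @param data Real matrix `(nx*ny) x M` of wrapped phases in `(-pi, pi]`.
#' @param frame_times_ms Frame times, ms.
#' @param grid A [grid2d()].
#' @param low_signal Optional logical matrix flagging voxels/frames where
#'   both magnitudes were below the signal floor.
#' @return An object of class `phase_series`.
#' @export
phase_series <- function(data, frame_times_ms, grid, low_signal = NULL) {
  stopifnot(inherits(grid, "grid2d"))
  data <- as.matrix(data)
  if (any(data <= -pi - 1e-12 | data > pi + 1e-12)) {
    stop_validation("phase values must lie in (-pi, pi]")
  }
  structure(list(data = data, frame_times_ms = as.numeric(frame_times_ms),
                 grid = grid, low_signal = low_signal),
            class = "phase_series")
}

#' Region-of-interest mask
#'
#' @param mask Logical `nx x ny` matrix with at least one `TRUE` pixel.
#' @param grid The [grid2d()] the mask refers to (fixes the pixel area).
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, grid) {
  stopifnot(inherits(grid, "grid2d"))
  mask <- matrix(as.logical(mask), grid$nx, grid$ny)
  if (!any(mask)) stop_validation("ROI mask must contain at least one pixel")
  structure(list(mask = mask, grid = grid,
                 pixel_area_mm2 = pixel_area(grid, "mm2")),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d px on %dx%d grid (%.2f mm2 each)\n",
              sum(x$mask), x$grid$nx, x$grid$ny, x$pixel_area_mm2))
  invisible(x)
}

#' Flow waveform
#'
#' A time series of ROI-mean velocity (cm/s) or volumetric flow (mL/s) — the
#' unit all flow analytics operate on. Stored as a tibble with columns
#' `time_s` and `value` so waveforms pipe directly into dplyr/ggplot2.
#'
#' @param time_s Strictly increasing times in seconds.
#' @param value Finite values (cm/s for `"mean_velocity"`, mL/s for `"flow"`).
#' @param quantity What the values measure.
#' @param period_s Optional known repetition period (used when a waveform is
#'   extended periodically, e.g. by the phantom renderer).
#' @return A tibble of class `flow_waveform`.
#' @export
flow_waveform <- function(time_s, value,
                          quantity = c("mean_velocity", "flow", "custom"),
                          period_s = NA_real_) {
  quantity <- match.arg(quantity)
  time_s <- as.numeric(time_s); value <- as.numeric(value)
  if (length(time_s) != length(value)) {
    stop_validation("`time_s` and `value` must have equal length")
  }
  if (length(time_s) > 1L && any(diff(time_s) <= 0)) {
    stop_validation("`time_s` must be strictly increasing")
  }
  if (!all(is.finite(value))) stop_validation("waveform values must be finite")
  out <- tibble(time_s = time_s, value = value)
  attr(out, "quantity") <- quantity
  attr(out, "period_s") <- as.numeric(period_s)
  class(out) <- c("flow_waveform", class(out))
  out
}

waveform_quantity <- function(w) attr(w, "quantity") %||% "custom"
waveform_period <- function(w) attr(w, "period_s") %||% NA_real_
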