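#' Nominal temporal resolution of the interleaved real-time acquisition
#'
#' One reconstruction frame of the interleaved training/imaging scheme
#' spans one training line and one imaging line for each of the `nv`
#' velocity encodings, i.e. `2 * nv * TR`. With `nv = 2` (flow-compensated
#' plus one flow-encoded) and TR = 4.5 ms this gives the 18 ms frame period
#' of the in vivo protocol; TR = 5.0 ms gives the 20 ms of the phantom
#' protocol.
#'
#' @param nv Number of velocity encodings, >= 1.
#' @param tr_ms Repetition time in ms, > 0.
#' @return The nominal frame period in ms.
#' @examples
#' nominal_temporal_resolution(2, 4.5) # 18
#' @export
nominal_temporal_resolution <- function(nv, tr_ms) {
  if (nv < 1) stop_validation("`nv` must be >= 1")
  if (tr_ms <= 0) stop_validation("`tr_ms` must be > 0")
  2 * nv * tr_ms
}

#' Temporal resolution of a retrospectively gated cine acquisition
#'
#' Cine imaging folds many heartbeats into `n_phases` cardiac phases over
#' an assumed cycle, so its effective frame period is the assumed period
#' divided by the number of phases (e.g. a 2 s cycle at 36 phases is about
#' 56 ms).
#'
#' @param period_s Assumed cardiac period in seconds.
#' @param n_phases Number of reconstructed cardiac phases.
#' @return Frame period in ms.
#' @export
cine_temporal_resolution <- function(period_s, n_phases) {
  if (period_s <= 0 || n_phases < 1) {
    stop_validation("`period_s` must be > 0 and `n_phases` >= 1")
  }
  1000 * period_s / n_phases
}

#' Interleaved training/imaging Cartesian sampling pattern
#'
#' Generates the (k,t)-space schedule of the real-time acquisition: TR
#' slots cycle through the velocity encodings, alternating a training line
#' drawn from the central ky band with `imaging_lines_per_frame` imaging
#' lines drawn uniformly at random without replacement from the remaining
#' (outer) ky lines, re-shuffling each time the outer lines are exhausted.
#' The identical ky schedule is applied to every encoding, so each
#' reconstruction frame of duration `nv * (1 + imaging_lines_per_frame) * TR`
#' contains the same training/imaging budget per encoding (the nominal
#' temporal resolution `2 * nv * TR` corresponds to the default of one
#' imaging line per frame).
#'
#' @param ny Number of phase-encode lines; must exceed the training band.
#' @param nv Number of velocity encodings.
#' @param tr_ms Repetition time in ms (one line per TR slot).
#' @param n_frames Number of reconstruction frames to schedule.
#' @param central_halfwidth Half-width `w` of the training band
#'   `[ny%/%2 - w, ny%/%2 + w]`; the default 0 uses the single centre line.
#' @param imaging_lines_per_frame Imaging lines per encoding per frame.
#' @param seed Optional integer seed; the pattern is a pure function of its
#'   arguments including the seed.
#' @return A tibble of class `sampling_pattern` with one row per TR slot:
#'   `slot` (0-based), `t_ms`, `encoding`, `ky` (0-based), `role`.
#' @export
make_interleaved_pattern <- function(ny, nv, tr_ms, n_frames,
                                     central_halfwidth = 0L,
                                     imaging_lines_per_frame = 1L,
                                     seed = NULL) {
  ny <- as.integer(ny); nv <- as.integer(nv); n_frames <- as.integer(n_frames)
  w <- as.integer(central_halfwidth)
  k <- as.integer(imaging_lines_per_frame)
  if (n_frames < 1L) stop_validation("`n_frames` must be >= 1")
  if (k < 1L) stop_validation("`imaging_lines_per_frame` must be >= 1")
  if (w < 0L) stop_validation("`central_halfwidth` must be >= 0")
  centre <- ny %/% 2L
  band <- seq.int(max(0L, centre - w), min(ny - 1L, centre + w))
  outer_lines <- setdiff(0L:(ny - 1L), band)
  if (ny <= 2L * w + 1L || length(outer_lines) == 0L) {
    stop_validation("central training band covers all of ky; no imaging lines possible")
  }
  n_img <- n_frames * k
  draw <- function() {
    # uniform without replacement per sweep, re-shuffled when exhausted
    sweeps <- ceiling(n_img / length(outer_lines))
    ks <- unlist(lapply(seq_len(sweeps), function(i) sample(outer_lines)))
    ks[seq_len(n_img)]
  }
  imaging_ky <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  training_ky <- band[((seq_len(n_frames) - 1L) %% length(band)) + 1L]

  slots_per_frame <- nv * (1L + k)
  n_slots <- n_frames * slots_per_frame
  frame <- rep(seq_len(n_frames) - 1L, each = slots_per_frame)
  # within a frame: for each encoding, one training slot then k imaging slots
  within <- rep(seq_len(slots_per_frame) - 1L, times = n_frames)
  encoding <- within %/% (1L + k) + 1L
  pos <- within %% (1L + k)
  role <- ifelse(pos == 0L, "training", "imaging")
  ky <- integer(n_slots)
  ky[role == "training"] <- rep(training_ky, each = nv)
  img_idx <- frame[role == "imaging"] * k + pos[role == "imaging"]
  ky[role == "imaging"] <- imaging_ky[img_idx]  # same schedule for all encodings
  out <- tibble(
    slot = seq_len(n_slots) - 1L,
    t_ms = (seq_len(n_slots) - 1L) * tr_ms,
    encoding = as.integer(encoding),
    ky = as.integer(ky),
    role = role
  )
  attr(out, "ny") <- ny
  attr(out, "nv") <- nv
  attr(out, "tr_ms") <- tr_ms
  attr(out, "n_frames") <- n_frames
  attr(out, "frame_ms") <- slots_per_frame * tr_ms
  attr(out, "central_halfwidth") <- w
  attr(out, "imaging_lines_per_frame") <- k
  attr(out, "seed") <- seed
  class(out) <- c("sampling_pattern", class(out))
  out
}

#' Assemble a sampling pattern from explicit slots
#'
#' Escape hatch for custom schedules (e.g. full-Nyquist reference scans):
#' takes an explicit slot table and attaches the pattern metadata.
#'
#' @param slots Data frame with columns `slot`, `t_ms`, `encoding`, `ky`,
#'   `role`.
#' @inheritParams make_interleaved_pattern
#' @param frame_ms Frame period in ms.
#' @return A `sampling_pattern` tibble.
#' @export
sampling_pattern <- function(slots, ny, nv, tr_ms, frame_ms) {
  out <- as_tibble(slots)
  need <- c("slot", "t_ms", "encoding", "ky", "role")
  if (!all(need %in% names(out))) {
    stop_format(paste0("slots must have columns: ", paste(need, collapse = ", ")))
  }
  if (any(out$ky < 0L | out$ky >= ny)) stop_validation("ky outside [0, ny)")
  attr(out, "ny") <- as.integer(ny)
  attr(out, "nv") <- as.integer(nv)
  attr(out, "tr_ms") <- tr_ms
  attr(out, "frame_ms") <- frame_ms
  attr(out, "n_frames") <- max(floor(out$t_ms / frame_ms)) + 1L
  class(out) <- unique(c("sampling_pattern", class(out)))
  out
}

pattern_attr <- function(p, nm) attr(p, nm)

#' Coverage and acceleration summary of a sampling pattern
#'
#' @param pattern A `sampling_pattern`.
#' @return A list of class `coverage_report` with `summary` (one row per
#'   encoding: acceleration factor ny / mean imaging lines per frame,
#'   training rate, outer-line coverage) and `ky_histogram` tibbles.
#' @export
coverage_report <- function(pattern) {
  ny <- pattern_attr(pattern, "ny")
  frame_ms <- pattern_attr(pattern, "frame_ms")
  p <- as_tibble(pattern)
  p$frame <- floor(p$t_ms / frame_ms)
  n_frames <- length(unique(p$frame))
  summ <- dplyr::group_by(p, .data$encoding)
  summ <- dplyr::summarise(
    summ,
    n_slots = dplyr::n(),
    n_training = sum(.data$role == "training"),
    n_imaging = sum(.data$role == "imaging"),
    imaging_lines_per_frame = sum(.data$role == "imaging") / n_frames,
    acceleration = ny / (sum(.data$role == "imaging") / n_frames),
    training_rate = mean(.data$role == "training"),
    ky_coverage = length(unique(.data$ky)) / ny,
    .groups = "drop")
  hist <- dplyr::count(p, .data$encoding, .data$role, .data$ky, name = "n")
  structure(list(summary = summ, ky_histogram = hist, n_frames = n_frames),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report> %d frames\n", x$n_frames))
  print(x$summary)
  invisible(x)
}

# frame centre times for a pattern's reconstruction grid
pattern_frame_times <- function(pattern) {
  frame_ms <- pattern_attr(pattern, "frame_ms")
  (seq_len(pattern_attr(pattern, "n_frames")) - 0.5) * frame_ms
}
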