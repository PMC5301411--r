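#' Pipeline run configuration
#'
#' Bundles the phantom, sampling, reconstruction and analysis parameters of
#' a full simulate / reconstruct / analyse run, with one global seed. The
#' defaults reproduce the digital phantom protocol: 64 x 64 grid at 1.2 mm,
#' a 15-mm vessel, waveform I (2 s period, 80 cm/s peak over a 10 cm/s
#' baseline), Nv = 2, TR = 5 ms (20 ms frames), VENC = 100 cm/s, 8 coils,
#' complex noise sd 0.05 and a joint rank-20 reconstruction.
#'
#' @param nx,ny Grid size.
#' @param pixel_mm Pixel size (mm).
#' @param vessel_radius_mm Vessel radius (mm).
#' @param waveform_kind `"I"` or `"II"`.
#' @param period_s Waveform period (s); `NULL` for the kind's default.
#' @param peak_cm_s,baseline_cm_s Waveform amplitudes (cm/s).
#' @param second_peak_ratio Kind II second-bell ratio.
#' @param profile `"plug"` or `"parabolic"` velocity profile.
#' @param duration_s Acquisition duration (s).
#' @param nv,nc Number of encodings and coils.
#' @param tr_ms Repetition time (ms).
#' @param venc_cm_s Encoding velocity (cm/s).
#' @param noise_sd Complex-sample noise standard deviation.
#' @param central_halfwidth,imaging_lines_per_frame Sampling-pattern knobs.
#' @param L,mode,tol,max_iter Reconstruction parameters (see
#'   [recon_config()]).
#' @param correction_order Background-phase polynomial order.
#' @param seed Global integer seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(nx = 64L, ny = 64L, pixel_mm = 1.2,
                       vessel_radius_mm = 7.5,
                       waveform_kind = "I", period_s = NULL,
                       peak_cm_s = 80, baseline_cm_s = 10,
                       second_peak_ratio = 0.6,
                       profile = "plug", duration_s = 10,
                       nv = 2L, nc = 8L, tr_ms = 5, venc_cm_s = 100,
                       noise_sd = 0.05,
                       central_halfwidth = 0L, imaging_lines_per_frame = 1L,
                       L = 20L, mode = "joint", tol = 1e-6, max_iter = 100L,
                       correction_order = 2L, seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(cfg$period_s)) {
    cfg$period_s <- if (waveform_kind == "II") 4 else 2
  }
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` a `run_config`. The round trip is lossless.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

config_objects <- function(config) {
  grid <- grid2d(config$nx, config$ny, config$pixel_mm)
  geometry <- phantom_geometry(grid, radius_mm = config$vessel_radius_mm)
  spec <- waveform_spec(kind = config$waveform_kind,
                        period_s = config$period_s,
                        peak_cm_s = config$peak_cm_s,
                        baseline_cm_s = config$baseline_cm_s,
                        second_peak_ratio = config$second_peak_ratio)
  list(grid = grid, geometry = geometry, spec = spec)
}

#' Simulate a phantom acquisition to disk
#'
#' Generates the ground-truth image series, coil maps and sampling
#' schedule from a [run_config()], acquires noisy (k,t)-space data, and
#' writes the raw container, ground-truth series and a JSON manifest of all
#' parameters and seeds. A fixed config and seed reproduce the raw file
#' bit-identically.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the written `paths` and the in-memory
#'   `kt`, `truth`, `pattern`, `sens` objects.
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  obj <- config_objects(config)
  n_frames <- max(1L, floor(1000 * config$duration_s /
    (config$nv * (1 + config$imaging_lines_per_frame) * config$tr_ms)))
  pattern <- make_interleaved_pattern(
    ny = config$ny, nv = config$nv, tr_ms = config$tr_ms,
    n_frames = n_frames, central_halfwidth = config$central_halfwidth,
    imaging_lines_per_frame = config$imaging_lines_per_frame,
    seed = config$seed)
  wave <- make_waveform(obj$spec, duration_s = config$period_s)
  truth <- render_truth(obj$geometry, wave, pattern_frame_times(pattern),
                        config$venc_cm_s, profile = config$profile)
  sens <- make_sensitivities(config$nc, obj$grid, seed = config$seed + 1L)
  kt <- acquire(truth, sens, pattern, noise_sd = config$noise_sd,
                seed = config$seed + 2L)
  raw_path <- file.path(out_dir, "raw.h5")
  write_kt(kt, raw_path)
  truth_paths <- file.path(out_dir, c("truth_compensated.h5", "truth_encoded.h5"))
  write_series_h5(truth[[1]], truth_paths[1], complex_data = TRUE)
  write_series_h5(truth[[2]], truth_paths[2], complex_data = TRUE)
  manifest <- list(stage = "simulate", config = unclass(config),
                   seeds = list(pattern = config$seed,
                                sensitivities = config$seed + 1L,
                                noise = config$seed + 2L),
                   n_frames = n_frames,
                   package_version = as.character(utils::packageVersion("ktflow")),
                   files = c(raw = raw_path, truth_paths))
  jsonlite::write_json(manifest, file.path(out_dir, "simulate_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(paths = manifest$files, kt = kt, truth = truth,
                 pattern = pattern, sens = sens))
}

#' Reconstruct a raw container to disk
#'
#' @param raw_path Path to a raw HDF5 container (see [write_kt()]).
#' @param config A [run_config()].
#' @param out_dir Output directory; receives per-encoding image series and
#'   a JSON log of solver diagnostics.
#' @return Invisibly, the `kt_recon` object and written paths.
#' @export
run_recon <- function(raw_path, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  kt <- read_kt(raw_path)
  cfg <- recon_config(L = config$L, mode = config$mode, tol = config$tol,
                      max_iter = config$max_iter)
  rec <- reconstruct(kt, cfg)
  paths <- file.path(out_dir, sprintf("recon_encoding%d.h5", seq_along(rec$series)))
  for (v in seq_along(rec$series)) {
    write_series_h5(rec$series[[v]], paths[v], complex_data = TRUE)
  }
  diag <- list(stage = "recon", L = rec$tsub$L, mode = cfg$mode,
               summary = as.list(glance(rec)),
               cg = lapply(rec$diagnostics, function(d) {
                 list(encoding = d$encoding, iterations = d$iterations,
                      converged = d$converged, residuals = d$residuals)
               }),
               files = paths)
  jsonlite::write_json(diag, file.path(out_dir, "recon_diagnostics.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(recon = rec, paths = paths))
}

#' Analyse reconstructed series to disk
#'
#' Post-processing stage: phase difference, background-phase correction,
#' velocity mapping, ROI waveform, beat segmentation, per-cycle peak
#' velocities and stroke volumes, SNR/VNR, and (optionally) Bland-Altman
#' agreement of the per-cycle peaks against a reference waveform.
#'
#' @param compensated_path,encoded_path Paths to the reconstructed
#'   per-encoding HDF5 series (encoding 1 and 2).
#' @param config A [run_config()] (provides the ROI geometry).
#' @param out_dir Output directory.
#' @param reference Optional [flow_waveform()] of the true ROI-mean
#'   velocity for agreement analysis.
#' @return Invisibly, a list with the velocity series, waveform,
#'   segmentation and the report (also written as JSON, with the waveform
#'   as CSV and velocity as HDF5).
#' @export
run_analyze <- function(compensated_path, encoded_path, config, out_dir,
                        reference = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  comp <- read_series(compensated_path)
  enc <- read_series(encoded_path)
  obj <- config_objects(config)
  if (!same_grid(comp$grid, obj$grid)) {
    stop_validation("configured ROI grid does not match the reconstructed series")
  }
  roi <- vessel_mask(obj$geometry)
  static <- static_tissue_mask(obj$geometry)
  bg <- background_mask(obj$geometry)
  pd <- phase_difference(enc, comp)
  corr <- background_phase_correction(pd, comp, order = config$correction_order)
  vel <- to_velocity(corr$phase, config$venc_cm_s)
  wave <- roi_mean_waveform(vel, roi)
  seg <- segment_beats(wave)
  peaks <- if (nrow(seg)) peak_velocity(wave, seg) else NULL
  volumes <- if (nrow(seg)) stroke_volume(vel, roi, seg) else NULL
  peak_frame <- which.max(wave$value)
  report <- list(
    stage = "analyze",
    n_frames = length(wave$value),
    n_cycles = nrow(seg),
    peak_velocity_overall = peak_velocity(wave),
    per_cycle_peaks = if (!is.null(peaks)) peaks$peak,
    per_cycle_volumes_ml = if (!is.null(volumes)) volumes$volume_ml,
    snr = snr(comp, peak_frame, roi, bg),
    vnr = vnr(vel, peak_frame, roi, static))
  if (!is.null(reference) && !is.null(peaks) && nrow(seg) >= 2) {
    ref_peaks <- peak_velocity(reference, segment_beats(reference))
    n <- min(nrow(peaks), nrow(ref_peaks))
    ba <- bland_altman(peaks$peak[seq_len(n)], ref_peaks$peak[seq_len(n)])
    report$bland_altman <- as.list(glance(ba))
  }
  manifest <- write_outputs(comp, vel, list(wave), out_dir)
  jsonlite::write_json(report, file.path(out_dir, "analysis_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(velocity = vel, waveform = wave, segmentation = seg,
                 report = report, manifest = manifest))
}
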