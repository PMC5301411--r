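quiet_h5write <- function(...) suppressMessages(rhdf5::h5write(...))

#' Read and write the raw (k,t)-space container
#'
#' The raw container is a single HDF5 file:
#' \preformatted{
#' /data/lines_real, /data/lines_imag   nx x n_lines doubles (complex readouts)
#' /data/meta/encoding, coil, ky, t_ms  per-line metadata (ky is 0-based)
#' /data/meta/role                      "training" | "imaging"
#' root attributes: TR_ms, VENC_cm_s, Nv, Nc, nx, ny, pixel_mm, frame_ms
#' }
#' Field names mirror ISMRMRD conventions where a one-to-one mapping exists;
#' complex data are stored as paired real/imag datasets. The round trip
#' `write_kt()` then `read_kt()` is bit-exact for all line records.
#'
#' @param kt A [kt_samples()] object.
#' @param path File path of the HDF5 container.
#' @return `read_kt()` returns a validated [kt_samples()]; `write_kt()`
#'   returns `path` invisibly.
#' @export
write_kt <- function(kt, path) {
  validate_kt_samples(kt)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "data")
  rhdf5::h5createGroup(path, "data/meta")
  sig <- vapply(kt$lines$signal, identity, complex(kt$grid$nx))
  sig <- matrix(sig, nrow = kt$grid$nx)
  quiet_h5write(Re(sig), path, "data/lines_real")
  quiet_h5write(Im(sig), path, "data/lines_imag")
  quiet_h5write(as.integer(kt$lines$encoding), path, "data/meta/encoding")
  quiet_h5write(as.integer(kt$lines$coil), path, "data/meta/coil")
  quiet_h5write(as.integer(kt$lines$ky), path, "data/meta/ky")
  quiet_h5write(as.numeric(kt$lines$t_ms), path, "data/meta/t_ms")
  quiet_h5write(as.character(kt$lines$role), path, "data/meta/role")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  att <- list(TR_ms = kt$tr_ms, VENC_cm_s = kt$venc_cm_s,
              Nv = as.integer(kt$nv), Nc = as.integer(kt$nc),
              nx = as.integer(kt$grid$nx), ny = as.integer(kt$grid$ny),
              pixel_mm = kt$grid$pixel_mm, frame_ms = kt$frame_ms)
  for (nm in names(att)) rhdf5::h5writeAttribute(att[[nm]], fid, nm)
  invisible(path)
}

#' @rdname write_kt
#' @export
read_kt <- function(path) {
  if (!file.exists(path)) stop_format(paste0("file not found: ", path))
  contents <- rhdf5::h5ls(path)
  have <- file.path(contents$group, contents$name)
  need <- c("/data/lines_real", "/data/lines_imag", "/data/meta/encoding",
            "/data/meta/coil", "/data/meta/ky", "/data/meta/t_ms",
            "/data/meta/role")
  miss <- setdiff(need, have)
  if (length(miss)) {
    stop_format(paste0("raw container is missing dataset(s): ",
                       paste(miss, collapse = ", ")))
  }
  att <- rhdf5::h5readAttributes(path, "/")
  for (nm in c("TR_ms", "VENC_cm_s", "Nv", "Nc", "nx", "ny", "pixel_mm")) {
    if (is.null(att[[nm]])) {
      stop_format(paste0("raw container is missing attribute: ", nm))
    }
  }
  re <- rhdf5::h5read(path, "data/lines_real")
  im <- rhdf5::h5read(path, "data/lines_imag")
  sig <- matrix(complex(real = re, imaginary = im), nrow = nrow(re))
  lines <- tibble(
    encoding = as.integer(rhdf5::h5read(path, "data/meta/encoding")),
    coil = as.integer(rhdf5::h5read(path, "data/meta/coil")),
    ky = as.integer(rhdf5::h5read(path, "data/meta/ky")),
    t_ms = as.numeric(rhdf5::h5read(path, "data/meta/t_ms")),
    role = as.character(rhdf5::h5read(path, "data/meta/role")),
    signal = lapply(seq_len(ncol(sig)), function(j) sig[, j])
  )
  grid <- grid2d(att$nx, att$ny, as.numeric(att$pixel_mm))
  kt_samples(lines, grid, nv = att$Nv, nc = att$Nc, tr_ms = att$TR_ms,
             venc_cm_s = att$VENC_cm_s,
             frame_ms = if (!is.null(att$frame_ms)) att$frame_ms else NULL)
}

write_series_h5 <- function(x, path, complex_data) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "series")
  if (complex_data) {
    quiet_h5write(Re(x$data), path, "series/real")
    quiet_h5write(Im(x$data), path, "series/imag")
  } else {
    quiet_h5write(x$data, path, "series/values")
  }
  quiet_h5write(x$frame_times_ms, path, "series/frame_times_ms")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  att <- list(nx = as.integer(x$grid$nx), ny = as.integer(x$grid$ny),
              pixel_mm = x$grid$pixel_mm,
              VENC_cm_s = x$venc_cm_s %||% NA_real_)
  for (nm in names(att)) rhdf5::h5writeAttribute(att[[nm]], fid, nm)
  invisible(path)
}

#' Read an image or velocity series from HDF5
#'
#' @param path HDF5 file written by [write_outputs()] (or the internal
#'   series writer): complex series carry `series/real` + `series/imag`,
#'   velocity series `series/values`.
#' @return An [image_series()] or [velocity_series()].
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop_format(paste0("file not found: ", path))
  contents <- rhdf5::h5ls(path)
  have <- file.path(contents$group, contents$name)
  att <- rhdf5::h5readAttributes(path, "/")
  grid <- grid2d(att$nx, att$ny, as.numeric(att$pixel_mm))
  ft <- as.numeric(rhdf5::h5read(path, "series/frame_times_ms"))
  venc <- as.numeric(att$VENC_cm_s)
  if ("/series/real" %in% have) {
    data <- matrix(complex(real = rhdf5::h5read(path, "series/real"),
                           imaginary = rhdf5::h5read(path, "series/imag")),
                   nrow = n_voxels(grid))
    image_series(data, ft, grid, venc)
  } else if ("/series/values" %in% have) {
    velocity_series(matrix(rhdf5::h5read(path, "series/values"),
                           nrow = n_voxels(grid)), ft, grid, venc)
  } else {
    stop_format("file contains neither series/real+imag nor series/values")
  }
}

#' Write waveforms to CSV
#'
#' @param w A [flow_waveform()].
#' @param path CSV path; columns `time_s`, `value`, `quantity`.
#' @return `path` invisibly.
#' @export
write_waveform_csv <- function(w, path) {
  readr::write_csv(
    tibble(time_s = w$time_s, value = w$value, quantity = waveform_quantity(w)),
    path)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  flow_waveform(d$time_s, d$value,
                quantity = as.character(d$quantity[1]))
}

#' Write reconstruction and analysis outputs
#'
#' Persists a magnitude/complex image series and a velocity series as HDF5,
#' any number of flow waveforms as CSV, and (optionally) NIfTI volumes of
#' the magnitude and velocity series with the frame index as the fourth
#' dimension.
#'
#' @param series An [image_series()].
#' @param velocity A [velocity_series()] on the same grid.
#' @param waveforms A (possibly empty) list of [flow_waveform()]s.
#' @param dir Output directory (created if needed).
#' @param nifti Also write NIfTI exports of |series| and velocity.
#' @return A tibble manifest with columns `file` and `kind`.
#' @export
write_outputs <- function(series, velocity, waveforms = list(), dir,
                          nifti = FALSE) {
  stopifnot(inherits(series, "image_series"),
            inherits(velocity, "velocity_series"))
  if (!same_grid(series$grid, velocity$grid)) {
    stop_validation("series and velocity must share one grid")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(); kinds <- character()
  p <- file.path(dir, "images.h5")
  write_series_h5(series, p, complex_data = TRUE)
  files <- c(files, p); kinds <- c(kinds, "image_series")
  p <- file.path(dir, "velocity.h5")
  write_series_h5(velocity, p, complex_data = FALSE)
  files <- c(files, p); kinds <- c(kinds, "velocity_series")
  if (nifti) {
    g <- series$grid
    mag <- array(Mod(series$data), c(g$nx, g$ny, 1L, ncol(series$data)))
    p <- file.path(dir, "magnitude.nii.gz")
    RNifti::writeNifti(RNifti::asNifti(mag, pixdim = c(g$pixel_mm, 1, 1)), p)
    files <- c(files, p); kinds <- c(kinds, "magnitude_nifti")
    vel <- array(velocity$data, c(g$nx, g$ny, 1L, ncol(velocity$data)))
    p <- file.path(dir, "velocity.nii.gz")
    RNifti::writeNifti(RNifti::asNifti(vel, pixdim = c(g$pixel_mm, 1, 1)), p)
    files <- c(files, p); kinds <- c(kinds, "velocity_nifti")
  }
  for (i in seq_along(waveforms)) {
    w <- waveforms[[i]]
    p <- file.path(dir, sprintf("waveform_%02d_%s.csv", i, waveform_quantity(w)))
    write_waveform_csv(w, p)
    files <- c(files, p); kinds <- c(kinds, "waveform_csv")
  }
  tibble(file = files, kind = kinds)
}
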