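#' Two-dimensional image grid
#'
#' Describes the fixed Cartesian grid on which all image-domain objects live:
#' `nx` readout samples by `ny` phase-encode lines, with a physical pixel
#' size in millimetres. The k-space origin sits at the 0-based index
#' `(nx %/% 2, ny %/% 2)`, matching the centred-FFT convention used by the
#' acquisition and reconstruction operators.
#'
#' @param nx Number of readout samples (frequency-encode direction), >= 2.
#' @param ny Number of phase-encode lines, >= 2.
#' @param pixel_mm Pixel size in mm; either a scalar (isotropic) or a
#'   length-2 vector `c(dx, dy)`.
#' @return An object of class `grid2d`.
#' @examples
#' grid2d(64, 64, pixel_mm = 1.2)
#' @export
grid2d <- function(nx, ny, pixel_mm = 1) {
  nx <- as.integer(nx)
  ny <- as.integer(ny)
  if (length(nx) != 1L || length(ny) != 1L || is.na(nx) || is.na(ny) ||
      nx < 2L || ny < 2L) {
    stop_validation("`nx` and `ny` must be single integers >= 2")
  }
  pixel_mm <- as.numeric(pixel_mm)
  if (length(pixel_mm) == 1L) pixel_mm <- rep(pixel_mm, 2L)
  if (length(pixel_mm) != 2L || any(!is.finite(pixel_mm)) || any(pixel_mm <= 0)) {
    stop_validation("`pixel_mm` must be one or two positive finite numbers")
  }
  structure(list(nx = nx, ny = ny, pixel_mm = pixel_mm), class = "grid2d")
}

#' @export
print.grid2d <- function(x, ...) {
  cat(sprintf("<grid2d> %d x %d, pixel %.3g x %.3g mm\n",
              x$nx, x$ny, x$pixel_mm[1], x$pixel_mm[2]))
  invisible(x)
}

n_voxels <- function(grid) grid$nx * grid$ny

#' Pixel area of a grid
#'
#' @param grid A [grid2d()].
#' @param units `"mm2"` or `"cm2"`.
#' @return Pixel area as a scalar.
#' @export
pixel_area <- function(grid, units = c("mm2", "cm2")) {
  units <- match.arg(units)
  a <- grid$pixel_mm[1] * grid$pixel_mm[2]
  if (units == "cm2") a / 100 else a
}

same_grid <- function(a, b) {
  a$nx == b$nx && a$ny == b$ny && isTRUE(all.equal(a$pixel_mm, b$pixel_mm))
}

# ---- centred unitary FFT helpers ------------------------------------------
#
# Convention: the image/k-space origin is at 0-based index n %/% 2, i.e. R
# index n %/% 2 + 1. ft2c / ift2c form a unitary pair (adjoint == inverse),
# which the CG solver's adjoint test relies on.

shift_idx <- function(n) ((seq_len(n) - 1L - n %/% 2L) %% n) + 1L   # corner -> centre
ishift_idx <- function(n) ((seq_len(n) - 1L + n %/% 2L) %% n) + 1L  # centre -> corner

fftshift2 <- function(x) x[shift_idx(nrow(x)), shift_idx(ncol(x)), drop = FALSE]
ifftshift2 <- function(x) x[ishift_idx(nrow(x)), ishift_idx(ncol(x)), drop = FALSE]

ft2c <- function(x) fftshift2(fft(ifftshift2(x))) / sqrt(length(x))
ift2c <- function(x) fftshift2(fft(ifftshift2(x), inverse = TRUE)) / sqrt(length(x))

# centred unitary 1-D FFT along the rows of a matrix (dim 1)
ft1c_mat <- function(x, inverse = FALSE) {
  n <- nrow(x)
  y <- mvfft(x[ishift_idx(n), , drop = FALSE], inverse = inverse)
  y[shift_idx(n), , drop = FALSE] / sqrt(n)
}

# centred unitary FFT along dim 2 (phase encode) of an (nx, ny, K) array
fty_c <- function(a, inverse = FALSE) {
  d <- dim(a)
  if (is.null(d)) stop("array input required")
  if (length(d) == 2L) d <- c(d, 1L)
  m <- aperm(array(a, d), c(2L, 1L, 3L))
  dim(m) <- c(d[2L], d[1L] * d[3L])
  m <- ft1c_mat(m, inverse = inverse)
  dim(m) <- c(d[2L], d[1L], d[3L])
  out <- aperm(m, c(2L, 1L, 3L))
  dim(out) <- dim(a)
  out
}

hann_window <- function(n) {
  if (n <= 1L) return(rep(1, n))
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)))
}
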