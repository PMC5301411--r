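#' Reconstruction configuration
#'
#' @param L Rank of the low-rank model (number of temporal basis functions).
#'   The default 20 balances representational power against noise
#'   amplification for typical real-time flow protocols.
#' @param mode `"joint"` (one subspace pair shared by all encodings via the
#'   joint Casorati matrix) or `"separate"` (an independent rank-L model per
#'   encoding).
#' @param tol Conjugate-gradient stopping tolerance on the relative residual
#'   of the normal equations.
#' @param max_iter Maximum CG iterations.
#' @param interp Temporal interpolation for the training data: `"linear"`
#'   (default) or `"cubic"`.
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(L = 20L, mode = c("joint", "separate"),
                         tol = 1e-6, max_iter = 100L,
                         interp = c("linear", "cubic")) {
  mode <- match.arg(mode)
  interp <- match.arg(interp)
  L <- as.integer(L)
  if (L < 1L) stop_validation("`L` must be >= 1")
  if (tol <= 0) stop_validation("`tol` must be > 0")
  structure(list(L = L, mode = mode, tol = tol,
                 max_iter = as.integer(max_iter), interp = interp),
            class = "recon_config")
}

#' @export
print.recon_config <- function(x, ...) {
  cat(sprintf("<recon_config> L = %d, mode = %s, tol = %g, max_iter = %d, interp = %s\n",
              x$L, x$mode, x$tol, x$max_iter, x$interp))
  invisible(x)
}

#' Temporally interpolate the training data onto the frame grid
#'
#' The central-k-space training lines are acquired once per frame per
#' encoding; this resamples every training channel (encoding, coil, readout
#' sample, training ky) onto the reconstruction frame times so the temporal
#' subspace is estimated at the same time instants as the imaging data.
#' Real and imaginary parts are interpolated independently; times outside
#' the acquired span are clamped to the edge values.
#'
#' @param kt A [kt_samples()] container.
#' @param target_times_ms Frame times to interpolate onto.
#' @param kind `"linear"` (default) or `"cubic"` spline interpolation.
#' @return An object of class `training_data`: per-encoding channel-by-frame
#'   complex matrices with a common channel ordering (training ky, then
#'   coil, then readout sample).
#' @export
interpolate_training <- function(kt, target_times_ms, kind = c("linear", "cubic")) {
  kind <- match.arg(kind)
  nx <- kt$grid$nx; nc <- kt$nc
  tl <- kt$lines[kt$lines$role == "training", ]
  if (nrow(tl) == 0L) stop_validation("no training lines in kt_samples")
  kys <- sort(unique(tl$ky))
  target_times_ms <- as.numeric(target_times_ms)
  m <- length(target_times_ms)
  blocks <- vector("list", kt$nv)
  for (v in seq_len(kt$nv)) {
    block <- matrix(0i, nx * nc * length(kys), m)
    for (b in seq_along(kys)) {
      sub <- tl[tl$encoding == v & tl$ky == kys[b], ]
      times <- sort(unique(sub$t_ms))
      if (length(times) < 2L) {
        stop_validation(sprintf(
          "training channel (encoding %d, ky %d) has fewer than 2 samples",
          v, kys[b]))
      }
      a <- array(0i, c(nx, nc, length(times)))
      it <- match(sub$t_ms, times)
      for (r in seq_len(nrow(sub))) {
        a[, sub$coil[r], it[r]] <- sub$signal[[r]]
      }
      dim(a) <- c(nx * nc, length(times))
      tt <- pmin(pmax(target_times_ms, times[1]), times[length(times)])
      if (kind == "linear") {
        k0 <- findInterval(tt, times, all.inside = TRUE)
        w <- (tt - times[k0]) / (times[k0 + 1L] - times[k0])
        w <- pmin(pmax(w, 0), 1)
        interp <- a[, k0, drop = FALSE] * rep(1 - w, each = nx * nc) +
          a[, k0 + 1L, drop = FALSE] * rep(w, each = nx * nc)
      } else {
        interp <- t(apply(a, 1, function(ch) {
          complex(real = stats::spline(times, Re(ch), xout = tt)$y,
                  imaginary = stats::spline(times, Im(ch), xout = tt)$y)
        }))
      }
      block[(b - 1L) * nx * nc + seq_len(nx * nc), ] <- interp
    }
    blocks[[v]] <- block
  }
  structure(list(blocks = blocks, frame_times_ms = target_times_ms,
                 nv = kt$nv, training_ky = kys, nc = nc, nx = nx),
            class = "training_data")
}

#' Estimate the temporal subspace by principal component analysis
#'
#' The rank-L temporal basis is the set of L leading right singular vectors
#' of the training matrix. In joint mode the per-encoding training blocks
#' are concatenated along the frame axis — each channel row then is a row
#' functional of the joint Casorati matrix `[C_1, ..., C_Nv]`, so the
#' resulting basis spans its temporal subspace. In separate mode one basis
#' is estimated per encoding.
#'
#' @param train A `training_data` object from [interpolate_training()].
#' @param L Rank; must not exceed the training matrix dimensions. If it
#'   exceeds the numerical rank, the trailing basis vectors span an
#'   arbitrary orthonormal complement (a warning is issued).
#' @param mode `"joint"` or `"separate"`.
#' @return A [temporal_subspace()].
#' @export
estimate_temporal_subspace <- function(train, L, mode = c("joint", "separate")) {
  mode <- match.arg(mode)
  L <- as.integer(L)
  top_rows <- function(x, L) {
    if (L > min(dim(x))) {
      stop_validation(sprintf("L = %d exceeds the training matrix dimensions %d x %d",
                              L, nrow(x), ncol(x)))
    }
    s <- svd(x)
    if (L > sum(s$d > max(dim(x)) * .Machine$double.eps * s$d[1])) {
      warn("L exceeds the numerical rank of the training data; trailing basis vectors are arbitrary")
    }
    Conj(t(s$v[, seq_len(L), drop = FALSE]))
  }
  if (mode == "joint") {
    x <- do.call(cbind, train$blocks)
    v <- top_rows(x, L)
  } else {
    v <- lapply(train$blocks, top_rows, L = L)
  }
  temporal_subspace(v, mode = mode, frame_times_ms = train$frame_times_ms,
                    nv = train$nv)
}

#' Estimate coil sensitivities from temporally averaged k-space
#'
#' Averages all flow-compensated (encoding 1) samples at each k-space
#' location over time, zero-fills unvisited ky lines, applies a Hann taper
#' over the filled ky band when the band does not cover k-space (a complete
#' average needs no taper), inverse-transforms, and normalises each coil
#' image by the root sum of squares across coils. The support is where the
#' RSS exceeds a relative threshold; sensitivities are zero outside it.
#'
#' @param kt A [kt_samples()] container with flow-compensated lines.
#' @param support_threshold Relative RSS threshold defining the support.
#' @return A [sensitivity_maps()] object.
#' @export
estimate_sensitivities <- function(kt, support_threshold = 0.05) {
  g <- kt$grid
  ln <- kt$lines[kt$lines$encoding == 1L, ]
  if (nrow(ln) == 0L) stop_validation("no flow-compensated (encoding 1) lines present")
  nx <- g$nx; ny <- g$ny; nc <- kt$nc
  ksum <- array(0i, c(nx, ny, nc))
  count <- matrix(0, ny, nc)
  for (r in seq_len(nrow(ln))) {
    j <- ln$ky[r] + 1L
    i <- ln$coil[r]
    ksum[, j, i] <- ksum[, j, i] + ln$signal[[r]]
    count[j, i] <- count[j, i] + 1
  }
  band <- which(rowSums(count) > 0)
  if (length(band) < ny) {
    wky <- rep(0, ny)
    span <- seq(min(band), max(band))
    wky[span] <- hann_window(length(span))
  } else {
    wky <- rep(1, ny)
  }
  imgs <- array(0i, c(nx, ny, nc))
  for (i in seq_len(nc)) {
    avg <- ksum[, , i]
    nz <- count[, i] > 0
    avg[, nz] <- avg[, nz, drop = FALSE] / rep(count[nz, i], each = nx)
    avg <- avg * rep(wky, each = nx)
    imgs[, , i] <- ift2c(avg)
  }
  rss <- sqrt(apply(Mod(imgs)^2, c(1, 2), sum))
  support <- rss >= support_threshold * max(rss)
  maps <- array(0i, c(nx, ny, nc))
  for (i in seq_len(nc)) {
    mi <- imgs[, , i]
    mi[support] <- mi[support] / rss[support]
    mi[!support] <- 0
    maps[, , i] <- mi
  }
  sensitivity_maps(maps, support, g)
}

# ---- forward model plumbing ------------------------------------------------
#
# The readout (kx) direction is always fully sampled, so the data are moved
# once into hybrid (x, ky) space by a unitary 1-D inverse FFT along kx; the
# encoding operator then reduces to coil modulation followed by a centred
# unitary 1-D FFT along y and selection of the scheduled ky lines. This is a
# unitary change of variables of the least-squares problem in the 2-D
# k-space formulation, so solutions coincide while the transform count drops
# by an order of magnitude.

# Build the solver workspace for one least-squares problem.
# lines: tibble subset (single-coil ordering applies to all coils),
# col_of_line: Casorati column (1..T) of every line.
build_plan <- function(kt, sens, v_mat, lines, col_of_line) {
  g <- kt$grid
  nx <- g$nx; ny <- g$ny
  nc <- kt$nc
  t_total <- ncol(v_mat)
  ord <- order(lines$t_ms, lines$encoding, lines$ky)
  per_coil <- split(seq_len(nrow(lines)), lines$coil)
  ref <- per_coil[[1]][order(lines$t_ms[per_coil[[1]]],
                             lines$encoding[per_coil[[1]]],
                             lines$ky[per_coil[[1]]])]
  nl <- length(ref)
  d <- array(0i, c(nx, nl, nc))
  for (i in seq_len(nc)) {
    idx <- per_coil[[i]]
    idx <- idx[order(lines$t_ms[idx], lines$encoding[idx], lines$ky[idx])]
    if (length(idx) != nl) {
      stop_validation("coils do not share an identical line set for the solve")
    }
    sig <- vapply(lines$signal[idx], identity, complex(nx))
    d[, , i] <- ft1c_mat(matrix(sig, nx), inverse = TRUE)  # hybrid (x, ky)
  }
  fi <- (col_of_line[ref] - 1L) * ny + lines$ky[ref] + 1L
  has_dup <- anyDuplicated(fi) > 0L
  list(nx = nx, ny = ny, nc = nc, t_total = t_total, v = v_mat,
       maps = sens$maps, fi = fi, has_dup = has_dup, d = d,
       n = nx * ny, L = nrow(v_mat))
}

op_forward <- function(u, plan) {
  cc <- u %*% plan$v
  dim(cc) <- c(plan$nx, plan$ny, plan$t_total)
  y <- array(0i, c(plan$nx, length(plan$fi), plan$nc))
  for (i in seq_len(plan$nc)) {
    h <- fty_c(cc * as.vector(plan$maps[, , i]))
    dim(h) <- c(plan$nx, plan$ny * plan$t_total)
    y[, , i] <- h[, plan$fi]
  }
  y
}

op_adjoint <- function(y, plan) {
  g <- matrix(0i, plan$nx, plan$ny * plan$t_total)
  for (i in seq_len(plan$nc)) {
    z <- matrix(0i, plan$nx, plan$ny * plan$t_total)
    yi <- y[, , i, drop = FALSE]
    dim(yi) <- c(plan$nx, length(plan$fi))
    if (plan$has_dup) {
      for (l in seq_along(plan$fi)) {
        z[, plan$fi[l]] <- z[, plan$fi[l]] + yi[, l]
      }
    } else {
      z[, plan$fi] <- yi
    }
    dim(z) <- c(plan$nx, plan$ny, plan$t_total)
    b <- fty_c(z, inverse = TRUE) * Conj(as.vector(plan$maps[, , i]))
    dim(b) <- c(plan$nx, plan$ny * plan$t_total)
    g <- g + b
  }
  dim(g) <- c(plan$n, plan$t_total)
  g %*% Conj(t(plan$v))
}

# Fast-path inputs for the compiled normal operator: everything is moved to
# a y-fastest voxel ordering with the phase-encode axis in natural FFT
# ordering, so the C++ kernel needs no fftshifts. Unitarily equivalent to
# the (hybrid-space) operator above; solutions coincide.
build_solver_inputs <- function(kt, sens, v_mat, lines, col_of_line) {
  g <- kt$grid
  nx <- g$nx; ny <- g$ny; nc <- kt$nc
  t_total <- ncol(v_mat)
  yorder <- ishift_idx(ny)
  s_cube <- aperm(sens$maps[, yorder, , drop = FALSE], c(2L, 1L, 3L))
  row_nat <- shift_idx(ny)[lines$ky + 1L]
  per_coil <- split(seq_len(nrow(lines)), lines$coil)
  if (length(per_coil) != nc ||
      length(unique(lengths(per_coil))) != 1L) {
    stop_validation("coils do not share an identical line set for the solve")
  }
  w <- matrix(0, ny, t_total)
  ref <- per_coil[[1]]
  for (l in ref) {
    w[row_nat[l], col_of_line[l]] <- w[row_nat[l], col_of_line[l]] + 1
  }
  gmat <- matrix(0i, ny, nx * t_total)
  for (i in seq_len(nc)) {
    idx <- per_coil[[i]]
    z <- matrix(0i, ny, nx * t_total)
    hyb <- ft1c_mat(matrix(vapply(lines$signal[idx], identity, complex(nx)), nx),
                    inverse = TRUE)
    for (j in seq_along(idx)) {
      l <- idx[j]
      cols <- (col_of_line[l] - 1L) * nx + seq_len(nx)
      z[row_nat[l], cols] <- z[row_nat[l], cols] + hyb[, j]
    }
    b <- mvfft(z, inverse = TRUE) / sqrt(ny)
    gmat <- gmat + b * rep(Conj(as.vector(s_cube[, , i])), times = t_total)
  }
  dim(gmat) <- c(ny * nx, t_total)
  rhs <- gmat %*% Conj(t(v_mat))
  # map permuted rows back to the standard x-fastest ordering
  xv <- rep(seq_len(nx), each = ny)
  ypv <- rep(seq_len(ny), times = nx)
  std_row <- xv + (yorder[ypv] - 1L) * nx
  list(v = v_mat, s_cube = s_cube, w = w, rhs = rhs, std_row = std_row,
       n = nx * ny)
}

solve_one <- function(inp, cfg) {
  sol <- cg_normal(function(u) kt_normal_op(u, inp$v, inp$s_cube, inp$w),
                   inp$rhs, cfg$tol, cfg$max_iter)
  u_std <- matrix(0i, inp$n, ncol(inp$rhs))
  u_std[inp$std_row, ] <- sol$x
  list(u = u_std, sol = sol)
}

cdot_re <- function(a, b) Re(sum(Conj(a) * b))

# Conjugate gradient on the (Hermitian PSD) normal equations, zero start.
cg_normal <- function(amul, b, tol, max_iter) {
  x <- matrix(0i, nrow(b), ncol(b))
  r <- b
  p <- r
  rs <- cdot_re(r, r)
  bn <- sqrt(rs)
  if (bn == 0) {
    return(list(x = x, iterations = 0L, residuals = numeric(0), converged = TRUE))
  }
  hist <- numeric(0)
  n_inc <- 0L
  best_rs <- rs
  best_x <- x
  for (it in seq_len(max_iter)) {
    ap <- amul(p)
    pap <- cdot_re(p, ap)
    if (pap <= 0) break  # numerically null direction
    alpha <- rs / pap
    x <- x + alpha * p
    r <- r - alpha * ap
    rs_new <- cdot_re(r, r)
    hist <- c(hist, sqrt(rs_new) / bn)
    if (rs_new < best_rs) {
      best_rs <- rs_new
      best_x <- x
    }
    n_inc <- if (rs_new > rs) n_inc + 1L else 0L
    if (n_inc >= 5L) {
      if (rs_new > 100 * best_rs) {
        stop_solver("conjugate gradient diverged (residual increased for 5 consecutive iterations)",
                    residuals = hist)
      }
      # stagnation at the numerical floor: keep the best iterate
      return(list(x = best_x, iterations = it, residuals = hist,
                  converged = sqrt(best_rs) / bn <= tol))
    }
    if (sqrt(rs_new) / bn <= tol) {
      return(list(x = x, iterations = it, residuals = hist, converged = TRUE))
    }
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  list(x = best_x, iterations = length(hist), residuals = hist,
       converged = FALSE)
}

#' Solve for the spatial subspace given the temporal basis
#'
#' Recovers `U` as the least-squares minimiser of the multi-coil
#' data-consistency objective
#' `sum_i || d_i - Omega[F S_i (U V)] ||^2`
#' by conjugate gradient on the normal equations from zero initialisation.
#' Both training and imaging samples enter the data term. In separate mode
#' the problem decouples into one solve per encoding.
#'
#' @param kt A [kt_samples()] container.
#' @param sens [sensitivity_maps()] for the SENSE model.
#' @param tsub A [temporal_subspace()] whose frame grid covers the data.
#' @param cfg A [recon_config()] (rank is taken from `tsub`).
#' @return A [spatial_subspace()] with CG diagnostics in
#'   `attr(, "diagnostics")`.
#' @export
solve_spatial_subspace <- function(kt, sens, tsub, cfg = recon_config()) {
  m <- length(tsub$frame_times_ms)
  lines <- kt$lines
  frame_of <- pmin(pmax(floor(lines$t_ms / kt$frame_ms), 0), m - 1L) + 1L
  if (tsub$mode == "joint") {
    col <- (lines$encoding - 1L) * m + frame_of
    inp <- build_solver_inputs(kt, sens, tsub$v, lines, col)
    res <- solve_one(inp, cfg)
    out <- spatial_subspace(res$u, kt$grid, mode = "joint")
    diag <- list(list(encoding = NA_integer_, iterations = res$sol$iterations,
                      residuals = res$sol$residuals,
                      converged = res$sol$converged))
  } else {
    us <- vector("list", kt$nv)
    diag <- vector("list", kt$nv)
    for (v in seq_len(kt$nv)) {
      keep <- lines$encoding == v
      inp <- build_solver_inputs(kt, sens, tsub$v[[v]], lines[keep, ],
                                 frame_of[keep])
      res <- solve_one(inp, cfg)
      us[[v]] <- res$u
      diag[[v]] <- list(encoding = v, iterations = res$sol$iterations,
                        residuals = res$sol$residuals,
                        converged = res$sol$converged)
    }
    out <- spatial_subspace(us, kt$grid, mode = "separate")
  }
  attr(out, "diagnostics") <- diag
  out
}

#' Compose image series from the subspace factors
#'
#' Forms `C = U V` and splits the joint Casorati columns back into the
#' per-encoding image sequences (columns `1..M` belong to encoding 1,
#' `M+1..2M` to encoding 2, ...).
#'
#' @param usub A [spatial_subspace()].
#' @param tsub The paired [temporal_subspace()].
#' @param venc_cm_s VENC to carry into the series (optional).
#' @return A list of per-encoding [image_series()].
#' @export
compose <- function(usub, tsub, venc_cm_s = NA_real_) {
  ft <- tsub$frame_times_ms
  m <- length(ft)
  if (usub$mode != tsub$mode) stop_validation("subspace modes do not match")
  if (tsub$mode == "joint") {
    if (ncol(usub$u) != nrow(tsub$v)) stop_validation("U and V ranks do not match")
    cc <- usub$u %*% tsub$v
    lapply(seq_len(tsub$nv), function(v) {
      image_series(cc[, (v - 1L) * m + seq_len(m), drop = FALSE], ft,
                   usub$grid, venc_cm_s)
    })
  } else {
    lapply(seq_len(tsub$nv), function(v) {
      if (ncol(usub$u[[v]]) != nrow(tsub$v[[v]])) {
        stop_validation("U and V ranks do not match")
      }
      image_series(usub$u[[v]] %*% tsub$v[[v]], ft, usub$grid, venc_cm_s)
    })
  }
}

#' End-to-end subspace reconstruction
#'
#' Convenience pipeline: assign lines to reconstruction frames, interpolate
#' the training data onto the frame grid, estimate the temporal subspace by
#' PCA, estimate coil sensitivities from the temporally averaged
#' flow-compensated k-space, solve the SENSE least-squares problem for the
#' spatial subspace, and compose the per-encoding image series.
#'
#' @param kt A [kt_samples()] container.
#' @param cfg A [recon_config()].
#' @return An object of class `kt_recon`: `$series` (list of per-encoding
#'   [image_series()]), the subspace factors, sensitivities, configuration
#'   and solver diagnostics.
#' @export
reconstruct <- function(kt, cfg = recon_config()) {
  validate_kt_samples(kt)
  m <- floor(max(kt$lines$t_ms) / kt$frame_ms) + 1L
  frame_times <- (seq_len(m) - 0.5) * kt$frame_ms
  train <- interpolate_training(kt, frame_times, kind = cfg$interp)
  l_max <- if (cfg$mode == "joint") {
    min(nrow(do.call(cbind, train$blocks)), kt$nv * m)
  } else {
    min(vapply(train$blocks, function(b) min(dim(b)), numeric(1)))
  }
  l_use <- cfg$L
  if (l_use > l_max) {
    warn(sprintf("rank L = %d exceeds the training data size; using L = %d",
                 cfg$L, l_max))
    l_use <- l_max
  }
  tsub <- estimate_temporal_subspace(train, l_use, cfg$mode)
  sens <- estimate_sensitivities(kt)
  usub <- solve_spatial_subspace(kt, sens, tsub, cfg)
  series <- compose(usub, tsub, kt$venc_cm_s)
  structure(list(series = series, tsub = tsub, usub = usub, sens = sens,
                 config = cfg, frame_times_ms = frame_times,
                 diagnostics = attr(usub, "diagnostics")),
            class = "kt_recon")
}

#' @export
print.kt_recon <- function(x, ...) {
  it <- sum(vapply(x$diagnostics, function(d) d$iterations, numeric(1)))
  cat(sprintf("<kt_recon> mode %s, L = %d, %d encodings x %d frames, %d CG iterations\n",
              x$config$mode, x$tsub$L, length(x$series),
              length(x$frame_times_ms), it))
  invisible(x)
}

#' @describeIn reconstruct One-row summary of a reconstruction (mode, rank,
#'   frames, CG iterations and final residual).
#' @param x A `kt_recon` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.kt_recon <- function(x, ...) {
  res <- vapply(x$diagnostics,
                function(d) if (length(d$residuals)) tail(d$residuals, 1) else NA_real_,
                numeric(1))
  tibble(mode = x$config$mode, L = x$tsub$L,
         n_encodings = length(x$series),
         n_frames = length(x$frame_times_ms),
         cg_iterations = sum(vapply(x$diagnostics, function(d) d$iterations, numeric(1))),
         final_residual = max(res),
         converged = all(vapply(x$diagnostics, function(d) isTRUE(d$converged), logical(1))))
}

#' @describeIn reconstruct Per-iteration CG residual history as a tibble.
#' @exportS3Method generics::tidy
tidy.kt_recon <- function(x, ...) {
  dplyr::bind_rows(lapply(x$diagnostics, function(d) {
    if (!length(d$residuals)) return(NULL)
    tibble(encoding = d$encoding, iteration = seq_along(d$residuals),
           residual = d$residuals)
  }))
}
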