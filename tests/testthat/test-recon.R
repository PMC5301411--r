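test_that("training interpolation is exact at nodes and for linear signals", {
  g <- tiny_grid(4, 8)
  # two training channels (one per encoding), linear in time: a + b * t
  a <- complex(real = 1:4, imaginary = 4:1)
  b <- complex(real = rep(0.5, 4), imaginary = rep(-0.25, 4))
  mk <- function(t, v) list(a + b * t)
  times <- c(0, 10, 20, 30)
  lines <- tibble::tibble(
    encoding = rep(c(1L, 2L), times = 4),
    coil = 1L, ky = 4L,
    t_ms = rep(times, each = 2),
    role = "training",
    signal = lapply(rep(times, each = 2), function(t) a + b * t))
  kt <- kt_samples(lines, g, 2, 1, 5, 100)
  # at the nodes: unchanged
  tr <- interpolate_training(kt, times)
  for (v in 1:2) {
    expect_equal(tr$blocks[[v]][, 2], a + b * 10)
  }
  # between nodes: exact for the linear kind, clamped at the edges
  tr5 <- interpolate_training(kt, c(-10, 5, 45))
  expect_equal(tr5$blocks[[1]][, 1], a + b * 0)
  expect_equal(tr5$blocks[[1]][, 2], a + b * 5)
  expect_equal(tr5$blocks[[1]][, 3], a + b * 30)
  # constant channel stays constant
  const <- lines
  const$signal <- lapply(seq_len(nrow(const)), function(i) a)
  ktc <- kt_samples(const, g, 2, 1, 5, 100)
  trc <- interpolate_training(ktc, c(3, 17, 29))
  expect_lt(max(Mod(trc$blocks[[1]] - a)), 1e-14)
})

test_that("a starved training channel is reported by name", {
  g <- tiny_grid(4, 8)
  lines <- tibble::tibble(
    encoding = c(1L, 1L, 2L), coil = 1L, ky = 4L,
    t_ms = c(0, 10, 20), role = "training",
    signal = replicate(3, complex(real = rnorm(4)), simplify = FALSE))
  kt <- kt_samples(lines, g, 2, 1, 5, 100)
  expect_error(interpolate_training(kt, c(0, 10)), "encoding 2",
               class = "ktflow_validation_error")
})

test_that("PCA subspace reproduces exact-rank training data", {
  set.seed(4)
  ph <- stepped_phantom(nx = 16, nc = 2, n_frames = 8,
                        imaging_lines_per_frame = 4)
  m <- length(ph$frame_times)
  tr <- interpolate_training(ph$kt, ph$frame_times)
  x <- do.call(cbind, tr$blocks)
  tsub <- estimate_temporal_subspace(tr, 2, "joint")
  proj <- x %*% Conj(t(tsub$v)) %*% tsub$v
  expect_lt(rel_err(proj, x), 1e-10)
  # full subspace: V V^H = I and zero residual
  suppressWarnings(tfull <- estimate_temporal_subspace(tr, min(dim(x)), "joint"))
  gram <- tfull$v %*% Conj(t(tfull$v))
  expect_lt(max(Mod(gram - diag(nrow(tfull$v)))), 1e-8)
  # separate mode returns one orthonormal basis per encoding (the static
  # compensated encoding has rank 1, so L = 2 warns about the complement)
  suppressWarnings(tsep <- estimate_temporal_subspace(tr, 2, "separate"))
  expect_length(tsep$v, 2L)
  expect_equal(ncol(tsep$v[[1]]), m)
})

test_that("truncated PCA obeys the Eckart-Young residual", {
  set.seed(9)
  # complex matrix with prescribed singular values (3, 2, 1, 0, ...)
  qz <- function(n) qr.Q(qr(matrix(complex(real = rnorm(n * n),
                                           imaginary = rnorm(n * n)), n)))
  d <- c(3, 2, 1, rep(0, 5))
  x <- qz(8) %*% diag(d) %*% Conj(t(qz(8)))
  sv <- svd(x)
  v2 <- Conj(t(sv$v[, 1:2]))
  resid <- x - x %*% Conj(t(v2)) %*% v2
  frac <- sqrt(sum(Mod(resid)^2) / sum(Mod(x)^2))
  expect_equal(frac, 1 / sqrt(14), tolerance = 1e-10)
  # projection residual is non-increasing in L
  fracs <- vapply(1:4, function(l) {
    vl <- Conj(t(sv$v[, seq_len(l), drop = FALSE]))
    sqrt(sum(Mod(x - x %*% Conj(t(vl)) %*% vl)^2))
  }, numeric(1))
  expect_true(all(diff(fracs) <= 1e-12))
})

test_that("sensitivity estimation recovers relative coil phases", {
  # static phantom, full sampling, noiseless
  g <- tiny_grid(16, 16)
  geom <- phantom_geometry(g, radius_mm = 5)
  w <- flow_waveform(c(0, 0.5), c(0, 0), period_s = 1)
  tr <- render_truth(geom, w, c(10, 30), 100)
  sens <- make_sensitivities(3, g, seed = 6)
  slots <- tibble::tibble(slot = 0:31, t_ms = rep(c(10, 30), each = 16),
                          encoding = 1L, ky = rep(0:15, 2), role = "imaging")
  pat <- sampling_pattern(slots, ny = 16, nv = 1, tr_ms = 5, frame_ms = 20)
  kt <- acquire(list(tr[[1]]), sens, pat, noise_sd = 0)
  est <- estimate_sensitivities(kt)
  sup <- est$support & matrix(as.vector(Mod(tr[[1]]$data[, 1]) > 0.5), 16, 16)
  expect_gt(sum(sup), 20)
  for (i in 1:3) {
    for (j in 1:3) {
      got <- (est$maps[, , i] * Conj(est$maps[, , j]))[sup]
      want <- (sens$maps[, , i] * Conj(sens$maps[, , j]))[sup]
      expect_lt(max(Mod(got - want)), 1e-6)
    }
  }
  # single-coil: magnitude exactly 1 on the support
  kt1 <- acquire(list(tr[[1]]), make_sensitivities(1, g, seed = 2), pat, 0)
  est1 <- estimate_sensitivities(kt1)
  expect_lt(max(abs(Mod(est1$maps[, , 1][est1$support]) - 1)), 1e-9)
  # pulsatile phantom, undersampled: RSS still exactly 1 on support
  ph <- stepped_phantom(nx = 16, nc = 3, n_frames = 6, noise_sd = 0.02)
  estp <- estimate_sensitivities(ph$kt)
  rss <- sqrt(apply(Mod(estp$maps)^2, c(1, 2), sum))
  expect_lt(max(abs(rss[estp$support] - 1)), 1e-9)
})

test_that("spatial solve recovers exact low-rank data and stays monotone", {
  ph <- stepped_phantom(nx = 16, nc = 3, n_frames = 8,
                        imaging_lines_per_frame = 4, profile = "plug")
  tsub <- exact_subspace(ph, 2)
  us <- solve_spatial_subspace(ph$kt, ph$sens, tsub,
                               recon_config(L = 2, tol = 1e-10, max_iter = 300))
  ser <- compose(us, tsub, 100)
  expect_lt(rel_err(cbind(ser[[1]]$data, ser[[2]]$data), ph$joint), 1e-8)
  # the residual envelope falls monotonically to the requested tolerance
  # (the per-iteration 2-norm itself may oscillate transiently)
  res <- attr(us, "diagnostics")[[1]]$residuals
  expect_true(attr(us, "diagnostics")[[1]]$converged)
  expect_lt(tail(res, 1), 1e-9)
  expect_lt(min(res) / res[1], 1e-8)
  # all-zero data give a zero spatial subspace without iterating
  zero_kt <- ph$kt
  zero_kt$lines$signal <- lapply(zero_kt$lines$signal, function(s) s * 0)
  us0 <- solve_spatial_subspace(zero_kt, ph$sens, tsub, recon_config(L = 2))
  expect_true(all(us0$u == 0i))
})

test_that("compose obeys the rank-1 and joint-splitting bookkeeping", {
  g <- tiny_grid(4, 4)
  set.seed(2)
  u1 <- matrix(complex(real = rnorm(16), imaginary = rnorm(16)), 16, 1)
  v_row <- matrix(exp(2i * pi * (0:5) / 6) / sqrt(6), 1, 6)
  usub <- spatial_subspace(u1, g, "joint")
  tsub <- temporal_subspace(v_row, "joint", frame_times_ms = c(10, 20, 30),
                            nv = 2)
  ser <- compose(usub, tsub)
  expect_length(ser, 2L)
  expect_equal(ncol(ser[[1]]$data), 3L)
  # every frame is a scalar multiple of u1
  for (v in 1:2) {
    for (m in 1:3) {
      expect_lt(rel_err(ser[[v]]$data[, m],
                        u1[, 1] * v_row[1, (v - 1) * 3 + m]), 1e-12)
    }
  }
  # identity factorisation reproduces a known Casorati matrix exactly
  set.seed(3)
  cc <- matrix(complex(real = rnorm(16 * 6), imaginary = rnorm(16 * 6)), 16, 6)
  tid <- temporal_subspace(diag(6) + 0i, "joint", c(10, 20, 30), nv = 2)
  uid <- spatial_subspace(cc, g, "joint")
  ser2 <- compose(uid, tid)
  expect_identical(ser2[[1]]$data, cc[, 1:3])
  expect_identical(ser2[[2]]$data, cc[, 4:6])
})

test_that("unconstrained reconstruction equals direct Fourier inversion", {
  # fully sampled, noiseless, L = M: the subspace model imposes nothing and
  # the least-squares solution is the coil-combined inverse FFT
  g <- tiny_grid(12, 12)
  geom <- phantom_geometry(g, radius_mm = 3)
  wave <- flow_waveform(seq(0, 0.3, by = 0.1), c(20, 50, 35, 70))
  n_frames <- 4
  slots <- NULL
  tr_ms <- 5
  slot <- 0L
  for (f in seq_len(n_frames)) {
    for (v in 1:2) {
      kys <- c(6L, 0:11)   # one training centre line plus a full sweep
      roles <- c("training", rep("imaging", 12))
      slots <- rbind(slots, data.frame(
        slot = slot + seq_along(kys) - 1L,
        t_ms = (slot + seq_along(kys) - 1L) * tr_ms,
        encoding = v, ky = kys, role = roles))
      slot <- slot + length(kys)
    }
  }
  pat <- sampling_pattern(slots, ny = 12, nv = 2, tr_ms = tr_ms,
                          frame_ms = 2 * 13 * tr_ms)
  ft <- pattern_frame_times(pat)
  truth <- render_truth(geom, flow_waveform(ft / 1000, c(20, 50, 35, 70)),
                        ft, 100)
  sens <- make_sensitivities(3, g, seed = 4)
  kt <- acquire(truth, sens, pat, noise_sd = 0)
  # L equals the frame count, beyond the dynamic rank: the (expected)
  # arbitrary-complement warning is irrelevant to the unconstrained limit
  suppressWarnings(
    rec <- reconstruct(kt, recon_config(L = n_frames, mode = "separate",
                                        tol = 1e-12, max_iter = 500)))
  est <- rec$sens
  for (v in 1:2) {
    for (m in seq_len(n_frames)) {
      k_lines <- kt$lines[kt$lines$encoding == v &
                            floor(kt$lines$t_ms / kt$frame_ms) == m - 1, ]
      combo <- matrix(0i, 12, 12)
      for (i in 1:3) {
        k <- matrix(0i, 12, 12)
        ci <- k_lines[k_lines$coil == i, ]
        for (r in seq_len(nrow(ci))) k[, ci$ky[r] + 1] <- ci$signal[[r]]
        combo <- combo + Conj(est$maps[, , i]) * ktflow:::ift2c(k)
      }
      expect_lt(max(Mod(matrix(rec$series[[v]]$data[, m], 12, 12) - combo)),
                1e-6)
    }
  }
})

test_that("joint reconstruction runs end to end and reports diagnostics", {
  ph <- stepped_phantom(nx = 16, nc = 2, n_frames = 10, values = c(15, 70),
                        imaging_lines_per_frame = 2, noise_sd = 0.03)
  rec <- reconstruct(ph$kt, recon_config(L = 6, mode = "joint", max_iter = 40))
  expect_length(rec$series, 2L)
  expect_equal(ncol(rec$series[[1]]$data), 10L)
  gl <- glance(rec)
  expect_equal(gl$mode, "joint")
  expect_equal(gl$L, 6L)
  expect_true(gl$cg_iterations > 0)
  td <- tidy(rec)
  expect_true(all(c("iteration", "residual") %in% names(td)))
  # separate mode on the same data returns the same shapes
  rec2 <- reconstruct(ph$kt, recon_config(L = 6, mode = "separate",
                                          max_iter = 40))
  expect_length(rec2$series, 2L)
  expect_equal(dim(rec2$series[[1]]$data), dim(rec$series[[1]]$data))
  expect_length(rec2$diagnostics, 2L)
})
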