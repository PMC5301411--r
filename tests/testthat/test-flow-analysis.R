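mk_velocity <- function(value_mat, g, dt_ms = 20, venc = 100) {
  velocity_series(value_mat, dt_ms * seq_len(ncol(value_mat)), g, venc)
}

test_that("ROI-mean waveform reduces correctly", {
  g <- tiny_grid(8, 8)
  roi <- roi_mask(matrix(rep(c(TRUE, FALSE), 32), 8, 8), g)
  vals <- matrix(rep(c(7, -3, 12), each = 64), 64, 3)
  w <- roi_mean_waveform(mk_velocity(vals, g), roi)
  expect_equal(w$value, c(7, -3, 12))
  expect_equal(w$time_s, c(0.02, 0.04, 0.06))
  # single-pixel ROI equals that pixel's series
  one <- matrix(FALSE, 8, 8); one[3, 5] <- TRUE
  set.seed(6)
  vals2 <- matrix(runif(64 * 3, -50, 50), 64, 3)
  w2 <- roi_mean_waveform(mk_velocity(vals2, g), roi_mask(one, g))
  expect_equal(w2$value, vals2[3 + 4 * 8, ])
})

test_that("parabolic phantom ROI mean equals half the centreline", {
  g <- grid2d(64, 64, 1.2)
  geom <- phantom_geometry(g, radius_mm = 12)
  wave <- flow_waveform(c(0, 0.5), c(80, 80), period_s = 1)
  truth <- render_truth(geom, wave, 10, 100, profile = "parabolic")
  vel <- to_velocity(phase_difference(truth[[2]], truth[[1]]), 100)
  w <- roi_mean_waveform(vel, vessel_mask(geom))
  expect_lt(abs(w$value[1] - 40) / 40, 0.02)
})

test_that("beat segmentation finds complete cycles of waveform I", {
  w <- make_waveform(waveform_spec("I", peak_cm_s = 80), duration_s = 10)
  seg <- segment_beats(w)
  expect_equal(nrow(seg), 4L)
  expect_true(all(abs(seg$duration_s - 2) <= 0.02 + 1e-12))
  # constant waveform: no upstrokes, empty segmentation
  flat <- flow_waveform(seq(0, 1, by = 0.1), rep(5, 11))
  expect_equal(nrow(segment_beats(flat)), 0L)
  # two bells 2 s apart: one complete cycle, trailing partial discarded
  t <- seq(0, 3.99, by = 0.02)
  two <- flow_waveform(t, 50 * (sin(pi * pmin(t %% 2, 1))^2))
  seg2 <- segment_beats(two, min_period_s = 1)
  expect_equal(nrow(seg2), 1L)
})

test_that("cycle averaging is idempotent, cancels and aligns durations", {
  # identical cycles: average equals one cycle
  w <- make_waveform(waveform_spec("I", peak_cm_s = 60), duration_s = 8)
  seg <- segment_beats(w)
  avg <- average_cycles(w, seg, n_points = 101)
  one <- stats::approx(w$time_s - seg$t_start_s[1], w$value,
                       xout = avg$time_s)$y
  expect_lt(max(abs(avg$value - one)), 0.6)
  expect_equal(max(avg$value), 60, tolerance = 0.01)
  # two cycles that are negatives of each other average to zero
  t <- seq(0, 1.0, by = 0.1)
  vals <- c(sin(pi * (0:4) / 4), -sin(pi * (0:4) / 4), 0)
  wav <- flow_waveform(t, vals)
  seg2 <- tibble::tibble(cycle = 1:2, start = c(1L, 6L), end = c(6L, 11L),
                         t_start_s = t[c(1, 6)], t_end_s = t[c(6, 11)],
                         duration_s = c(0.5, 0.5))
  class(seg2) <- c("beat_segmentation", class(seg2))
  avg2 <- average_cycles(wav, seg2, n_points = 5)
  expect_lt(max(abs(avg2$value)), 1e-12)
  # durations 1.8 s and 2.2 s with one normalised shape -> 2.0 s mean
  shape <- function(u) 30 + 40 * sin(pi * u)^2
  t1 <- seq(0, 1.8, by = 0.01); t2 <- seq(0, 2.2, by = 0.01)
  big <- flow_waveform(c(t1, 1.8 + t2[-1]),
                       c(shape(t1 / 1.8), shape(t2[-1] / 2.2)))
  seg3 <- tibble::tibble(cycle = 1:2, start = c(1L, length(t1)),
                         end = c(length(t1), length(big$value)),
                         t_start_s = c(0, 1.8), t_end_s = c(1.8, 4.0),
                         duration_s = c(1.8, 2.2))
  class(seg3) <- c("beat_segmentation", class(seg3))
  avg3 <- average_cycles(big, seg3, n_points = 200)
  expect_equal(waveform_period(avg3), 2.0)
  expect_lt(max(abs(avg3$value - shape(avg3$time_s / 2))) / 70, 0.01)
})

test_that("peak velocity reports per-cycle and overall maxima", {
  flat <- flow_waveform(seq(0, 1, by = 0.1), rep(42, 11))
  expect_equal(peak_velocity(flat), 42)
  w <- make_waveform(waveform_spec("I", peak_cm_s = 77), duration_s = 10)
  seg <- segment_beats(w)
  pk <- peak_velocity(w, seg)
  expect_equal(pk$peak, rep(77, nrow(pk)))
  w2 <- make_waveform(waveform_spec("II", peak_cm_s = 80,
                                    second_peak_ratio = 0.6), duration_s = 12)
  pk2 <- peak_velocity(w2, segment_beats(w2))
  big <- pk2$peak[pk2$peak > 60]; small <- pk2$peak[pk2$peak <= 60]
  expect_gt(length(big), 0); expect_gt(length(small), 0)
  expect_equal(mean(small) / mean(big), 0.6, tolerance = 0.01)
})

test_that("stroke volume matches its closed form and is additive", {
  # uniform 10 cm/s over exactly 1 cm^2 for exactly 1 s -> 10 mL
  g <- grid2d(10, 10, pixel_mm = sqrt(1 / 25) * 10)  # pixel 2 mm -> 0.04 cm^2
  roi <- roi_mask(matrix(c(rep(TRUE, 25), rep(FALSE, 75)), 10, 10), g)
  expect_equal(sum(roi$mask) * ktflow::pixel_area(g, "cm2"), 1)
  vals <- matrix(10, 100, 10)   # 10 frames at 100 ms -> 1 s
  vel <- velocity_series(vals, 100 * (1:10), g, 100)
  expect_equal(stroke_volume(vel, roi, c(1, 11)), 10)
  expect_equal(stroke_volume(velocity_series(0 * vals, 100 * (1:10), g, 100),
                             roi, c(1, 11)), 0)
  # linear in velocity
  expect_equal(stroke_volume(velocity_series(3 * vals, 100 * (1:10), g, 100),
                             roi, c(1, 11)), 30)
  # additive over a disjoint ROI partition
  m1 <- matrix(FALSE, 10, 10); m1[1:2, 1:5] <- TRUE
  m2 <- matrix(FALSE, 10, 10); m2[3:5, 1:5] <- TRUE
  set.seed(3)
  rnd <- velocity_series(matrix(runif(1000, -20, 20), 100, 10),
                         100 * (1:10), g, 100)
  expect_equal(stroke_volume(rnd, roi_mask(m1 | m2, g), c(2, 8)),
               stroke_volume(rnd, roi_mask(m1, g), c(2, 8)) +
                 stroke_volume(rnd, roi_mask(m2, g), c(2, 8)))
})

test_that("stroke volume integrates the generator waveform", {
  g <- grid2d(64, 64, 1.2)
  geom <- phantom_geometry(g, radius_mm = 7.5)
  spec <- waveform_spec("I", peak_cm_s = 80, baseline_cm_s = 10)
  wave <- make_waveform(spec, duration_s = 4)
  ft <- seq(10, 3990, by = 20)
  truth <- render_truth(geom, wave, ft, 100)
  vel <- to_velocity(phase_difference(truth[[2]], truth[[1]]), 100)
  roi <- vessel_mask(geom)
  sv <- stroke_volume(vel, roi, c(1, 101))  # exactly the first 2 s cycle
  # oracle: time integral of the waveform times the discretised lumen area
  area_cm2 <- sum(roi$mask) * ktflow::pixel_area(g, "cm2")
  oracle <- sum(wave$value[wave$time_s < 2]) * 0.02 * area_cm2
  expect_lt(abs(sv - oracle) / oracle, 0.03)
})

test_that("folding reproduces periodic cycles and distorts aperiodic ones", {
  # exact-period folding reproduces one cycle
  w <- make_waveform(waveform_spec("I", peak_cm_s = 70), duration_s = 8)
  folded <- fold_to_cycle(w, 2)
  # samples fall on the bin left edges here, so compare there exactly
  ref <- stats::approx(w$time_s[w$time_s < 2], w$value[w$time_s < 2],
                       xout = folded$time_s - 0.01, rule = 2)$y
  expect_lt(max(abs(folded$value - ref)), 1e-9)
  expect_equal(max(folded$value), 70, tolerance = 0.02)
  # constant waveform folds to a constant
  flat <- flow_waveform(seq(0, 5, by = 0.05), rep(9, 101))
  expect_true(all(fold_to_cycle(flat, 2)$value == 9))
  # waveform II folded at 2 s: single peak strictly between the two bells
  w2 <- make_waveform(waveform_spec("II", peak_cm_s = 80,
                                    second_peak_ratio = 0.6), duration_s = 12)
  f2 <- fold_to_cycle(w2, 2)
  expect_lt(max(f2$value), 80)
  expect_gt(max(f2$value), 48)
  # while per-cycle analysis of the unfolded record recovers both peaks
  pk <- peak_velocity(w2, segment_beats(w2))
  expect_equal(max(pk$peak), 80, tolerance = 1e-6)
  expect_equal(min(pk$peak), 48, tolerance = 1e-6)
})

test_that("SNR and VNR follow their ROI definitions", {
  g <- tiny_grid(8, 8)
  img <- matrix(0i, 64, 1)
  roi_m <- matrix(FALSE, 8, 8); roi_m[3:4, 3:4] <- TRUE
  bg_m <- matrix(FALSE, 8, 8); bg_m[7:8, 7:8] <- TRUE
  img[as.vector(roi_m), 1] <- 10 + 0i
  img[as.vector(bg_m), 1] <- c(1, 3, 1, 3)  # sd = 2/sqrt(3) * ...
  ser <- image_series(img, 10, g)
  got <- snr(ser, 1, roi_mask(roi_m, g), roi_mask(bg_m, g))
  expect_equal(got, 10 / sd(c(1, 3, 1, 3)))
  # scale invariance
  ser2 <- image_series(5 * img, 10, g)
  expect_equal(snr(ser2, 1, roi_mask(roi_m, g), roi_mask(bg_m, g)), got)
  # VNR definition and zero-flow case
  vel <- matrix(0, 64, 1)
  vel[as.vector(roi_m), 1] <- 50
  vel[as.vector(bg_m), 1] <- c(-5, 5, -5, 5)
  vs <- velocity_series(vel, 10, g, 100)
  expect_equal(vnr(vs, 1, roi_mask(roi_m, g), roi_mask(bg_m, g)),
               50 / sd(c(-5, 5, -5, 5)))
  vzero <- velocity_series(matrix(c(rep(0, 60), -5, 5, -5, 5), 64, 1), 10, g, 100)
  expect_equal(vnr(vzero, 1, roi_mask(roi_m, g), roi_mask(bg_m, g)), 0)
  # overlapping masks are rejected
  expect_error(snr(ser, 1, roi_mask(roi_m, g), roi_mask(roi_m, g)),
               class = "ktflow_validation_error")
})

test_that("bland_altman matches a direct arithmetic oracle", {
  a <- c(1, 2, 3, 4); b <- c(1.1, 1.9, 3.2, 3.8)
  ba <- bland_altman(a, b)
  d <- a - b
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$sd_diff, sd(d))
  expect_equal(ba$loa_lower, mean(d) - 1.96 * sd(d))
  expect_equal(ba$loa_upper, mean(d) + 1.96 * sd(d))
  expect_equal(ba$pearson_r, cor(a, b))
  # paired t-test cross-check against the reference implementation
  tt <- stats::t.test(a, b, paired = TRUE)
  expect_equal(ba$t_stat, unname(tt$statistic))
  expect_equal(ba$p_value, tt$p.value)
  expect_equal(ba$n, 4L)
  td <- tidy(ba)
  expect_equal(td$estimate[td$term == "bias"], mean(d))
  gl <- glance(ba)
  expect_equal(gl$pearson_r, cor(a, b))
})

test_that("bland_altman handles degenerate and shifted pairs", {
  same <- bland_altman(c(2, 5, 9), c(2, 5, 9))
  expect_equal(same$bias, 0)
  expect_equal(same$loa_lower, 0)
  expect_equal(same$loa_upper, 0)
  shifted <- bland_altman(c(2, 5, 9) + 1, c(2, 5, 9))
  expect_equal(shifted$bias, 1)
  expect_equal(shifted$loa_lower, 1)
  expect_equal(shifted$loa_upper, 1)
  const <- bland_altman(c(3, 3, 3), c(1, 2, 3))
  expect_true(is.na(const$pearson_r))
  expect_error(bland_altman(1, 1), class = "ktflow_validation_error")
  expect_error(bland_altman(1:3, 1:4), class = "ktflow_validation_error")
})

test_that("bias of same-distribution pairs vanishes as n grows", {
  set.seed(11)
  biases <- vapply(c(50, 500, 5000), function(n) {
    abs(bland_altman(rnorm(n), rnorm(n))$bias)
  }, numeric(1))
  expect_lt(biases[3], 0.05)
  expect_lt(biases[3], biases[1] + 0.05)
})
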