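# Shared builders for small in-memory phantom instances.

tiny_grid <- function(nx = 16, ny = 16, pixel_mm = 1.2) grid2d(nx, ny, pixel_mm)

# A stepped plug/parabolic phantom whose waveform takes `q` distinct values,
# giving an exactly low-rank joint Casorati matrix.
stepped_phantom <- function(nx = 32, nc = 4, n_frames = 8,
                            imaging_lines_per_frame = 8,
                            values = c(10, 60), profile = "plug",
                            venc = 100, noise_sd = 0, seed = 7) {
  g <- grid2d(nx, nx, 1.2)
  geom <- phantom_geometry(g, radius_mm = 0.2 * nx)
  pat <- make_interleaved_pattern(nx, 2, 5, n_frames = n_frames,
                                  imaging_lines_per_frame = imaging_lines_per_frame,
                                  seed = seed)
  ft <- pattern_frame_times(pat)
  # sample the stepped waveform exactly at the frame times so each frame
  # carries one of the q values (keeps the joint Casorati exactly low rank)
  wave <- flow_waveform(ft / 1000, rep_len(values, length(ft)))
  truth <- render_truth(geom, wave, ft, venc, profile = profile)
  sens <- make_sensitivities(nc, g, seed = seed + 1)
  kt <- acquire(truth, sens, pat, noise_sd = noise_sd, seed = seed + 2)
  joint <- cbind(truth[[1]]$data, truth[[2]]$data)
  list(grid = g, geometry = geom, wave = wave, pattern = pat,
       frame_times = ft, truth = truth, sens = sens, kt = kt, joint = joint)
}

# exact temporal subspace of the true joint Casorati matrix
exact_subspace <- function(ph, L) {
  v <- Conj(t(svd(ph$joint)$v[, seq_len(L), drop = FALSE]))
  temporal_subspace(v, "joint", ph$frame_times, nv = 2L)
}

rel_err <- function(a, b) sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))

# standard phantom-protocol simulation used by the heavier end-to-end tests
protocol_sim <- function(kind = "I", duration_s = 10, nx = 64, nc = 8,
                         noise_sd = 0.05, seed = 5) {
  g <- grid2d(nx, nx, 1.2)
  geom <- phantom_geometry(g, radius_mm = 7.5)
  spec <- waveform_spec(kind)
  wave <- make_waveform(spec)
  n_frames <- floor(1000 * duration_s / nominal_temporal_resolution(2, 5))
  pat <- make_interleaved_pattern(nx, 2, 5, n_frames = n_frames, seed = seed)
  truth <- render_truth(geom, wave, pattern_frame_times(pat), 100)
  sens <- make_sensitivities(nc, g, seed = seed + 1)
  kt <- acquire(truth, sens, pat, noise_sd = noise_sd, seed = seed + 2)
  list(grid = g, geometry = geom, spec = spec, wave = wave, pattern = pat,
       truth = truth, sens = sens, kt = kt)
}
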