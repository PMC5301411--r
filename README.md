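# ktflow

Real-time (ungated) 2D phase-contrast flow MRI reconstruction and analysis
in R, built around a **joint low-rank Casorati model with SENSE parallel
imaging**, plus a digital pulsatile-flow phantom so the whole method can be
exercised and validated without scanner data.

## Who this is for

Researchers developing or evaluating dynamic MRI reconstruction — in
particular flow quantification where ECG gating breaks down (arrhythmia,
beat-to-beat variability) — and anyone needing a reproducible, scriptable
reference implementation of subspace-constrained (k,t) reconstruction with
flow analytics.

## The method

Each velocity encoding's image sequence is a Casorati matrix
`C_v ∈ C^(N×M)` (voxels × frames); the encodings are concatenated into the
joint matrix `C = [C_1, …, C_Nv]`, factorised as `C = U V` with rank
`L ≪ min(N, Nv·M)`. An interleaved Cartesian schedule acquires one central
**training** line and randomly placed outer **imaging** lines per encoding
per frame (nominal temporal resolution `2·Nv·TR`: 18 ms at TR = 4.5 ms,
20 ms at TR = 5.0 ms). The temporal basis `V̂` comes from PCA of the
temporally interpolated training channels; the spatial factor solves the
convex SENSE least-squares problem

```
Û = argmin_U Σ_i ‖ d_i − Ω[F S_i (U V̂)] ‖²
```

by conjugate gradient (compiled FFTW hot path). Velocities follow from the
phase difference of the flow-encoded and flow-compensated series,
`V = Δφ/π · VENC`, after polynomial background-phase (eddy-current)
correction. Flow analytics cover ROI waveforms, beat segmentation, cycle
averaging, per-beat peak velocity and stroke volume, a retrospective-gating
surrogate (`fold_to_cycle()`), SNR/VNR, and Bland–Altman agreement with a
paired t-test.

## Worked example

Simulate the pulsatile phantom protocol (64×64 at 1.2 mm, 15-mm vessel,
waveform I: 1 s bell to 80 cm/s then 1 s at 10 cm/s, Nv = 2, TR = 5 ms,
VENC = 100 cm/s, 8 coils, 10 s of data), reconstruct with the joint rank-20
model, and analyse the flow:

```r
library(ktflow)

cfg <- run_config(duration_s = 10, seed = 5)
run_simulate(cfg, "out")                                # raw.h5 + truth
run_recon("out/raw.h5", cfg, "out")                     # joint, L = 20
res <- run_analyze("out/recon_encoding1.h5",
                   "out/recon_encoding2.h5", cfg, "out")
str(res$report)
#> List of 8
#>  $ stage                : chr "analyze"
#>  $ n_frames             : int 500
#>  $ n_cycles             : int 4
#>  $ peak_velocity_overall: num 80.9
#>  $ per_cycle_peaks      : num [1:4] 80.2 80.9 78.8 80.4
#>  $ per_cycle_volumes_ml : num [1:4] 93.8 94.9 95.4 94
#>  $ snr                  : num 35.9
#>  $ vnr                  : num 27.3
```

Reading the numbers: the 10 s record contains 4 complete cardiac cycles of
the 2 s waveform; every per-cycle peak velocity sits within ~1.5% of the
programmed 80 cm/s even though each 20 ms frame was reconstructed from two
k-space lines per encoding. The per-cycle stroke volumes (≈94 mL against a
discretised-lumen oracle of ≈95 mL) integrate velocity × lumen area over
each beat. SNR/VNR are the ROI-over-background ratios computed on the peak
systolic frame.

Individual stages are plain functions on tidy objects if you want the
pieces: `make_interleaved_pattern()`, `render_truth()`, `acquire()`,
`reconstruct()`, `phase_difference()`, `to_velocity()`,
`roi_mean_waveform()`, `segment_beats()`, `bland_altman()` (with
`tidy()`/`glance()` methods), and `autoplot()` for waveforms, patterns and
Bland–Altman plots. A thin CLI over the same stages ships in
`inst/cli/ktflow`.

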