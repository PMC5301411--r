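---
title: "Real-time phase-contrast flow MRI with a joint low-rank subspace model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Real-time phase-contrast flow MRI with a joint low-rank subspace model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ktflow)
```

## The problem

Phase-contrast cardiovascular MR quantifies blood velocity by encoding it in
the image phase: a flow-compensated and a flow-encoded acquisition are
interleaved, and their phase difference at a voxel maps linearly to
through-plane velocity, with a phase of $\pi$ corresponding to the encoding
velocity VENC. Conventional cine flow imaging relies on ECG gating: data from
many heartbeats are retrospectively sorted into one averaged cardiac cycle.
That fails outright when the flow is not periodic — arrhythmia, ectopic
beats, exercise — because folding aperiodic beats into one synthetic cycle
averages unrelated flow states and reports peaks that belong to no actual
beat.

Real-time (ungated) imaging avoids the assumption but must reconstruct each
frame from a tiny fraction of k-space. `ktflow` implements a model-based
route: the dynamic image sequences are assumed to be jointly low rank, the
temporal subspace is estimated from rapidly repeated central-k-space
*training* lines, and the spatial component is recovered from randomly
sampled outer *imaging* lines through a SENSE parallel-imaging model.

## The model

Write each encoding's image sequence as a Casorati matrix
$C_v \in \mathbb{C}^{N \times M}$ (voxels by frames), and concatenate the
encodings into the joint matrix $C = [C_1, \dots, C_{N_v}]$. Flow images are
spatiotemporally correlated both within and across encodings, so $C$ admits
a low-rank factorisation $C = U V$ with $U \in \mathbb{C}^{N \times L}$,
$V \in \mathbb{C}^{L \times N_v M}$ and small $L$. Multi-coil data follow

$$ d_i = \Omega\left[ F\, S_i\, (U V) \right] + \eta_i, $$

with $S_i$ the coil sensitivities, $F$ the (unitary, centred) spatial
Fourier transform, $\Omega$ the sampling operator and $\eta_i$ complex
Gaussian noise. Jointly estimating $U$ and $V$ is non-convex; the package
instead pre-estimates $\hat V$ as the leading right singular vectors (PCA)
of the temporally interpolated training data and then solves the convex
least-squares problem

$$ \hat U = \arg\min_U \sum_{i=1}^{N_c}
   \left\lVert d_i - \Omega\left[F S_i (U \hat V)\right] \right\rVert_2^2 $$

by conjugate gradient on the normal equations. The reconstruction is
$\hat C = \hat U \hat V$, split back into per-encoding series, from which
velocity maps follow as $\mathrm{V}(r,t) = \Delta\phi(r,t)/\pi \cdot$VENC.

Two modes are exposed. In **joint** mode one $(U, V)$ pair spans all
encodings — the model the package exists for. In **separate** mode each
encoding gets its own rank-$L$ factorisation; it reconstructs the same data
with twice the degrees of freedom and a temporal basis estimated from half
the training rows, and serves as the comparison arm: on matched synthetic
experiments the joint model yields visibly higher SNR and VNR, which the
acceptance suite checks as a statistical expectation over ten noise
realisations.

## Sampling design and temporal resolution

The interleaved Cartesian schedule acquires, per reconstruction frame and
per encoding, one training line from the central ky band and (by default)
one imaging line drawn uniformly at random without replacement from the
outer lines, re-shuffling when a sweep is exhausted. The same random ky
schedule is applied to every encoding. One line is acquired per TR, so a
frame spans $2 N_v \cdot$TR: 18 ms at TR = 4.5 ms and 20 ms at TR = 5.0 ms
for one-directional encoding ($N_v = 2$). `make_interleaved_pattern()` also
accepts more imaging lines per frame (the frame period generalises to
$N_v (1 + k)\,$TR), which the test suite uses to build moderately
undersampled, exactly-determined instances; the protocol default remains
one.

The training band defaults to the single centre line: temporal subspace
estimation needs temporal, not spatial, diversity, and every readout sample
of every coil on that line is an independent channel observing the same
temporal dynamics. A configurable half-width is available.

## The digital phantom

The generator emulates the pump-driven flow phantom used to validate such
methods: a circular vessel (default radius 7.5 mm, i.e. a 15-mm tube) in a
static-tissue ellipse, unit magnitude, with through-plane velocity painted
into the encoded phase. Two waveform programs are built in, both with a
raised-cosine "bell" — smooth and parameter-free, chosen because only the
qualitative bell shape is prescribed:

* **Waveform I** (periodic): a 1 s bell followed by constant baseline flow,
  repeating every 2 s.
* **Waveform II** (aperiodic for a 2 s gating assumption): two different
  1 s bells per 4 s period, the second peaking at a configurable fraction
  (default 0.6) of the first.

Amplitudes are not printed in the protocol this phantom mirrors; the
defaults — 80 cm/s peak, 10 cm/s baseline at VENC = 100 cm/s — are
physiologically plausible aortic values that stay below VENC, and are fixed
once here rather than tuned. The velocity profile is plug by default (a
blunt profile is typical for pump phantoms and large vessels); a parabolic
(Poiseuille) option exists, whose full-vessel ROI mean is analytically half
the centreline value — a property the tests exploit.

Coil maps are smooth Gaussian-bump magnitudes with slowly varying phase,
RSS-normalised; noise is i.i.d. complex Gaussian with `noise_sd` the
standard deviation per complex sample (each component gets
$\sigma/\sqrt{2}$). The default `noise_sd = 0.05` against unit magnitude
corresponds to an image-domain SNR of 20 under fully sampled unitary-FFT
reconstruction — deliberately conservative for a surface coil array.

What the phantom does *not* emulate: respiratory and bulk motion,
through-plane inflow enhancement, intra-voxel dephasing, off-resonance, and
continuous inter-frame motion (each line is drawn from the nearest rendered
frame, matching the discrete image model). Passing tests therefore
demonstrate correctness of the algorithmic chain under the stated forward
model, not robustness to every in vivo effect.

## Numerical choices

* **FFT convention**: unitary and centred in both directions, origin at the
  0-based index $n/2$; the adjoint equals the inverse, which makes the
  operator adjoint test exact.
* **Solver**: CG on the normal equations from zero initialisation, relative
  residual tolerance $10^{-6}$, at most 100 iterations. The readout
  direction is always fully sampled, so data are moved once into hybrid
  $(x, k_y)$ space — a unitary change of variables that leaves the
  least-squares solution unchanged — and the hot operator applies only
  length-$n_y$ FFTs (compiled, FFTW). The per-iteration 2-norm residual can
  oscillate transiently (only the A-norm error is monotone for CG), so the
  solver keeps the best iterate, stops on stagnation at the numerical
  floor, and raises an error only on genuine divergence.
* **Rank**: default $L = 20$, the value used for the joint-versus-separate
  comparison this package reproduces; raising $L$ buys representational
  power at the cost of noise and conditioning, and the choice is exposed in
  `recon_config()`.
* **Temporal interpolation**: linear per channel (real and imaginary parts
  independently), edges clamped. At one training line per 18-20 ms frame
  the training rate is far above cardiac bandwidth, so linear suffices;
  cubic is available behind the config flag.
* **PCA on k-space channels**: the temporal subspace is invariant under any
  fixed spatial linear map, so right singular vectors of raw training
  channels equal those of any interim image reconstruction; estimating them
  directly avoids committing to one.
* **Sensitivities**: temporally averaged flow-compensated k-space,
  zero-filled, Hann-tapered over the filled ky band *only when the band is
  incomplete* (a complete average has no truncation edge to apodise),
  inverse FFT, RSS normalisation, support at 5% of the peak RSS. Outside
  the support the maps are zero, which pins the reconstruction to zero
  there — one consequence is that an SNR background region placed outside
  the support is degenerate (zero variance, reported as `Inf`).
* **Phase correction**: static tissue is detected as high-magnitude voxels
  with temporal phase standard deviation below 0.1 rad; a polynomial
  (default order 2) is fit to the temporal-mean phase difference over that
  mask and subtracted everywhere. The thresholds are conventional and
  config-exposed. No temporal unwrapping is attempted; velocities beyond
  VENC alias, and the package documents rather than repairs this.
* **Beat segmentation**: upward crossings of 30% of the global maximum with
  a 0.4 s refractory period — the simplest reproducible rule; both knobs
  are arguments.

## Problem sizes used in validation

The test suite exercises the full chain at deliberately modest sizes chosen
to keep a complete run comfortable on a single CPU: exact-recovery and
operator tests at 16–32 pixels; the waveform-I parameter-recovery and
waveform-II cine-failure experiments at $64 \times 64$, 8 coils, 10 s of
data (500 frames at 20 ms); the joint-versus-separate comparison at
$32 \times 32$, 4 coils, 10 noise realisations. These mirror the published
protocol's geometry at reduced matrix size; the mechanisms under test
(subspace estimation, SENSE data consistency, phase-difference velocimetry,
beat analytics) do not change with matrix size.

## Known limitations

* Single 2D slice, one-directional through-plane encoding ($N_v = 2$);
  no 3D/4D flow.
* No regularisation beyond the rank constraint (no sparsity term), no coil
  compression, no non-convex joint $(U, V)$ refinement.
* Velocity aliasing is not unwrapped.
* The cine comparison inside the package is a folding surrogate
  (`fold_to_cycle()`), not a full simulated gated acquisition.
* The raw-data HDF5 layout mirrors ISMRMRD naming where a one-to-one
  mapping exists but is not a compliant ISMRMRD file.
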