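Package: ktflow
Title: Real-Time Phase-Contrast Flow MRI with Joint Low-Rank Subspace
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstruction and analysis of real-time (ungated) 2D
    phase-contrast flow MRI from undersampled multi-coil (k,t)-space data.
    Implements a joint low-rank Casorati model across the flow-compensated
    and flow-encoded image sequences, with the temporal subspace estimated
    by principal component analysis of interleaved central-k-space training
    lines and the spatial subspace recovered by a SENSE-integrated
    conjugate-gradient least-squares solve. Includes a digital pulsatile
    flow phantom with programmable bell-shaped waveforms, interleaved
    training/imaging Cartesian sampling-pattern generation, velocity
    mapping with polynomial background-phase correction, and flow
    quantification (beat segmentation, cycle averaging, peak velocity,
    stroke volume, retrospective-gating surrogate, SNR/VNR, Bland-Altman
    agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rhdf5,
    rlang,
    RNifti,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
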