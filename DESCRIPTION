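Package: ssvepwave
Title: Phase Locking and Traveling-Wave Analysis of Steady-State Visual
    Evoked Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for the generation and scalp propagation of
    high-frequency steady-state visual evoked potentials (SSVEPs) recorded
    with multichannel EEG.  Provides a synthetic traveling-wave EEG
    generator with known ground truth, preprocessing (zero-phase line-noise
    notch, anti-aliased decimation, spherical-spline surface Laplacian,
    stimulus-locked epoching), event-related synchronization maps,
    narrowband equiripple FIR filtering with group-delay correction,
    Hilbert-transform instantaneous phase, stimulus-locked phase-locking
    values with trial-shuffled surrogate statistics, locking-delay source
    identification, and phase-gradient estimation of propagation velocity
    and wavelength on a spherical head model.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    tools,
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    geosphere,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
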