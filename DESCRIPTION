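Package: megdot
Title: Simulation and Correlation Analysis of Simultaneous MEG and
    Diffuse Optical Tomography Somatosensory Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the coupling between magnetoencephalographic
    (MEG) somatosensory evoked responses and hemodynamic responses imaged with
    high-density diffuse optical tomography (DOT). Provides a seeded synthetic
    data generator (median-nerve stimulus trains, equivalent-current-dipole
    waveforms with frequency-dependent habituation, a layered head phantom
    with analytic diffusion sensitivity kernels, and noisy two-wavelength
    optical recordings with a configurable neurovascular coupling ground
    truth); MEG dipole feature extraction (N20m, P35m, P60m, SII and RMS
    features); canonical-HRF convolution prediction of hemodynamic regressors;
    Laplacian-regularized Tikhonov reconstruction of absorption and hemoglobin
    images with FIR deconvolution of block responses; correlation-based
    cluster statistics with Fisher z group tests, Bonferroni correction and a
    null-calibration routine for the minimum cluster volume; and atlas and
    point-cloud head registration with a combined surface and landmark error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    MASS
Config/testthat/edition: 3
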