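Package: orfieeg
Title: Simulation and Statistical Analysis of Outcome-Monitoring EEG in
    Deterministic Reversal Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate a deterministic reversal-learning task with
    SAME/SIMI/DIFF outcome categories, generate multi-subject synthetic
    high-density EEG (156 channels, 1000 Hz) through an analytic
    spherical-head dipole forward model, and reproduce a complete
    outcome-monitoring analysis chain: FIR band-pass and average-reference
    preprocessing with amplitude-based epoch rejection and spherical-spline
    channel interpolation; mass-univariate 2x3 repeated-measures ANOVA with
    Greenhouse-Geisser correction and spatiotemporal extent thresholding;
    electrode-cluster paired-t tests with temporal cluster-permutation
    correction; Hanning short-time Fourier time-frequency power with dB
    baseline correction and 2-D cluster statistics; and scalar
    minimum-variance beamformer source power maps with SnPM-style spatial
    cluster correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deldir,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    RNifti,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
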