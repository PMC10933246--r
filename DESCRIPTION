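Package: dmirep
Title: Simulation and Repeatability Analysis for Deuterium Metabolic Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for assessing the test-retest repeatability of deuterium
    metabolic imaging (DMI) of the brain at clinical field strength. Provides
    a synthetic-study generator that emulates a 3D chemical-shift-imaging
    acquisition of the four deuterium resonances (water, glucose,
    glutamate+glutamine, lactate) with subject- and session-level variance
    components; spectral reconstruction (FFT with zero filling);
    Marchenko-Pastur principal-component denoising with automatic rank
    selection; prior-knowledge time-domain Lorentzian fitting with
    Cramer-Rao lower bounds and voxel quality control; saturation,
    partial-volume (Richardson-Lucy) and bias-field corrections; baseline,
    phantom and cerebellum quantification; and within-/between-subject
    coefficient-of-variation, repeatability-coefficient and Bland-Altman
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
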