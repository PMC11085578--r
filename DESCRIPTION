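Package: sodiumQA
Title: Simulation-Based Quality Assurance for Quantitative Sodium (23Na) MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-testable re-creation of a quantitative sodium (23Na) MRI
    quality-assurance setup at 3 Tesla. Provides a digital dilution phantom
    (thirteen cylindrical saline vials in three sizes at a two-fold dilution
    series plus a central 154 mM reference), a 3D radial golden-angle k-space
    simulator with FLASH steady-state amplitude, bi-exponential transverse
    decay and calibrated complex Gaussian noise, density-compensated gridding
    (adjoint NUFFT) reconstruction with translation alignment, automatic ROI
    statistics and noise-anchored linear-regression conversion of image
    intensity to sodium concentration, intra-/inter-day repeatability analysis
    via the coefficient of variation, and radiofrequency-coil bench-test
    arithmetic (perturbing-sphere sensitivity, quality factor, Larmor
    frequency, Ernst angle, scan time).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    Rcpp,
    RNifti,
    yaml,
    jsonlite,
    rlang
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'sodiumQA-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'phantom.R'
    'acquisition.R'
    'bench.R'
    'recon.R'
    'config.R'
    'quantify.R'
    'io.R'
    'repeatability.R'
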