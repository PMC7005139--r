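Package: hbdot
Title: Hierarchical Bayesian Diffuse Optical Tomography for Resting-State
    Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate high-density multi-distance functional
    near-infrared spectroscopy (fNIRS) recordings with known cortical
    connectivity and scalp interference, to reconstruct volumetric
    hemodynamic changes by diffuse optical tomography with three inverse
    algorithms (a two-step hierarchical Bayesian solver that estimates
    scalp and cortical compartments simultaneously, and two
    depth-compensated minimum-norm variants), and to quantify
    resting-state functional connectivity from the reconstructions via
    ROI partial correlations, together with the similarity and
    test-retest reliability statistics (Fisher-z matrix similarity,
    ICC(C,1)/ICC(C,k), split-half designs, ANOVA with Tukey-Kramer
    comparisons) used to compare the algorithms.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
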