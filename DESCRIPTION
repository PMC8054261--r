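Package: discgrowth
Title: Growth Kinetics, Dose Response and Scaffold Segmentation for
    High-Content Imaging of Cancer Cells on ECM Discs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of high-content imaging experiments in
    which colorectal cancer cells grow on extracellular-matrix scaffold
    discs under multifactorial microenvironmental perturbations (oxygen
    tension, substrate stiffness, drug dose).  Provides texture-based
    segmentation of scaffold discs in well-scan images (local standard
    deviation filtering, light-profile candidates, morphological
    refinement with an automated parameter-sweep selector), co-registration
    of cell centroids with the disc mask, exponential growth-rate
    extraction from time-series live-cell counts by damped nonlinear least
    squares, IC50 estimation by linear interpolation on a log-concentration
    scale, and the comparative statistics used for such screens: the exact
    two-sided sign test, hierarchical Bayesian growth-rate models and
    empirical-Bayes IC50-difference models with Cauchy-prior scales, and
    Welch t tests.  A seeded synthetic-data generator emulates well images,
    detection tables, growth curves, dilution series and multi-experiment
    rate tables with known ground truth, and an end-to-end pipeline runner
    ties the stages together reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    lme4
Config/testthat/edition: 3
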