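Package: cmraudit
Title: Fairness Auditing of Cardiac MR Segmentation with Synthetic Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing demographic bias in convolutional
    segmentation models for short-axis cine cardiac magnetic resonance (CMR).
    Generates two-group synthetic SAX phantoms in which the location and
    magnitude of every group-level distributional shift (subcutaneous fat,
    ghosting artefacts, heart geometry, covariates) is known by construction;
    trains small residual classifiers and U-shaped encoder-decoder segmenters
    from scratch; and provides channel-combination classification audits,
    GradCAM attribution-region taxonomies, crop/blur interventions,
    training-set imbalance sweeps with per-group Dice comparisons,
    latent-space demographic probes, and confounder regression on Dice scores.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    RNifti,
    EBImage,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
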