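Package: ratvbm
Title: Voxel-Based Group Analysis of Rodent Structural MRI with Venous
    Sinus Caliber Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A reusable pipeline for group analysis of anisotropic rodent
    brain structural MRI. Provides atlas-guided skull stripping, bias-field
    correction, rigid/affine spatial normalization to a common atlas space,
    region-based group statistics with false-discovery-rate control,
    voxel-based morphometry with permutation-calibrated cluster-extent
    thresholding, contrast-enhanced difference imaging, a sphere-growing
    estimator of venous sinus diameter, and quality control for interslice
    gap confounds. Includes a synthetic phantom generator that emulates
    multi-subject, multi-session studies with anisotropic slicing, bias
    fields, pose variation and injected vascular effects, so that every
    stage of the pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
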