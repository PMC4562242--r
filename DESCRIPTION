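Package: decodelight
Title: Searchlight and ROI Multi-Voxel Pattern Decoding with
    Permutation-Based Group Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for multi-voxel pattern analysis (MVPA) of event-related
    fMRI. Implements trial-wise response-amplitude estimation with the
    least-squares-separate (LSS) scheme, Gaussian naive Bayes decoding under
    leave-one-run-out cross-validation with per-sample z-normalization,
    trial balancing and one-way-ANOVA feature selection, spherical
    searchlight accuracy mapping with a compiled inner loop, and group-level
    significance testing by within-run label permutation and bootstrap
    resampling with voxelwise thresholding, cluster-size null distributions
    and Benjamini-Hochberg cluster correction. A seeded synthetic-data
    generator produces event tables, motion confounds, behavioral responses
    and 4D BOLD volumes with condition-specific multivoxel patterns so the
    whole pipeline is testable end to end without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    e1071,
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
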