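Package: dynfnc
Title: Static and Dynamic Functional Network Connectivity of IC Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of resting-state independent-component (IC) time courses:
    static functional network connectivity (Pearson + Fisher z, network-level
    aggregation), tapered sliding-window dynamic connectivity with L1-regularized
    inverse-covariance (graphical lasso) estimation, k-means brain-state analysis
    with elbow-based model selection and temporal-property metrics (fraction time,
    mean dwell time, transition number), per-component temporal variability, and
    group/clinical statistics with FDR control. Includes a synthetic cohort
    generator with planted Markov-switching connectivity states so every stage can
    be validated against ground truth, plus group spatial ICA scaffolding
    (reduction, fixed-point ICA, back-reconstruction, template labeling).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mclust,
    optparse,
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
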