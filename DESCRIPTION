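Package: dynfc
Title: Dynamic Functional Connectivity States and Regional Temporal Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sliding-window dynamic functional connectivity analysis for
    ROI-level resting-state fMRI time series. Builds per-window Pearson
    correlation matrices, detects recurring connectivity states by a
    two-stage k-means procedure with L1 (cityblock) distances and
    exemplar subsampling, quantifies state temporal properties (dwell
    time, transition number, transition frequencies) and nodal temporal
    variability, and compares groups edgewise and regionwise with
    covariate-adjusted models, FDR correction, ROC summaries and partial
    correlations with clinical scores. Includes a synthetic
    state-switching cohort generator with known ground truth so the full
    pipeline can be validated end to end without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    nortest,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
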