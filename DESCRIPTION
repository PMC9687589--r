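Package: epifc
Title: Functional-Connectivity EEG Features and Classifiers for Epilepsy Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for diagnosing epilepsy from resting-state
    scalp EEG after a suspected first seizure. Implements FIR band-pass
    filtering, ICA-based EOG artifact removal, dual epoching with
    cross-validated epoch cleaning, longitudinal bipolar referencing with
    anterior/posterior scalp groups, Welch band powers with 1/f correction and
    a global band-power epoch-selection statistic, four functional-connectivity
    estimators (imaginary coherency, phase-locking value, Kraskov mutual
    information, and partial directed coherence from a multivariate
    autoregressive model), weighted graph measures, hemispheric asymmetry
    ratios, and cross-validated classifiers evaluated against surrogate ROC
    nulls and fused with clinician EEG readings. Ships a synthetic EEG cohort
    generator with planted directed coupling so the whole pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    nnet,
    pROC,
    purrr,
    randomForest,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
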