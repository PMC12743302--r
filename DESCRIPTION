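Package: fcdrift
Title: Inter-Areal Functional Connectivity Drift Across Sleep States
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to test whether the structure of inter-areal functional
    connectivity (FC) between simultaneously recorded neurons is homogeneous
    within brain states (wakefulness, NREM and REM sleep) at 5-second epoch
    resolution. Includes a four-area conductance-based leaky
    integrate-and-fire network simulator for ground-truth validation, a
    current-based decomposition estimator that fits a recurrent neural
    network to population rates and reads off directed source-to-target
    currents as FC, a synthetic multi-state session generator with
    controllable state-atypical epochs, session-level preparation
    (exclusion rules, state-magnitude tests, percentile tail selection with
    cross-state guards), and a hypothesis-testing engine built on a
    modified leave-one-out support vector machine classifier, a
    bin-stratified label-shuffle null, Fisher combination of session
    p-values and a resampling-based power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    e1071,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
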