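Package: tierbn
Title: Tiered Discrete Bayesian Networks for Clinical Recurrence Prediction
Version: 0.1.0
Authors@R:
    person("tierbn", "maintainers", email = "tierbn@example.org", role = c("aut", "cre"))
Description: Discrete Bayesian networks for predicting local tumor recurrence
    in rectal cancer after neoadjuvant chemoradiation and surgery. Provides a
    timeline-tiered expert-elicitation workflow (consensus intersection,
    reviewer approval, cycle and tier checks), score-based structure learning
    (decomposable BIC, hill climbing with add/delete/reverse moves, blacklists
    and random restarts), exact inference by variable elimination, maximum
    likelihood and Laplace parameter estimation, nominal-feature SMOTE
    rebalancing, a synthetic cohort generator calibrated to published cohort
    marginals, and a clinical evaluation surface (Mann-Whitney AUC, DeLong
    confidence intervals and paired tests, confusion metrics, bootstrap
    calibration curves, structural diffs with CPDAG-based Hamming distance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
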