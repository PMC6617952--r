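Package: silverphen
Title: Weakly Supervised Detection of Undiagnosed Dementia from Electronic Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for flagging probable undiagnosed dementia
    in electronic health record (EHR) cohorts when no gold-standard labels
    exist. Clinical notes are summarised as topic features by running latent
    Dirichlet allocation several times and keeping only topics that are stable
    across runs; structured codes (diagnoses, procedures, medications, note
    types) are aggregated to binary presence features; a silver-standard
    logistic model trained on coded diagnosis status scores every subject; and
    a stratified chart-review calibration stage converts review outcomes into
    per-bin undiagnosed rates, a zero-intercept rate line, per-bin undiagnosed
    counts, sensitivity/specificity at variable thresholds, and an ROC curve.
    A synthetic-EHR generator with planted ground truth makes every stage
    testable without access to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
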