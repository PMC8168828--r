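Package: rctscreen
Title: Recall-Calibrated Screening of Randomized Controlled Trial Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trains, calibrates and validates a high-recall binary text
    classifier that decides whether a title-abstract bibliographic record
    reports a randomized controlled trial (RCT). The classifier is an
    ensemble of two linear support vector machines over binary bag-of-words
    n-gram features (one uni/bi/tri-gram model, one unigram model trained
    with minority-class oversampling), joined and converted to calibrated
    probabilities by Platt scaling, with the classification threshold set to
    the largest probability achieving a mandated recall (99% by default) on
    a calibration set. Includes length-based machine/manual routing of
    records, bootstrap internal validation (recall, precision, specificity,
    C statistic, Brier score, calibration curve, percentile confidence
    intervals), study-level loss accounting for trials with multiple
    reports, lost-per-1,000-by-year rates, and a synthetic corpus generator
    so the whole pipeline can be exercised without proprietary screening
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    data.table,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
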