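Package: incrval
Title: Incremental Value of a Continuous Diagnostic Marker via Bayes Risk
    Updating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the incremental diagnostic value of a new continuous
    marker (for example, a malignancy probability produced by an image model
    for pulmonary nodules) over an existing clinical risk calculator.  Prior
    risks from configurable logistic risk models are updated with an estimated
    marker likelihood ratio through Bayes' rule (posterior odds = likelihood
    ratio x prior odds), and the gain is evaluated with ROC/AUC comparisons,
    the integrated discrimination improvement (IDI), reclassification tables
    with percent reclassified, and the category net reclassification index
    (NRI).  Includes a seeded synthetic-cohort generator with a binormal
    marker model, per-scan region-score reduction with exclusion of unscored
    subjects, multiple imputation by chained equations with Rubin's-rules
    pooling, and a config-driven end-to-end study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
Config/testthat/edition: 3
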