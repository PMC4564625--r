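Package: gbmrelapse
Title: Decision-Aligned Classification of Tumour Progression from
    Longitudinal Multiparametric MRI Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting glioblastoma relapse status from
    longitudinal multiparametric MRI feature tables. Implements
    decision-aligned label propagation for follow-up time series,
    volume-conditioned imputation of missing perfusion, diffusion and
    spectroscopy features, a leave-one-patient-out evaluation harness over a
    bank of supervised classifiers, per-time-point balanced error rates and
    their temporally and population weighted aggregate (wBER), and a
    synthetic cohort generator that emulates the sampling structure and
    per-modality missingness of a real follow-up study so that every stage
    of the pipeline can be exercised without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    rpart,
    nnet,
    randomForest,
    e1071,
    readr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
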