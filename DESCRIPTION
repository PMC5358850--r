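Package: nodesig
Title: Validation Pipeline for a qRT-PCR Lymph-Node Metastasis Gene
    Expression Signature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quality control, delta-Ct normalization, risk scoring and
    statistical validation for a 20-gene qRT-PCR expression signature
    predicting lymph-node-positive disease in muscle-invasive bladder
    cancer. Implements replicate reconciliation with undetermined-value
    ceiling rules, per-transcript reliability flagging, housekeeping-based
    sample discard, delta-Ct normalization over ACTB, the down-minus-up
    mean delta-Ct risk score, ROC/AUC with DeLong or bootstrap confidence
    intervals, per-gene logistic odds ratios, Mann-Whitney two-group
    tests with exact enumeration, Pearson correlation with
    complete-linkage clustering on 1-r distances, Table-1 style cohort
    comparisons, and a plate-structured synthetic qPCR cohort generator
    with a closed-form AUC oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
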