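Package: ctcsig
Title: Circulating Tumor Cell Expression Signatures from Array and qPCR Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis workflow for characterizing the circulating tumor cell
    (CTC) population enriched from peripheral blood. Reads Agilent Feature
    Extraction style spot tables, applies spot-level quality filtering,
    detection calls against the negative-control range, quantile
    normalization and probe-to-gene collapse; derives a CTC-specific gene
    signature by subtracting the healthy-donor lymphocyte background with a
    k-of-n patient presence rule; and runs the qPCR validation arm
    (CD45-normalized 40-Ct scoring, two-tailed Mann-Whitney tests with
    Benjamini-Hochberg FDR, a combined logistic panel with ROC/AUC, and
    Kaplan-Meier / Cox survival analysis of marker-dichotomized groups).
    Includes synthetic cohort generators that emulate the assumed data
    structure so every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    pROC,
    survival,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
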