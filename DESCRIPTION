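Package: prognomod
Title: Prognostic Gene-Expression Models from Stable Co-Expression Modules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds robust blood gene-expression prognostic models by an
    integrative module-based strategy: two-group moderated-t differential
    expression with Benjamini-Hochberg control, weighted co-expression
    network module detection in independent reference cohorts, Fisher-exact
    cross-cohort module stability calling, pathway/cell-type functional-core
    annotation, representative-gene selection, and a Gaussian naive-Bayes
    classifier sized by leave-one-out cross-validation.  Includes per-gene
    median/MAD cross-platform calibration (microarray, RNA-seq, qPCR), the
    fixed four-gene qPCR logistic score, survival evaluation machinery
    (Kaplan-Meier, log-rank, Cox proportional hazards, concordance), and a
    multi-cohort synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    e1071
Config/testthat/edition: 3
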