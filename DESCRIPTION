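Package: stromaTSP
Title: NanoString Stromal Expression Normalization, Differential Testing,
    and Top-Scoring-Pair Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for NanoString nCounter gene-expression
    panels profiling tumor-adjacent stroma. Provides lane quality control
    (binding density, fields of view), three-step count normalization
    (positive-control factors, mean-of-negatives background correction,
    top-75 content factors) with factor-range gating and missingness
    filters, per-gene two-group differential expression (Mann-Whitney U
    and Welch t tests, Benjamini-Hochberg false discovery rate, ROC AUC,
    log2 fold change), and a rank-based top-scoring-pair classifier with
    a label-permutation significance test. Includes a synthetic cohort
    generator with recorded ground truth so the whole pipeline is
    testable without access to instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
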