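Package: mprascope
Title: Quantification, Feature Ranking and Predictive Modelling of MPRA Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for massively parallel reporter assay (MPRA) meta-analysis:
    estimation of per-region transcription rates from barcode-level DNA/RNA
    counts under a Gamma-Poisson (negative binomial) model, robust-z active
    region calling with Benjamini-Hochberg control, sequence and epigenomic
    featurization (k-mers, composition, exact-p-value motif scanning, interval
    overlaps, predicted-binding score summaries), a nine-test median-rank
    feature assessment with subsample robustness, ensemble regression and
    classification of MPRA output with deterministic ten-section
    cross-validation and cross-dataset transfer, region hardness analysis,
    predictive transcription-factor overlap enrichment, and saturation
    mutagenesis variant-effect prediction. Includes synthetic-data generators
    that emulate the statistical structure of MPRA experiments so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
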