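Package: evpanel
Title: Biomarker Panel Discovery from Targeted Proteomics of Extracellular Vesicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, simulation-testable pipeline for discovering
    combinatorial protein biomarker panels from targeted (parallel reaction
    monitoring, PRM) proteomics of plasma extracellular vesicles.  Covers
    transition-level quantification with spectral-contrast (dotp) interference
    filtering, total-ion-current and reference-peptide normalization,
    missing-not-at-random imputation, spectral-library curation and
    gas-phase-fractionation DIA window arithmetic, differential screening,
    exhaustive combinatorial panel search with a PCA + linear-SVM pipeline
    tuned by leave-one-out cross-validation, exact Shapley feature
    attribution, and 4-parameter-logistic ELISA quantification with
    Youden-threshold diagnostics.  A synthetic-cohort generator with planted
    ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    e1071,
    minpack.lm,
    withr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    knitr,
    rmarkdown
Config/testthat/edition: 3
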