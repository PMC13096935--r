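Package: wcvr
Title: Weighted Composite Value Ratio Biomarkers for Amyloid-Beta Peptide Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for data-driven amyloid-beta (Abeta) peptide biomarker
    analysis in familial Alzheimer's disease cell models. Harmonizes
    multi-assay peptide panels (Abeta37/38/40/42/43) onto a dimensionless
    control-relative scale, evaluates fixed and exhaustively enumerated
    peptide ratios, searches for weighted composite value ratios (wCVR) by
    genetic algorithm under classification and age-at-onset regression
    objectives, and validates results with stratified bootstrap confidence
    intervals, leave-one-out cross-validation with a specificity-first
    threshold rule, and paired tests with Benjamini-Hochberg correction.
    Includes a synthetic multi-cohort generator emulating the statistical
    structure of familial Alzheimer's disease peptide panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
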