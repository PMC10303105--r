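Package: ihcdx
Title: Diagnostic and Prognostic Analysis of Semi-Quantitative IHC Biomarkers
    in T-Cell Lymphoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for semi-quantitative immunohistochemistry (IHC) biomarker
    studies in mature T-cell lymphoma, centred on the differential diagnosis of
    ALK-negative anaplastic large cell lymphoma versus CD30-high peripheral
    T-cell lymphoma, not otherwise specified. Computes H-scores from staining
    intensity profiles and a tumor-infiltrating-lymphocyte (TILs) weighted
    composite score; builds empirical ROC curves with Youden-index optimal
    cutoffs, evaluates parallel/serial marker combinations, and compares paired
    AUCs by the DeLong method; provides exact two-sided Fisher, Mann-Whitney U,
    Kruskal-Wallis and Spearman group-comparison statistics; estimates
    Kaplan-Meier survival with log-rank testing, TILs-score prognostic
    stratification and additive clinical risk indices; and simulates fully
    reproducible synthetic cohorts with the four-group structure these analyses
    assume, so the whole pipeline is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils
Suggests:
    pROC,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
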