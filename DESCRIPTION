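Package: serumsig
Title: Serum Proteomics Biomarker Discovery by CDF Permutation Statistics
    and Random-Forest Concordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for label-free serum LC-MS/MS biomarker
    discovery in small case-control cohorts. Implements left-censored
    (MinProb) imputation of peptide intensities, per-group minimum-coverage
    filtering with full removal accounting, duplicate-peptide collapsing, a
    permutation-based empirical-CDF deviation statistic (S) with significance
    banding, Random-Forest leave-one-out cross-validation with mean-decrease-
    Gini feature ranking, peptide-to-protein evidence aggregation with
    MALDI-TOF/TOF cross-validation, and 2D-DIGE master-spot screening. A
    synthetic-cohort generator with intensity-dependent (MNAR) dropout makes
    every stage testable without access to confidential raw data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    randomForest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
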