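Package: metabatch
Title: Batch-Effect Correction and Model Selection for Multi-Batch
    Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Location/scale batch-effect correction for large multi-batch
    LC-MS metabolomics feature tables, with a score-based framework for
    choosing among candidate models.  Implements two-stage regression
    correction (ber) and its bootstrap-bagged variant, empirical-Bayes
    ComBat in parametric and nonparametric modes, and a QC-sample lowess
    signal-drift comparator.  Model performance is ranked by the maximum
    per-feature adjusted R-squared of intensity on batch.  Includes
    preprocessing (log2 transform, presence filtering, missing-value
    imputation), sample- and feature-level diagnostics (PCA, hierarchical
    clustering, per-feature distribution summaries), downstream validation
    statistics (Fisher-z correlation intervals, covariate-adjusted
    association scans, differential analysis), and a seeded simulator of
    multi-batch acquisitions with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    sva,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
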