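Package: hrvpart
Title: Heart Rate Variability Response to Orthostatic Stress and
    Hierarchical Partitioning of Regression R-Squared
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how echocardiographic aortic-valve parameters
    independently explain the change of heart-rate-variability (HRV) indices
    between supine rest and active standing. Computes the standard short-term
    HRV indices from NN-interval series (meanNN, SDNN, RMSSD, pNN20, Welch
    LF/HF band powers with normalized units, the detrended-fluctuation
    short-term scaling exponent alpha1, and sample entropy), derives
    supine-minus-standing deltas, builds three-group comparison tables with an
    Anderson-Darling normality gate and Bonferroni-adjusted post hoc tests,
    pre-selects predictors by per-category stepwise linear regression, and
    decomposes the combined model R-squared into per-predictor independent and
    joint contributions by hierarchical partitioning (Chevan-Sutherland /
    Shapley decomposition). A synthetic-data module generates RR-interval
    series, single-lead ECG and respiration waveforms, and cohort covariate
    tables with known ground truth so that every stage of the analysis is
    testable without access to recordings.
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
    MASS,
    nortest,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
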