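Package: tdcroc
Title: Time-Dependent ROC Analysis for Right-Censored Biomarker Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Cumulative/dynamic time-dependent ROC analysis for baseline
    biomarkers under right censoring. Implements the Kaplan-Meier and
    nearest-neighbor (kernel-weighted bivariate survival) estimators of
    time-dependent sensitivity and specificity, trapezoidal AUC, Youden-index
    threshold selection, censoring-aware confusion matrices with positive and
    negative predictive values, a weighted expected misclassification cost,
    Cox proportional-hazards composite risk scores, and Monte Carlo, K-fold
    and leave-one-out cross-validation of prognostic markers. Includes a
    Weibull proportional-hazards cohort simulator calibrated to emulate a
    breast-radiotherapy late-fibrosis cohort with a radiosensitivity assay
    (RILA) marker.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
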