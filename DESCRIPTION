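Package: he4align
Title: Harmonization of HE4 Immunoassay Measurements and
    Covariate-Adjusted ROC Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for aligning serum HE4 (human epididymal secretory
    protein 4) measurements across laboratories running different
    immunoassay platforms, and for evaluating the diagnostic accuracy of
    the harmonized marker. Fits ordinary least product (geometric-mean)
    regressions of a reference laboratory's shared calibration-curve
    readings on each test laboratory's readings to detect fixed and
    proportional systematic biases, and corrects biased laboratories onto
    the reference scale. Provides a two-stage covariate-adjusted ROC
    regression (linear control model, probit-link ROC-GLM on placement
    values) with hospital-cluster bootstrap confidence intervals,
    empirical ROC curves, Youden-index cut-off selection, DeLong's paired
    test for equality of two AUCs, a study pipeline with eligibility
    filtering and menopause/age stratification, and a synthetic-data
    generator for calibration experiments and patient cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    pROC,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
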