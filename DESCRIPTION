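Package: steromap
Title: Determinants of the Urinary Steroid-Hormone Metabolome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for mapping clinical, lifestyle and
    sociodemographic determinants onto the urinary conjugated steroid-hormone
    (SH) metabolome in pregnancy cohorts. Derives molecular features
    (individual metabolites, family and hormone-group sums,
    sulfate/glucuronide ratios, product/precursor enzyme-activity indices)
    from a 50-metabolite conjugated-steroid panel; preprocesses
    concentrations (reproducibility filtering, left-censored
    limit-of-detection imputation, molar conversion, specific-gravity
    dilution correction, multiples-of-median gestational-age normalization);
    runs exposome-wide association scans with effective-number-of-tests
    correction, bootstrap-stable elastic-net selection, LMG variance
    decomposition, and second-cohort replication. Includes a calibrated
    synthetic two-cohort generator carrying ground-truth effects for
    recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    quantreg,
    randomForest,
    stats,
    tibble,
    dplyr,
    purrr,
    rlang,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
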