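Package: heartally
Title: Point-Based Heart Age, ALLY Statistic and Atherogenic Index Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a sex-specific point-based heart-age calculator
    (total cholesterol, HDL cholesterol, fasting glucose, smoking, body
    mass index and blood pressure bands), the derived ALLY statistic
    (avoidable lost life years: heart age minus chronological age) with a
    high-ALLY classifier, and three atherogenic lipid indices (TC/HDL-c,
    LDL-c/HDL-c, TG/HDL-c) with sex-specific risk categories.  Provides a
    calibrated synthetic occupational-cohort generator, ROC curve analysis
    with DeLong confidence intervals and Youden-index cut-off selection,
    logistic regression with odds ratios and Hosmer-Lemeshow goodness of
    fit, age-stratified modelling, bivariate descriptive tables, and a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
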