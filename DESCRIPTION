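Package: hccscreen
Title: Longitudinal Biomarker Screening Algorithms for Hepatocellular
    Carcinoma Surveillance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements two screening algorithms for early detection of
    hepatocellular carcinoma (HCC) from serial alpha-fetoprotein (AFP)
    measurements in cirrhosis surveillance cohorts: a parametric empirical
    Bayes (PEB) sequential rule that shrinks each patient's screening
    history toward the population mean of log2(AFP), and a six-month risk
    prediction model built on linear-spline (hinge) bases of AFP, ALT,
    platelets, age and the annualized AFP rate of change, fitted by
    cross-sectional resampling of longitudinal records. Both algorithms are
    embedded in an AFP >= 400 ng/ml OR rule and evaluated with a
    longitudinal performance framework: windowed patient-level true
    positive rates, screening-level false positive rates, predictive
    values, risk-percentile curves, decile risk, first-positive timing and
    per-patient false-positive burden. A synthetic cohort generator with
    the random-intercept structure the methods assume makes every stage
    testable without access to registry data.
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
    glmnet,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
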