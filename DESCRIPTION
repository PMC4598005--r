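Package: readmitrsf
Title: Random-Survival-Forest Risk Stratification for 30-Day Hospital
    Readmission
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for 30-day hospital
    readmission risk modelling on encounter-level electronic health record
    data: a seeded synthetic EHR cohort generator with a known discrete-time
    readmission hazard; 12-month look-back feature aggregation with
    variance-based filtering and chronic-disease by inpatient-history
    sub-cohorting; a from-scratch random survival forest with log-rank node
    splitting and Nelson-Aalen terminal cumulative hazards; positive
    predictive value (PPV) calibration of the ensemble hazard to a unified
    0-100 risk score with Low/Intermediate/High tiers; tiered evaluation
    (risk-bin readmission rates, Kaplan-Meier readmission-free curves,
    c-statistic); and PCA plus K-means phenotype clustering of high-risk
    patients with an elbow rule on the within-cluster sum-of-squares
    reduction rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
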