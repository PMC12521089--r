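Package: faersignal
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous Report Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pharmacovigilance pipeline for spontaneous
    adverse-event report databases in the FDA Adverse Event Reporting System
    (FAERS) quarterly ASCII dialect: report ingestion, case deduplication,
    drug-cohort construction, MedDRA term standardisation with Important
    Medical Event and drug-label flagging, 2x2 disproportionality analysis
    with four estimators (reporting odds ratio, proportional reporting
    ratio, the BCPNN information component, and the empirical-Bayes
    geometric mean under a two-component gamma-Poisson mixture prior),
    consensus signal calling, time-to-onset analysis, and demographic
    summaries. A synthetic FAERS generator with designed reporting-rate
    multipliers provides ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
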