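Package: inrmu
Title: Measurement Uncertainty of PT/INR in a Thromboplastin Reference
    Measurement System
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bottom-up measurement-uncertainty analysis for prothrombin-time
    (PT) based International Normalized Ratio (INR) results in a thromboplastin
    reference measurement system. Propagates the repeatability of PT replicates,
    the intermediate precision of the mean normal PT (MNPT), and the
    between-laboratory reproducibility of the International Sensitivity Index
    (ISI) into a standard deviation of ln(INR) by a GUM-style delta method in
    log space, with coverage-factor confidence intervals and relative
    uncertainty in percent. Includes a CLSI EP17-style precision-profile power
    fit, uncertainty-budget allocation across the calibration hierarchy, a
    Monte Carlo simulation oracle that validates the analytic propagation, and
    a seeded generator of synthetic multicenter calibration-study raw data for
    top-down/bottom-up concordance checks.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
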