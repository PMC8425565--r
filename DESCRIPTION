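Package: phenovalid
Title: Validation of Coded Outcome Definitions in Claims and EMR Export Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for validating electronic-health-record phenotyping
    algorithms: applies coded outcome definitions with month-level temporal
    logic to longitudinal claims extracts and simplified SS-MIX2-style export
    stores, adjudicates potential cases with laboratory-threshold rules
    (including an acute serum-creatinine elevation rule with prior-creatinine
    stratification), and summarises validity as positive predictive values
    with Wald 95% confidence intervals. Includes a synthetic cohort generator
    with known ground truth for parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
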