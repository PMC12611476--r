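Package: ptpaths
Title: Treatment-Pathway Analysis of Outpatient Psychotherapy in Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for analysing outpatient treatment pathways of
    incident depression in statutory health-insurance claims data.
    Selects an incident cohort with a 12-month diagnosis-free lead-in,
    assigns depression severity by a hierarchical rule set, maps billed
    services to session-normalised psychotherapeutic service events,
    classifies service sequences against pre- and post-reform pathway
    catalogues under a 91-day same-service gap rule, computes
    first-contact to first-therapy intervals, and compares periods with
    the Mann-Whitney U test and phi, Cramer's V and eta effect sizes.
    Ships a synthetic claims generator with per-person ground truth so
    the whole pipeline is testable without access to real claims.
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
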