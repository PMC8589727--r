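Package: thrombadhere
Title: Antithrombotic Prescribing, Adherence and Persistence Analysis from
    Linked Electronic Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for drug-utilisation studies of
    anticoagulants and antiplatelets in routinely collected electronic health
    records. Builds new-user (drug-naive) cohorts with prevalent liver disease
    and incident cardiovascular indications from four linked tables (patients,
    prescriptions, diagnoses, laboratory measurements); estimates prescribing
    prevalence per 100 persons with Wald confidence intervals; computes
    proportion-of-days-covered (PDC) adherence under a 30-day supply rule,
    primary non-adherence, and 90-day-gap persistence with in-class switch
    censoring; scores liver severity (Child-Pugh, FIB-4) and stroke risk
    (CHA2DS2-VASc); derives Rosendaal time-in-therapeutic-range from INR
    series; and fits logistic and Cox models of non-adherence, non-persistence,
    stroke and bleeding risk. A seeded synthetic-EHR generator emulates the
    cohort structure so every stage is testable end to end without access to
    licensed patient data.
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
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
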