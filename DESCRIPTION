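Package: kinloss
Title: Orphanhood and Grandparent Caregiver Loss from Vital Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates incidence and prevalence of orphanhood and of
    co-residing grandparent caregiver loss among children aged 0-17 from
    cause-specific vital-statistics count tables (deaths, live births,
    population sizes, pediatric survival and household co-residence
    proportions). Implements stratified fertility-rate attribution of
    expected children to decedents, life-table hazard corrections for
    double parental loss, survival-adjusted prevalence accrual,
    de-duplication of parental and grandparent caregiver loss, Monte Carlo
    uncertainty propagation with co-monotone Poisson replicates, and
    state-level suppression and rescaling adjustments. Includes a
    family-level microsimulation generator with exact kin-loss truth for
    validating the estimator end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
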