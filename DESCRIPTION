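Package: reliefwatch
Title: Analysis of Electronically Monitored Beta-Agonist Overuse and
    Medical Review in High-Risk Asthma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing time-stamped inhaler actuation logs from
    electronic medication monitors in asthma trials. Classifies days of
    high, marked and extreme beta-agonist use at regimen-specific
    thresholds, links overuse days to medical-review attendances under a
    48-hour rule with a restartable 7-day stand-down period, constructs
    severe-exacerbation episodes from systemic corticosteroid courses and
    extracts peri-exacerbation medication-use profiles, and computes
    between-arm contingency and over-dispersed Poisson rate statistics.
    Includes a synthetic two-arm cohort generator so the full pipeline can
    be exercised and validated without access to trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
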