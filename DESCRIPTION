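Package: faersignal
Title: Disproportionality and Time-to-Onset Signal Detection for
    Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: A tidy pipeline for pharmacovigilance signal detection in
    FAERS-style spontaneous reporting data: reading '$'-delimited quarterly
    ASCII tables, FDA-rule case deduplication, primary-suspect drug
    filtering, cohort description, 2x2 contingency construction with sex
    and age subgroups, four disproportionality statistics (reporting odds
    ratio, proportional reporting ratio, the BCPNN information component,
    and the multi-item gamma-Poisson shrinker EBGM) with interval
    estimates and signal criteria, FDR-screened volcano tables per system
    organ class, and time-to-onset analysis with Weibull maximum
    likelihood, failure-type classification, Kaplan-Meier cumulative
    incidence, and log-rank comparison. A seeded synthetic-report
    generator with a ground-truth ledger makes every stage testable
    without the multi-gigabyte FAERS download.
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
    utils
Suggests:
    fitdistrplus,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
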