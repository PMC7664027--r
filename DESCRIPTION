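Package: dhisclean
Title: Systematic Cleaning of DHIS2 HIV-Indicator Facility Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of a screening-diagnosis-treatment
    data-cleaning pipeline for aggregate HIV-indicator facility reports extracted
    from DHIS2-style national reporting systems. Merges reporting-rate extracts,
    annual indicator extracts and facility master lists into facility-year records;
    computes completeness and timeliness metrics (Reporting Rate, Reporting Rate on
    Time, Cumulative Percent Completion); classifies every record into a situation
    taxonomy; removes non-reporting, erroneous and duplicated records across audited
    cleaning cycles; and analyses the distribution of data-quality situations across
    programmatic areas with Friedman and Wilcoxon signed-rank tests. A synthetic-data
    generator emulates DHIS2 extracts with injected, labelled anomalies so every
    stage is testable without access to a national database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
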