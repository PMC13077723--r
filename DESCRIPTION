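Package: faersignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection on FAERS-style
    spontaneous adverse-event report data. Includes a configurable synthetic
    report generator with known injected drug-event associations, readers for
    the quarterly $-delimited ASCII dialect, case deduplication and
    primary-suspect filtering, Preferred Term to System Organ Class
    aggregation, 2x2 contingency-table construction, four disproportionality
    statistics (reporting odds ratio, proportional reporting ratio with
    Yates-corrected chi-square, the BCPNN information component, and
    empirical-Bayes gamma-Poisson shrinkage EBGM) with conventional signal
    thresholds, and demographic summary tables with count-(percent) layout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
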