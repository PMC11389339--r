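Package: equileague
Title: Equity-Weighted Cost-Effectiveness League Tables from Delphi Panel Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning expert-panel (Delphi) equity scores for disease
    conditions into standardized equity weights and equity-adjusted
    cost-effectiveness league tables, as used in health benefit package
    design. Aggregates ordinal expert scores per condition, summarizes them
    by GBD level-2 category, categorizes conditions into high/medium/low
    equity groups, applies a maternal-and-child-health reassignment rule,
    standardizes scores to multiplicative equity weights on [1, 2], divides
    intervention cost-effectiveness ratios by those weights, and compares the
    resulting intervention rankings. Includes a seeded synthetic-data
    generator emulating the statistical structure of such panels so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
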