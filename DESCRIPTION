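Package: rorscan
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance analysis of FAERS-style
    spontaneous adverse-event report data: reads dollar-delimited quarterly
    table bundles (DEMO, DRUG, REAC, OUTC, THER, INDI), de-duplicates report
    versions by case identifier, extracts drug cohorts by name lexicon and
    primary-suspect role, maps reaction preferred terms to a system organ
    class, characterizes cases (demographics, reporting characteristics,
    outcomes), computes time-to-onset distributions with regimen comparisons,
    and detects adverse-event signals by the reporting odds ratio with
    report-count and confidence-interval positivity criteria. Includes a
    synthetic report generator with known ground truth (planted drug-event
    association strengths, duplicate versions, partial and invalid dates) so
    every stage is testable without access to the real database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    readr,
    tibble,
    purrr,
    stringr,
    rlang,
    stats,
    utils,
    survival,
    yaml,
    jsonlite
Suggests:
    ggplot2,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
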