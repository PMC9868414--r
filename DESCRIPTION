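Package: prrscreen
Title: Disproportionality Signal Screening for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance disproportionality analysis of
    FAERS-style spontaneous adverse-event report databases. Reads the
    three-table report layout (demographics, drugs per report, reactions per
    report), normalizes verbatim drug names against a user-supplied synonym
    vocabulary, defines adverse events as MedDRA Preferred Term sets, builds
    per (drug, event) 2x2 contingency tables against the all-other-reports
    background, and computes the proportional reporting ratio (PRR),
    chi-squared statistic and the Evans positive-signal classification
    (PRR >= 2, chi-squared >= 4, at least 3 cases). Includes demographic
    overview tables, cross-event overlap summaries, and a seeded generator of
    synthetic report databases with planted drug-event associations for
    pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
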