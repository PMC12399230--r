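Package: oncolot
Title: Line-of-Therapy Derivation, Healthcare Resource Use and Cost
    Outcomes from Administrative Claims in Oncology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for claims-based treatment-sequencing analyses in
    oncology: a typed data model for enrollment, medical and pharmacy
    claims; a proxy cohort-selection algorithm for EGFR-mutated advanced
    non-small cell lung cancer (two lung-cancer diagnoses, small-cell
    exclusion, 12-month washout, advanced-disease qualifier, EGFR-TKI
    index on/after the osimertinib approval date, prior-malignancy and
    surgery exclusions) with a full attrition log; a line-of-therapy
    engine implementing the 21-day regimen window, new-agent line breaks
    and the >90-day re-treatment rule; per-patient-per-month healthcare
    resource utilization and cost summaries adjusted to 2022 US dollars
    with the medical-care CPI, including the Quan adaptation of the
    Charlson comorbidity index; report builders for baseline, HRU, cost
    and treatment-sequencing tables with mean differences and Welch
    confidence intervals; and a synthetic claims generator with ground
    truth labels so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14.0),
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    withr
Config/testthat/edition: 3
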