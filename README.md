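# oncolot

Claims-based treatment-sequencing analysis for oncology: cohort selection,
line-of-therapy (LOT) derivation, and per-patient-per-month (PPPM)
healthcare-resource-utilization (HRU) and cost outcomes, built for studies of
EGFR-mutated advanced non-small cell lung cancer (NSCLC) in administrative
claims data, together with a synthetic claims generator that makes the whole
pipeline testable end to end without access to any proprietary database.

## Who this is for

Health-economics and outcomes researchers who work with longitudinal
administrative claims (enrollment spans, diagnosis/procedure-coded medical
claims, days-supply pharmacy claims) and need a reproducible, tested
implementation of the standard building blocks of a treatment-sequencing
study: a proxy cohort-selection algorithm, a rule-based LOT engine, PPPM
aggregation with CPI adjustment, the Quan coding of the Charlson comorbidity
index, and descriptive reporting with mean differences and Welch confidence
intervals.

## The algorithms at the core

**Cohort selection** (claims proxy for EGFR-mutated advanced NSCLC, since no
ICD code captures mutation status): patients need (1) ≥2 lung-cancer
diagnoses (ICD-9 162.2x–162.9x, ICD-10 C34.x) on distinct dates within one
continuous-eligibility period; (2) no small-cell first-line regimen
(etoposide/irinotecan/topotecan); (3) ≥12 months of eligibility before the
first lung-cancer diagnosis (washout); (4) advanced disease — first-line
initiation of a guideline-recommended regimen, or a metastatic diagnosis
(196.x/197.x/198.x/209.7, C77–C79/C7B) within 30 days of the first
lung-cancer diagnosis followed eventually by first-line initiation; (5) an
EGFR-TKI initiation (gefitinib, erlotinib, afatinib, osimertinib,
dacomitinib) in any LOT on/after 2018-04-18 (osimertinib approval), defining
the index date; (6) no other-cancer diagnosis before the first lung-cancer
diagnosis; (7) among patients without the 30-day metastatic qualifier, no
lung-cancer surgery before index. Every step is logged in an attrition
table.

**LOT derivation**: the first antineoplastic claim on/after the first
lung-cancer diagnosis starts 1L; all antineoplastics first observed within
the inclusive 21-day window `[start, start + 21]` form the regimen (one
cycle of common NSCLC regimens). A line ends the day before a non-regimen
antineoplastic initiation, the day before the same regimen (exact agent-set
equality) resumes after a gap of more than 90 days measured from the last
exposure end (pharmacy supply end or infusion date), or at the end of
observation. Later lines repeat the same rules. Oral TKI exposure comes from
days-supply pharmacy fills; infused agents from outpatient claims carrying
the agent key among their procedure codes.

**Outcomes**: per line, all-cause HRU (distinct outpatient service days,
admissions and inpatient days from merged inpatient claims, ED days outside
admissions) and costs split into inpatient, outpatient
(antineoplastic+administration vs other), ED+other, and pharmacy — each
CPI-adjusted to 2022 USD by service year and divided by the line length in
30.4375-day months. `total = medical + pharmacy` and
`medical = inpatient + outpatient + ED/other` hold exactly.

## Worked example

```r
library(oncolot)
codes <- code_config()                                   # code sets + drug dictionary
sim <- generate_claims(sim_config(n_patients = 300))     # synthetic claims + ground truth
sel <- select_cohort(sim$dataset, codes, data_end_date = as.Date("2023-01-31"))
sel$attrition[, 1:3]
#>                                          step n_before n_after
#> 1: two_lc_diagnoses_in_continuous_eligibility      300     300
#> 2:                             sclc_exclusion      300     293
#> 3:                                washout_12m      293     286
#> 4:                 advanced_disease_qualifier      286     279
#> 5:                 egfr_tki_on_after_approval      279     217
#> 6:                      no_prior_other_cancer      217     207
#> 7:                    no_surgery_before_index      207     192
```

192 of 300 simulated patients survive the seven selection steps (the
generator plants small-cell, washout, prior-malignancy, non-advanced,
surgery and pre-approval-TKI decoys, and platinum-treated patients without a
later TKI drop out at step 5). Deriving lines and summarizing costs:

```r
lines <- derive_lines_cohort(sim$dataset, sel$cohort, codes)
summaries <- summarize_lines(lines, sim$dataset, codes)  # PPPM, 2022 USD
report <- build_report(sel$cohort, lines, summaries)
report$progression
#>    from_depth n_at_depth n_next  pct
#> 1:          1        192     58 30.2
#> 2:          2         58     17 29.3
report$cost_shares[group == "overall" & line_number == 1]
#>      group line_number                  component  mean_pppm share_pct
#> 1: overall           1        cost_inpatient_pppm   804.2805       4.0
#> 2: overall           1 cost_outpatient_total_pppm  5688.5975      28.2
#> 3: overall           1  cost_outpatient_anti_pppm  1090.2049       5.4
#> 4: overall           1    cost_ed_plus_other_pppm   204.1027       1.0
#> 5: overall           1         cost_pharmacy_pppm 13502.4648      66.8
```

30.2% of the selected cohort progressed to a second line, and in first-line
therapy pharmacy fills (dominated by oral TKIs at roughly $13.5k PPPM)
account for two-thirds of total costs — the expected signature of a
TKI-dominated first-line mix. `report$table1` … `report$table4` hold the
baseline, HRU and cost table shells; `write_report(report, dir)` writes them
as CSVs.

Ground truth is carried alongside the claims, so the pipeline can be checked
exactly:

```r
setdiff(sim$truth$patients[eligible == TRUE, patient_id], sel$cohort$patient_id)
#> character(0)
```

## Configuration files

* `code_config()` / `read_code_config()` / `write_code_config()` — diagnosis
  and procedure code sets, the drug dictionary and algorithm constants, as
  YAML so proprietary code lists can be swapped in.
* `inst/extdata/cpi.csv` — medical-care CPI deflators to 2022 USD
  (replaceable).
* `inst/extdata/quan_cci_map.csv` — Quan ICD-9/10 prefix map with the
  original Charlson weights (replaceable, e.g. by the 2011 weights).

See the methods vignette (`vignettes/oncolot-methods.Rmd`) for the modelling
assumptions, parameter choices and known limitations.
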