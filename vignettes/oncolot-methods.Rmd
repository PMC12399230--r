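---
title: "Methods: claims-based line-of-therapy and cost analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: claims-based line-of-therapy and cost analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncolot)
```

## The problem

Administrative claims record enrollment spans, diagnosis- and
procedure-coded medical claims and days-supply pharmacy fills — but no tumor
stage, no mutation status and no explicit treatment lines. Studies of
treatment sequencing and costs in EGFR-mutated advanced non-small cell lung
cancer (NSCLC) therefore rest on three inferential constructions, each of
which this package implements as tested, configurable code:

1. a **proxy cohort-selection algorithm** that identifies advanced NSCLC
   from diagnosis patterns and uses receipt of an EGFR tyrosine-kinase
   inhibitor (TKI) on/after the osimertinib approval date (2018-04-18) as a
   proxy for the mutation;
2. a **line-of-therapy (LOT) engine** that segments the antineoplastic claim
   stream into ordered, dated lines with regimens;
3. **per-patient-per-month (PPPM) aggregation** of all-cause healthcare
   resource use and costs, inflation-adjusted to 2022 US dollars.

Because the data such studies use are proprietary, the package ships a
synthetic claims generator with ground-truth labels; every pipeline stage is
validated against that truth and against independent brute-force oracles.

## Conventions that the code pins down

Claims algorithms live or die on boundary conventions. The ones adopted
here, each pinned by a fixture in `make_fixture()`:

* **All intervals are closed calendar-date intervals.** A line's days are
  `end - start + 1`; "the day prior to" the next initiation is the natural
  line end under this convention.
* **The 21-day regimen window is inclusive**: an agent first seen exactly 21
  days after the line start joins the regimen (`window_day21`); on day 22 it
  starts a new line (`window_day22`). The window length corresponds to one
  cycle of common NSCLC regimens, so dose adjustments after the first cycle
  are not mistaken for regimen changes.
* **The re-treatment gap is strict**: a 90-day gap never splits a line
  (`gap90`), a 91-day gap always does (`gap91`). The gap is measured from
  the latest *exposure end* of the regimen agents — fill date plus days
  supply minus one for oral agents, service date for infusions — to the next
  regimen-agent claim. Measuring from claim date instead is available as
  `code_config(gap_reference = "claim_date")`; with monthly 30-day fills the
  claim-date convention would never register exposure gaps shorter than the
  fill interval, which is why supply-end is the default.
* **Re-treatment means the same regimen, as exact agent-set equality**,
  assessed over the 21-day window at the resumption. If only a proper
  subset of a combination resumes after a long gap, the claim is neither a
  new agent nor a resumption of the same regimen, so the line simply
  continues (`partial_resume`). A line cannot end by discontinuation alone:
  with no further therapy it runs to the end of observation.
* **The 30-day metastatic window is inclusive** (`met_day30` vs
  `met_day31`), as is the washout boundary: exactly 365 days of eligibility
  before the first lung-cancer diagnosis passes (`washout_boundary`).
* **"≥2 lung-cancer diagnoses" requires distinct service dates.** Two codes
  on one day are one clinical encounter; this is an assumption, pinned in
  tests, not something the selection rule's wording settles.
* **Continuous eligibility is strict by default**: enrollment spans merge
  only when overlapping or directly adjacent (gap ≤ 1 day).
  `code_config(eligibility_bridge_days = n)` bridges longer administrative
  gaps for users who prefer the looser convention.
* **Inpatient claims merge into admissions as contiguous runs of inpatient
  days**: overlapping, same-day-abutting and consecutive-day claims (interim
  bills split at midnight) are one admission, so admission day counts equal
  the size of the union of claimed days. An emergency-department claim
  dated inside an admission is counted and costed as inpatient.
* **Same-day ties at a line start** join the starting regimen; zero-length
  lines cannot arise.
* **Index date** is the first *initiation* of an EGFR-TKI inside a line
  on/after the approval date, where initiation means the first TKI claim
  within that line — a TKI started before approval and merely continued
  afterwards does not qualify.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `combo_window_days` | 21 | days | one cycle of common regimens |
| `retreatment_gap_days` | 90 | days | conventional re-treatment threshold |
| `metastatic_window_days` | 30 | days | advanced-disease qualifier |
| `washout_days` | 365 | days | incident-diagnosis washout |
| `baseline_days` | 365 | days | baseline characterization window |
| `month_days` | 30.4375 | days | 365.25 / 12; the PPPM denominator unit |
| `eligibility_bridge_days` | 0 | days | strict continuous eligibility |
| `gap_reference` | `"supply_end"` | — | exposure-based gap measurement |

The drug dictionary (generic-name key → agent class, with a
guideline-regimen flag), the diagnosis/procedure code sets, the CPI
deflator table and the Quan-Charlson condition map are all data, not code:
`write_code_config()` round-trips the whole configuration through YAML, and
the CPI/Quan tables are CSVs under `inst/extdata/` that users can replace.
The shipped CPI table is derived from the annual-average US medical-care
consumer price index normalized to 2022; the shipped comorbidity map uses
Quan's ICD-9/ICD-10 coding algorithms simplified to dot-free code prefixes
with the original Charlson weights, applying the three standard hierarchy
rules (metastatic over malignancy, severe over mild liver disease,
complicated over uncomplicated diabetes).

## Statistical reporting

All reporting is descriptive: means, SDs and medians per group (SD is
reported empty below n = 2), frequencies and proportions for categorical
measures, and mean differences with 95% confidence intervals when comparing
costs across successive lines or between the first-line
osimertinib-monotherapy and first-line platinum-without-immunotherapy
subgroups. The interval is the unpaired, unequal-variance **Welch**
interval; the quantile is Student *t* with Welch–Satterthwaite degrees of
freedom by default (`ci_quantile = "normal"` switches to the normal
quantile — at the group sizes of interest the two are nearly
indistinguishable, and the coverage simulation in the test suite holds for
both). The LOT groups being compared share patients, so these are not
independent samples; they are nevertheless treated as separate groups, which
matches how such descriptive cost tables are conventionally presented, and
no multiplicity adjustment is applied. When both groups are constant the
interval degenerates to the point estimate.

Cost shares are `100 × component mean / total mean` to one decimal; PPPY
rates are `12 ×` the PPPM rate to one decimal; costs are reported to whole
dollars, rates to two decimals.

## What the synthetic generator emulates

`generate_claims(sim_config())` simulates, per patient: an enrollment span
with at least a year of pre-diagnosis history (plus occasional disjoint
historical spans), two dated lung-cancer diagnoses, a metastatic diagnosis
within the 30-day window for 90% of treated patients (with brain metastases
in 44% of those, coded before first-line start so they are visible at
baseline), non-malignant baseline comorbidities feeding the Quan-Charlson
score, pre-first-line corticosteroids/radiotherapy/surgery, and up to three
treatment lines. Regimen classes are drawn from a first-line mix dominated
by osimertinib monotherapy and class-conditional transition mixes; oral TKIs
are emitted as 30-day-supply fills, everything else as 21-day-cycle
outpatient infusion claims carrying the agent key in a procedure-code slot
(a stand-in for drug-specific billing codes) plus an administration
procedure code. Background utilization (outpatient visits, admissions with
Poisson lengths of stay, ED visits) arrives at class-specific Poisson rates,
and every event cost is drawn log-normal, reproducing the heavy right skew
(mean ≫ median) characteristic of claims costs. Line durations are
log-normal in months with class-specific locations (≈12 months for
first-line osimertinib monotherapy, ≈6 for platinum-based chemotherapy).
Mortality is not simulated — the claims sources such studies use lack it —
so all censoring is disenrollment or end of data.

Decoy archetypes exercise every selection filter: small-cell first-line
regimens, prior other-cancer diagnoses, short washout, patients with no
systemic therapy and no early metastatic code, early-stage surgery patients,
and pre-approval TKI initiators. The generator labels each patient with the
filter it should fail, computed from the construction itself, never by
running the pipeline — so selection-vs-truth comparisons are genuine
round-trips.

Two noise knobs deliberately break exact recovery when enabled:
`prob_non_regimen_decoy_claim` injects stray antineoplastic claims
mid-line (default 0), and `prob_retreatment_gap` (default 0.05) splits a
line by a >90-day same-regimen gap — the latter is deterministic and is
recovered exactly, so it stays on by default.

What the generator does **not** emulate: claim reversals and adjudication
artifacts, coding errors, dose changes within a regimen, maintenance phases,
mortality, and realistic correlation structure between utilization
categories. Exact ground-truth recovery on this generator therefore
demonstrates that the pipeline implements its stated rules, not that those
rules are robust to real-world coding noise.

## Verification design and problem sizes

* **Oracle equivalence.** `derive_lines()` is checked against an
  independently coded day-by-day simulator that applies the three
  line-ending rules literally, over all hand fixtures and 1,300 random
  small claim streams (≤6 agents, ≤200-day horizons).
* **Ground-truth recovery.** On a noise-free 500-patient cohort the selected
  set equals the truth-eligible set and every derived line matches the true
  line table exactly (dates, regimen, end reason).
* **Parameter recovery.** A 2,000-patient experiment checks that the
  pipeline's observed second-line progression proportion recovers a
  configured probability of 0.4 within three binomial standard errors. The
  experiment uses a first-line mix consisting only of TKI-containing
  regimens, an early initiation window and a low dropout hazard: because
  cohort entry requires a TKI in *some* line, platinum-first patients enter
  the cohort only if they progress, so a mixed first line would make the
  observed progression proportion a selection-biased estimate of the
  configured rate — with TKI-containing first lines, selection is
  independent of progression and the observed proportion is an unbiased
  binomial draw.
* **Cost additivity.** `total = medical + pharmacy`,
  `medical = inpatient + outpatient + ED/other` and
  `outpatient = antineoplastic + other` hold to 1e-6 relative tolerance on
  every generated patient-line.
* **Interval coverage.** The Welch interval covers a true mean difference in
  95% ± 2% of 1,000 simulated two-group replicates (n = 200 per group,
  unequal variances).

These sizes (250-patient shared test cohort, 500 for recovery, 2,000 for
parameter recovery) keep the full suite comfortably fast while leaving the
binomial tolerances meaningful.

## Known limitations

* The proxy algorithm inherits the usual caveats: TKI receipt is not
  mutation status, metastatic codes are not staging, and the "other cancer"
  exclusion is a configurable code-range convention (ICD-9 140–209 /
  ICD-10 C00–C96 outside the lung-cancer set, including metastatic codes).
* The default drug dictionary is a documented stand-in for a full
  guideline-regimen list; real studies should load their own dictionary via
  the YAML configuration.
* The generator's cost and utilization magnitudes are plausible for this
  disease area but deliberately uncalibrated; nothing in the package claims
  to reproduce any particular published table.
* Lines that end in disenrollment are censored, not completed; with no
  mortality data a final line always runs to the end of observation, which
  inflates last-line durations relative to time actually on drug.
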