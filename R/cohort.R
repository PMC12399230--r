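#' Select the proxy EGFR-mutated advanced NSCLC cohort
#'
#' Applies, in order, the claims-based selection steps: (1) at least two
#' lung-cancer diagnoses on distinct service dates within one continuous
#' eligibility period; (2) exclusion of small-cell disease (a first-line
#' regimen containing etoposide, irinotecan or topotecan); (3) a washout of
#' at least 12 months of continuous eligibility before the first lung-cancer
#' diagnosis; (4) advanced disease, qualified either by first-line initiation
#' of a guideline-recommended regimen or by a metastatic diagnosis within 30
#' days (inclusive) of the first lung-cancer diagnosis followed eventually by
#' first-line initiation; (5) initiation of an EGFR-TKI during any line of
#' therapy on or after the osimertinib approval date (2018-04-18), which
#' defines the index date; (6) exclusion of patients with any other-cancer
#' diagnosis before the first lung-cancer diagnosis; and (7), among patients
#' without the 30-day metastatic qualifier, exclusion of those with a
#' lung-cancer surgery claim during eligibility before the index date.
#'
#' Continuous eligibility periods come from [normalize_enrollment()] (gaps up
#' to `codes$eligibility_bridge_days` bridged; the default 0 is strict). The
#' qualifying period is the earliest normalized span holding two lung-cancer
#' diagnosis dates; the observation period runs from first-line initiation to
#' the earlier of its end and `data_end_date`.
#'
#' @param dataset a [claims_dataset()].
#' @param codes a [code_config()].
#' @param data_end_date last date of data availability.
#' @return A list with `cohort` (one row per selected patient: identifiers,
#'   dates, qualifier, plan type, age and sex) and `attrition` (ordered
#'   steps with `n_before`, `n_after` and the `;`-joined excluded ids).
#' @export
select_cohort <- function(dataset, codes, data_end_date) {
  stopifnot(inherits(dataset, "claims_dataset"))
  data_end_date <- as_date(data_end_date)
  all_ids <- sort(unique(dataset$patients$patient_id))

  spans <- normalize_enrollment(dataset$enrollment, bridge_days = codes$eligibility_bridge_days)
  dx_long <- medical_dx_long(dataset$medical)
  lc_dx <- dx_long[is_lc_code(dx_long$code, codes)]
  lc_dx <- unique(lc_dx[, c("patient_id", "service_date"), with = FALSE])

  # earliest continuous-eligibility span containing >= 2 distinct LC dx dates
  qual <- NULL
  if (nrow(lc_dx) && nrow(spans)) {
    j <- merge(lc_dx, spans, by = "patient_id", allow.cartesian = TRUE)
    j <- j[j$service_date >= j$start_date & j$service_date <= j$end_date]
    cnt <- j[, list(n_dx = length(unique(service_date)),
                    first_lc_dx_date = min(service_date)),
             by = c("patient_id", "start_date", "end_date", "plan_type")]
    cnt <- cnt[cnt$n_dx >= 2L]
    data.table::setorderv(cnt, c("patient_id", "start_date"))
    qual <- cnt[, utils::head(.SD, 1L), by = "patient_id"]
  }
  if (is.null(qual) || nrow(qual) == 0L) {
    qual <- data.table::data.table(patient_id = character(),
                                   start_date = as.Date(character()),
                                   end_date = as.Date(character()),
                                   plan_type = character(),
                                   first_lc_dx_date = as.Date(character()))
  }
  qual[, "observation_end" := pmin(qual$end_date, data_end_date)]

  attrition <- list()
  log_step <- function(step, before, after) {
    attrition[[length(attrition) + 1L]] <<- data.table::data.table(
      step = step, n_before = length(before), n_after = length(after),
      excluded_patient_ids = paste(sort(setdiff(before, after)), collapse = ";"))
  }

  ids1 <- intersect(all_ids, qual$patient_id)
  log_step("two_lc_diagnoses_in_continuous_eligibility", all_ids, ids1)

  # lines are needed from step 2 on; derive them once per remaining patient
  eps <- treatment_episodes(dataset, codes)
  eps <- eps[eps$patient_id %in% ids1]
  eps_split <- split(eps, eps$patient_id)
  qual_idx <- match(ids1, qual$patient_id)
  lines_by_pid <- stats::setNames(vector("list", length(ids1)), ids1)
  for (k in seq_along(ids1)) {
    pid <- ids1[k]
    pe <- eps_split[[pid]]
    if (is.null(pe) || nrow(pe) == 0L) next
    lines_by_pid[[pid]] <- derive_lines(pe, qual$first_lc_dx_date[qual_idx[k]],
                                        qual$observation_end[qual_idx[k]], codes)
  }
  first_regimen <- function(pid) {
    ln <- lines_by_pid[[pid]]
    if (is.null(ln) || nrow(ln) == 0L) return(character(0))
    strsplit(ln$regimen[1L], ";", fixed = TRUE)[[1L]]
  }

  # (2) small-cell exclusion: SCLC agent in the first-line regimen
  ids2 <- ids1[!vapply(ids1, function(pid)
    any(first_regimen(pid) %in% codes$sclc_agents), logical(1))]
  log_step("sclc_exclusion", ids1, ids2)

  # (3) 12-month washout before the first LC diagnosis
  q2 <- qual[match(ids2, qual$patient_id)]
  keep3 <- as.integer(q2$first_lc_dx_date - q2$start_date) >= codes$washout_days
  ids3 <- ids2[keep3]
  log_step("washout_12m", ids2, ids3)

  # (4) advanced disease qualifier
  met_dx <- dx_long[is_metastatic_code(dx_long$code, codes)]
  q3 <- qual[match(ids3, qual$patient_id)]
  adv <- vapply(seq_along(ids3), function(k) {
    pid <- ids3[k]
    ln <- lines_by_pid[[pid]]
    if (is.null(ln) || nrow(ln) == 0L) return(NA_character_)
    reg1 <- first_regimen(pid)
    dx0 <- q3$first_lc_dx_date[k]
    met30 <- any(met_dx$patient_id == pid &
                   met_dx$service_date >= dx0 &
                   met_dx$service_date <= dx0 + codes$metastatic_window_days)
    if (met30) return("metastatic_dx_within_30d")
    if (any(reg1 %in% guideline_agents(codes))) return("regimen_initiation")
    NA_character_
  }, character(1))
  ids4 <- ids3[!is.na(adv)]
  qualifier <- stats::setNames(adv[!is.na(adv)], ids4)
  log_step("advanced_disease_qualifier", ids3, ids4)

  # (5) EGFR-TKI initiation in any line on/after the approval date
  tki_index <- vapply(ids4, function(pid) {
    ln <- lines_by_pid[[pid]]
    pe <- eps_split[[pid]]
    tki <- pe[pe$agent %in% codes$egfr_tki_agents]
    if (nrow(tki) == 0L) return(NA_real_)
    inits <- vapply(seq_len(nrow(ln)), function(i) {
      w <- tki$start_date >= ln$start_date[i] & tki$start_date <= ln$end_date[i]
      if (any(w)) as.numeric(min(tki$start_date[w])) else NA_real_
    }, numeric(1))
    inits <- inits[!is.na(inits) & inits >= as.numeric(codes$osimertinib_approval_date)]
    if (length(inits)) min(inits) else NA_real_
  }, numeric(1))
  ids5 <- ids4[!is.na(tki_index)]
  index_date <- as.Date(tki_index[!is.na(tki_index)], origin = "1970-01-01")
  names(index_date) <- ids5
  log_step("egfr_tki_on_after_approval", ids4, ids5)

  # (6) any other-cancer diagnosis before the first LC diagnosis
  oc <- dx_long[is_other_cancer_code(dx_long$code, codes)]
  q5 <- qual[match(ids5, qual$patient_id)]
  has_oc <- vapply(seq_along(ids5), function(k)
    any(oc$patient_id == ids5[k] & oc$service_date < q5$first_lc_dx_date[k]), logical(1))
  ids6 <- ids5[!has_oc]
  log_step("no_prior_other_cancer", ids5, ids6)

  # (7) LC surgery before index among patients without the metastatic qualifier
  proc_long <- medical_proc_long(dataset$medical)
  surg <- proc_long[proc_long$code %in% codes$lc_surgery_procedure_codes]
  q6 <- qual[match(ids6, qual$patient_id)]
  excl7 <- vapply(seq_along(ids6), function(k) {
    pid <- ids6[k]
    if (qualifier[[pid]] == "metastatic_dx_within_30d") return(FALSE)
    any(surg$patient_id == pid &
          surg$service_date >= q6$start_date[k] &
          surg$service_date < index_date[[pid]])
  }, logical(1))
  ids7 <- ids6[!excl7]
  log_step("no_surgery_before_index", ids6, ids7)

  qf <- qual[match(ids7, qual$patient_id)]
  pat <- dataset$patients[match(ids7, dataset$patients$patient_id)]
  first_line_start <- as.Date(vapply(ids7, function(pid)
    as.numeric(lines_by_pid[[pid]]$start_date[1L]), numeric(1)), origin = "1970-01-01")
  cohort <- data.table::data.table(
    patient_id = ids7,
    first_lc_dx_date = qf$first_lc_dx_date,
    advanced_qualifier = unname(qualifier[ids7]),
    first_line_start_date = first_line_start,
    index_date = unname(index_date[ids7]),
    baseline_start = first_line_start - codes$baseline_days,
    baseline_end = first_line_start - 1L,
    observation_end = qf$observation_end,
    plan_type = qf$plan_type,
    age_at_1l = as.integer(format(first_line_start, "%Y")) - pat$birth_year,
    sex = pat$sex)
  list(cohort = cohort, attrition = data.table::rbindlist(attrition))
}

#' Baseline characteristics for selected patients
#'
#' For each cohort record, summarizes the pre-first-line eligible period
#' (from the start of the qualifying eligibility span to the day before
#' first-line initiation): flags for corticosteroid, radiotherapy and
#' surgery use (ever, and — for radiotherapy and surgery — within 30 days
#' before first line), a brain/cerebral-meninges metastasis flag, months
#' from the first lung-cancer diagnosis to first-line initiation and to the
#' first EGFR-TKI, the Quan-Charlson comorbidity score over the 12-month
#' baseline window, and baseline monthly utilization and CPI-adjusted costs
#' over that window (denominator 12 months).
#'
#' @param cohort cohort table from [select_cohort()].
#' @param dataset the [claims_dataset()] the cohort was selected from.
#' @param codes a [code_config()].
#' @param cpi a [cpi_table()].
#' @param cci_map a [quan_cci_map()].
#' @return A `data.table`, one row per cohort patient.
#' @export
baseline_characteristics <- function(cohort, dataset, codes, cpi = cpi_table(),
                                     cci_map = quan_cci_map()) {
  dx_long <- medical_dx_long(dataset$medical)
  proc_long <- medical_proc_long(dataset$medical)
  spans <- normalize_enrollment(dataset$enrollment, bridge_days = codes$eligibility_bridge_days)
  cortico <- codes$drug_dictionary$drug[codes$drug_dictionary$class == "corticosteroid"]
  med_split <- split(dataset$medical, dataset$medical$patient_id)
  pha_split <- split(dataset$pharmacy, dataset$pharmacy$patient_id)
  dx_split <- split(dx_long, dx_long$patient_id)
  proc_split <- split(proc_long, proc_long$patient_id)
  empty_dx <- dx_long[0L]; empty_proc <- proc_long[0L]
  out <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    pid <- cohort$patient_id[i]
    s1 <- cohort$first_line_start_date[i]
    sp <- spans[spans$patient_id == pid &
                  spans$start_date <= cohort$first_lc_dx_date[i] &
                  spans$end_date >= cohort$first_lc_dx_date[i]]
    pre_start <- if (nrow(sp)) sp$start_date[1L] else cohort$baseline_start[i]
    pdx <- dx_split[[pid]] %||% empty_dx
    ppr <- proc_split[[pid]] %||% empty_proc
    pph <- pha_split[[pid]]
    ph <- if (is.null(pph)) NULL else pph[pph$fill_date >= pre_start & pph$fill_date < s1]
    pr <- ppr[ppr$service_date >= pre_start & ppr$service_date < s1]
    dxp <- pdx[pdx$service_date >= pre_start & pdx$service_date < s1]
    radio <- pr[pr$code %in% codes$radiotherapy_procedure_codes]
    surg <- pr[pr$code %in% codes$lc_surgery_procedure_codes]
    tki <- if (is.null(pph)) NULL else pph[pph$drug_code %in% codes$egfr_tki_agents]
    tki_first <- if (!is.null(tki) && nrow(tki)) min(tki$fill_date) else as.Date(NA)
    bl_dx <- pdx[pdx$service_date >= cohort$baseline_start[i] &
                   pdx$service_date <= cohort$baseline_end[i]]
    bl <- window_summary(med_split[[pid]], pph, cohort$baseline_start[i],
                         cohort$baseline_end[i], codes, cpi)
    out[[i]] <- data.table::data.table(
      patient_id = pid,
      corticosteroid_ever = !is.null(ph) && any(ph$drug_code %in% cortico),
      radiotherapy_ever = nrow(radio) > 0L,
      radiotherapy_30d = any(radio$service_date >= s1 - 30L),
      surgery_ever = nrow(surg) > 0L,
      surgery_30d = any(surg$service_date >= s1 - 30L),
      brain_met = any(is_brain_met_code(dxp$code, codes)),
      months_dx_to_1l = as.numeric(s1 - cohort$first_lc_dx_date[i]) / codes$month_days,
      months_dx_to_tki = as.numeric(tki_first - cohort$first_lc_dx_date[i]) / codes$month_days,
      quan_cci = quan_cci(bl_dx$code, cci_map),
      bl_outpatient_days_pppm = bl$outpatient_service_days / 12,
      bl_inpatient_admissions_pppm = bl$inpatient_admissions / 12,
      bl_ed_days_pppm = bl$ed_visit_days / 12,
      bl_total_cost_pppm = bl$cost_total / 12,
      bl_medical_cost_pppm = bl$cost_medical / 12,
      bl_inpatient_cost_pppm = bl$cost_inpatient / 12,
      bl_outpatient_cost_pppm = bl$cost_outpatient_total / 12,
      bl_ed_other_cost_pppm = bl$cost_ed_plus_other / 12,
      bl_pharmacy_cost_pppm = bl$cost_pharmacy / 12)
  }
  data.table::rbindlist(out)
}
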