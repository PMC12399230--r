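#' Per-patient-per-month rate
#'
#' Converts a count or amount accrued over a closed date interval into a
#' monthly rate: `value / ((end - start + 1) / 30.4375)`, with 30.4375 days
#' (365.25 / 12) as the month-length constant.
#'
#' @param value count or amount accrued over the interval.
#' @param line_start,line_end closed interval of accrual (`line_end >=
#'   line_start`).
#' @param month_days month length in days.
#' @return The rate per month.
#' @export
pppm <- function(value, line_start, line_end, month_days = MONTH_DAYS) {
  days <- as.numeric(as_date(line_end) - as_date(line_start)) + 1
  if (any(days <= 0)) stop("line_end must be on or after line_start", call. = FALSE)
  value / (days / month_days)
}

#' Adjust a nominal amount to 2022 US dollars
#'
#' Multiplies `amount` by the deflator of its service year from a
#' [cpi_table()].
#'
#' @param amount nominal USD amount(s).
#' @param service_year calendar year(s) the amount was incurred.
#' @param cpi a [cpi_table()].
#' @return Amount(s) in 2022 USD.
#' @export
cpi_adjust <- function(amount, service_year, cpi) {
  defl <- cpi$deflator_to_2022[match(service_year, cpi$year)]
  if (anyNA(defl)) {
    stop("CPI table has no deflator for year(s): ",
         paste(sort(unique(service_year[is.na(defl)])), collapse = ", "), call. = FALSE)
  }
  amount * defl
}

# raw (not yet per-month) utilization and CPI-adjusted cost components over a
# closed window, from one patient's claims
window_summary <- function(med, pha, start, end, codes, cpi) {
  if (is.null(med)) med <- data.table::data.table()
  if (is.null(pha)) pha <- data.table::data.table()
  m <- if (nrow(med)) med[med$service_date >= start & med$service_date <= end] else med
  p <- if (nrow(pha)) pha[pha$fill_date >= start & pha$fill_date <= end] else pha

  adm <- build_admissions(m)
  inpatient_days <- if (nrow(adm)) sum(overlap_days(adm$admit_date, adm$discharge_date, start, end)) else 0L
  in_admission <- function(dates) {
    if (nrow(adm) == 0L || length(dates) == 0L) return(rep(FALSE, length(dates)))
    out <- rep(FALSE, length(dates))
    for (a in seq_len(nrow(adm))) {
      out <- out | (dates >= adm$admit_date[a] & dates <= adm$discharge_date[a])
    }
    out
  }

  if (nrow(m)) {
    amt <- cpi_adjust(m$paid_amount, m$service_year, cpi)
    setting <- m$setting
    ed_in_adm <- setting == "emergency" & in_admission(m$service_date)
    is_inp <- setting == "inpatient" | ed_in_adm
    is_out <- setting == "outpatient"
    is_ed <- setting == "emergency" & !ed_in_adm
    is_other <- setting == "other"
    anti_keys <- c(antineoplastic_agents(codes), codes$admin_procedure_codes)
    has_anti <- rep(FALSE, nrow(m))
    for (pc in paste0("proc", 1:4)) has_anti <- has_anti | m[[pc]] %in% anti_keys
    cost_inpatient <- sum(amt[is_inp])
    cost_out_anti <- sum(amt[is_out & has_anti])
    cost_out_other <- sum(amt[is_out & !has_anti])
    cost_ed_other <- sum(amt[is_ed | is_other])
    outpatient_days <- length(unique(m$service_date[is_out]))
    ed_days <- length(unique(m$service_date[is_ed]))
  } else {
    cost_inpatient <- cost_out_anti <- cost_out_other <- cost_ed_other <- 0
    outpatient_days <- ed_days <- 0L
  }
  cost_pharmacy <- if (nrow(p)) sum(cpi_adjust(p$paid_amount, p$service_year, cpi)) else 0
  cost_outpatient_total <- cost_out_anti + cost_out_other
  cost_medical <- cost_inpatient + cost_outpatient_total + cost_ed_other
  list(outpatient_service_days = outpatient_days,
       inpatient_admissions = nrow(adm),
       inpatient_days = inpatient_days,
       ed_visit_days = ed_days,
       cost_inpatient = cost_inpatient,
       cost_outpatient_anti = cost_out_anti,
       cost_outpatient_other = cost_out_other,
       cost_outpatient_total = cost_outpatient_total,
       cost_ed_plus_other = cost_ed_other,
       cost_pharmacy = cost_pharmacy,
       cost_medical = cost_medical,
       cost_total = cost_medical + cost_pharmacy)
}

#' Summarize utilization and costs for lines of therapy
#'
#' For each line, restricts claims to the closed interval
#' `[start_date, end_date]` and computes all-cause healthcare resource
#' utilization and cost components, CPI-adjusted to 2022 USD and scaled per
#' patient per month. Outpatient service days count distinct dates with at
#' least one outpatient claim; admissions and inpatient days come from
#' [build_admissions()] (days clipped to the line); emergency-department
#' days are distinct ED dates outside admissions, and an ED claim during an
#' admission is counted (and costed) as inpatient. Outpatient costs are
#' split into antineoplastic-drug-plus-administration versus other via the
#' drug dictionary and the administration procedure codes; `other`-setting
#' claims are grouped with ED costs; pharmacy covers all fills, including
#' oral EGFR-TKIs. The cost identities `total = medical + pharmacy`,
#' `medical = inpatient + outpatient + ED/other` and
#' `outpatient = antineoplastic + other` hold by construction.
#'
#' @param lines line table from [derive_lines_cohort()] (or a single line as
#'   a one-row data.frame for `summarize_line`).
#' @param line a single line (one-row data.frame).
#' @param dataset a [claims_dataset()].
#' @param codes a [code_config()].
#' @param cpi a [cpi_table()].
#' @return A `data.table`, one row per line, with `duration_months`, the
#'   `*_pppm` utilization and cost columns, `any_*` indicator columns and
#'   supportive-care flags.
#' @export
summarize_lines <- function(lines, dataset, codes, cpi = cpi_table()) {
  ln <- data.table::as.data.table(lines)
  med_split <- split(dataset$medical, dataset$medical$patient_id)
  pha_split <- split(dataset$pharmacy, dataset$pharmacy$patient_id)
  out <- vector("list", nrow(ln))
  for (i in seq_len(nrow(ln))) {
    pid <- ln$patient_id[i]
    s <- ln$start_date[i]; e <- ln$end_date[i]
    w <- window_summary(med_split[[pid]], pha_split[[pid]], s, e, codes, cpi)
    sup <- supportive_care_flags_one(med_split[[pid]], pha_split[[pid]], s, e, codes)
    months <- as.numeric(e - s + 1) / codes$month_days
    out[[i]] <- data.table::data.table(
      patient_id = pid, line_number = ln$line_number[i],
      start_date = s, end_date = e,
      regimen_class = if ("regimen_class" %in% names(ln)) ln$regimen_class[i] else NA_character_,
      duration_months = months,
      outpatient_service_days_pppm = w$outpatient_service_days / months,
      inpatient_admissions_pppm = w$inpatient_admissions / months,
      inpatient_days_pppm = w$inpatient_days / months,
      ed_visit_days_pppm = w$ed_visit_days / months,
      any_outpatient = w$outpatient_service_days > 0L,
      any_inpatient = w$inpatient_admissions > 0L,
      any_ed = w$ed_visit_days > 0L,
      cost_total_pppm = w$cost_total / months,
      cost_medical_pppm = w$cost_medical / months,
      cost_inpatient_pppm = w$cost_inpatient / months,
      cost_outpatient_total_pppm = w$cost_outpatient_total / months,
      cost_outpatient_anti_pppm = w$cost_outpatient_anti / months,
      cost_outpatient_other_pppm = w$cost_outpatient_other / months,
      cost_ed_plus_other_pppm = w$cost_ed_plus_other / months,
      cost_pharmacy_pppm = w$cost_pharmacy / months,
      supportive_pain = sup$pain, supportive_respiratory = sup$respiratory,
      supportive_gcsf = sup$gcsf, supportive_esa = sup$esa)
  }
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0L) {
    res <- data.table::data.table(
      patient_id = character(), line_number = integer(),
      start_date = as.Date(character()), end_date = as.Date(character()),
      regimen_class = character(), duration_months = numeric(),
      outpatient_service_days_pppm = numeric(), inpatient_admissions_pppm = numeric(),
      inpatient_days_pppm = numeric(), ed_visit_days_pppm = numeric(),
      any_outpatient = logical(), any_inpatient = logical(), any_ed = logical(),
      cost_total_pppm = numeric(), cost_medical_pppm = numeric(),
      cost_inpatient_pppm = numeric(), cost_outpatient_total_pppm = numeric(),
      cost_outpatient_anti_pppm = numeric(), cost_outpatient_other_pppm = numeric(),
      cost_ed_plus_other_pppm = numeric(), cost_pharmacy_pppm = numeric(),
      supportive_pain = logical(), supportive_respiratory = logical(),
      supportive_gcsf = logical(), supportive_esa = logical())
  }
  res
}

#' @rdname summarize_lines
#' @export
summarize_line <- function(line, dataset, codes, cpi = cpi_table()) {
  summarize_lines(line, dataset, codes, cpi)
}

supportive_care_flags_one <- function(med, pha, start, end, codes) {
  flag <- function(category) {
    agents <- supportive_agents(codes, category)
    hit <- FALSE
    if (!is.null(pha) && nrow(pha)) {
      hit <- any(pha$drug_code %in% agents & pha$fill_date >= start & pha$fill_date <= end)
    }
    if (!hit && !is.null(med) && nrow(med)) {
      m <- med[med$service_date >= start & med$service_date <= end]
      for (pc in paste0("proc", 1:4)) hit <- hit || any(m[[pc]] %in% agents)
    }
    hit
  }
  list(pain = flag("pain"), respiratory = flag("respiratory"),
       gcsf = flag("gcsf"), esa = flag("esa"))
}

#' Supportive-care flags during a line
#'
#' Flags whether a patient has at least one claim (pharmacy fill or medical
#' claim carrying the agent key) for pain management, respiratory support,
#' G-CSF/GM-CSF or erythropoiesis-stimulating agents inside the closed line
#' interval.
#'
#' @param line one-row data.frame with `patient_id`, `start_date`,
#'   `end_date`.
#' @inheritParams summarize_lines
#' @return Named list of four logicals.
#' @export
supportive_care_flags <- function(line, dataset, codes) {
  pid <- line$patient_id[1L]
  med <- dataset$medical[dataset$medical$patient_id == pid]
  pha <- dataset$pharmacy[dataset$pharmacy$patient_id == pid]
  supportive_care_flags_one(med, pha, as_date(line$start_date[1L]),
                            as_date(line$end_date[1L]), codes)
}

#' Quan-Charlson comorbidity score
#'
#' Computes the Charlson comorbidity index from a bag of ICD-9/10 diagnosis
#' codes using prefix matching against a Quan-style condition map. Within a
#' hierarchy group only the highest-weight condition present counts
#' (metastatic solid tumor supersedes malignancy, severe supersedes mild
#' liver disease, complicated supersedes uncomplicated diabetes). Adding
#' codes can never decrease the score.
#'
#' @param dx_codes character vector of diagnosis codes (typically all codes
#'   observed in a patient's baseline window).
#' @param map a [quan_cci_map()].
#' @return Integer score.
#' @export
quan_cci <- function(dx_codes, map = quan_cci_map()) {
  if (length(dx_codes) == 0L) return(0L)
  present <- vapply(seq_len(nrow(map)), function(i)
    any(match_prefix(dx_codes, c(map$icd9[[i]], map$icd10[[i]]))), logical(1))
  if (!any(present)) return(0L)
  hit <- data.table::data.table(group = map$hierarchy_group[present],
                                weight = map$weight[present])
  sum(hit[, list(w = max(weight)), by = "group"]$w)
}
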