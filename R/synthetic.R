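#' Simulation configuration for the synthetic claims generator
#'
#' Defaults target the magnitudes of published claims-based NSCLC
#' treatment-sequencing cohorts (for example ~68% first-line osimertinib
#' monotherapy, ~42% progression to second line, heavily right-skewed costs,
#' ~90% metastatic coding within 30 days of the first lung-cancer diagnosis)
#' without being calibrated to reproduce any particular table. All
#' probability vectors must sum to 1.
#'
#' Archetypes control which cohort filter a simulated patient exercises:
#' `eligible` patients follow the full advanced-NSCLC journey; `sclc`
#' patients receive a first-line small-cell regimen (etoposide + platinum);
#' `other_cancer` patients carry a malignancy diagnosis before the first
#' lung-cancer diagnosis; `washout` patients enroll less than 12 months
#' before it; `no_advanced` patients receive no systemic regimen and no
#' 30-day metastatic diagnosis; `surgery_excluded` patients lack the 30-day
#' metastatic diagnosis and have lung-cancer surgery before the index date;
#' `pre_approval_tki` patients initiate their only EGFR-TKI before the
#' osimertinib approval date.
#'
#' @param ... named overrides of any default element.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_patients = 500L,
    seed = 20180418L,
    data_start = as.Date("2010-01-01"),
    data_end = as.Date("2023-01-31"),
    age_mean = 60.5, age_sd = 10, prob_female = 0.702,
    plan_mix = c(commercial = 0.68, medicare_supplemental = 0.232, medicaid = 0.088),
    archetype_mix = c(eligible = 0.80, sclc = 0.04, other_cancer = 0.04,
                      washout = 0.04, no_advanced = 0.03, surgery_excluded = 0.03,
                      pre_approval_tki = 0.02),
    first_line_window = as.Date(c("2018-05-01", "2022-06-30")),
    prob_metastatic_dx_within_30d = 0.9,
    prob_brain_met = 0.44,
    first_line_mix = c(osimertinib_mono = 0.682, osimertinib_plus_chemo = 0.047,
                       other_egfr_tki = 0.046, pbc_no_io = 0.10, pbc_plus_io = 0.06,
                       io_mono = 0.015, other_chemo = 0.05),
    # lognormal (meanlog, sdlog) of line duration in months, by regimen class
    line_duration_months = list(
      osimertinib_mono = c(meanlog = 2.16, sdlog = 0.8),
      osimertinib_plus_chemo = c(meanlog = 2.00, sdlog = 0.8),
      other_egfr_tki = c(meanlog = 1.90, sdlog = 0.8),
      pbc_no_io = c(meanlog = 1.46, sdlog = 0.8),
      pbc_plus_io = c(meanlog = 1.60, sdlog = 0.8),
      io_mono = c(meanlog = 1.70, sdlog = 0.8),
      other_chemo = c(meanlog = 1.50, sdlog = 0.8)),
    prob_progress_to_2l = 0.416,
    prob_progress_to_3l = 0.50,
    second_line_mix = default_transition_mix(),
    third_line_mix = default_transition_mix(),
    outpatient_visit_rate_pppm = c(osimertinib_mono = 4.0, osimertinib_plus_chemo = 4.0,
                                   other_egfr_tki = 4.0, pbc_no_io = 6.4, pbc_plus_io = 6.4,
                                   io_mono = 4.0, other_chemo = 4.5),
    inpatient_admission_rate_pppm = c(osimertinib_mono = 0.08, osimertinib_plus_chemo = 0.08,
                                      other_egfr_tki = 0.08, pbc_no_io = 0.05, pbc_plus_io = 0.06,
                                      io_mono = 0.08, other_chemo = 0.08),
    ed_visit_rate_pppm = c(osimertinib_mono = 0.13, osimertinib_plus_chemo = 0.13,
                           other_egfr_tki = 0.13, pbc_no_io = 0.11, pbc_plus_io = 0.11,
                           io_mono = 0.13, other_chemo = 0.13),
    inpatient_los_extra_mean = 2,    # LOS = 1 + Poisson(this) days
    baseline_outpatient_rate_pppm = 1.96,
    baseline_inpatient_rate_pppm = 0.05,
    baseline_ed_rate_pppm = 0.09,
    # lognormal (meanlog, sdlog) of per-event nominal USD amounts
    cost_lognormal = list(
      inpatient_day = c(meanlog = 7.6, sdlog = 0.9),
      outpatient_visit = c(meanlog = 6.4, sdlog = 1.0),
      ed_visit = c(meanlog = 7.0, sdlog = 0.8),
      pharmacy_fill = c(meanlog = 9.64, sdlog = 0.15),
      infusion_admin = c(meanlog = 7.9, sdlog = 0.7),
      supportive_fill = c(meanlog = 3.9, sdlog = 0.8)),
    comorbidity_mean = 1.2,
    prob_pre1l_corticosteroid = 0.80,
    prob_pre1l_radiotherapy = 0.41,
    prob_pre1l_surgery_given_met = 0.21,
    prob_supportive_pain = 0.65,
    prob_supportive_respiratory = 0.06,
    prob_supportive_gcsf_chemo = 0.20,
    prob_supportive_gcsf_other = 0.02,
    prob_supportive_esa = 0.015,
    enrollment_dropout_hazard = 0.04, # monthly
    prob_extra_enrollment_span = 0.10,
    prob_non_regimen_decoy_claim = 0.0,
    prob_retreatment_gap = 0.05
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) stop("unknown sim_config element(s): ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    cfg[names(dots)] <- dots
  }
  cfg$data_start <- as_date(cfg$data_start); cfg$data_end <- as_date(cfg$data_end)
  if (cfg$n_patients < 0) stop("n_patients must be nonnegative", call. = FALSE)
  assert_prob_vector(cfg$plan_mix, "plan_mix")
  assert_prob_vector(cfg$archetype_mix, "archetype_mix")
  assert_prob_vector(cfg$first_line_mix, "first_line_mix")
  for (nm in names(cfg$second_line_mix)) assert_prob_vector(cfg$second_line_mix[[nm]],
                                                            paste0("second_line_mix$", nm))
  for (nm in names(cfg$third_line_mix)) assert_prob_vector(cfg$third_line_mix[[nm]],
                                                           paste0("third_line_mix$", nm))
  for (nm in names(cfg$cost_lognormal)) {
    if (cfg$cost_lognormal[[nm]][["sdlog"]] < 0) stop("sdlog must be >= 0", call. = FALSE)
  }
  if (any(cfg$outpatient_visit_rate_pppm < 0) || any(cfg$inpatient_admission_rate_pppm < 0) ||
      any(cfg$ed_visit_rate_pppm < 0)) stop("event rates must be >= 0", call. = FALSE)
  structure(cfg, class = "sim_config")
}

# next-line class probabilities conditioned on the prior line's class
default_transition_mix <- function() {
  list(
    osimertinib_mono = c(osimertinib_plus_chemo = 0.25, pbc_no_io = 0.25, pbc_plus_io = 0.15,
                         other_egfr_tki = 0.13, io_mono = 0.12, other_chemo = 0.10),
    osimertinib_plus_chemo = c(pbc_no_io = 0.30, pbc_plus_io = 0.20, other_egfr_tki = 0.20,
                               io_mono = 0.15, other_chemo = 0.15),
    other_egfr_tki = c(osimertinib_mono = 0.50, pbc_no_io = 0.20, pbc_plus_io = 0.10,
                       io_mono = 0.10, other_chemo = 0.10),
    pbc_no_io = c(osimertinib_mono = 0.60, other_egfr_tki = 0.10, pbc_plus_io = 0.10,
                  io_mono = 0.10, other_chemo = 0.10),
    pbc_plus_io = c(osimertinib_mono = 0.60, other_egfr_tki = 0.10, pbc_no_io = 0.10,
                    io_mono = 0.10, other_chemo = 0.10),
    io_mono = c(osimertinib_mono = 0.40, pbc_no_io = 0.30, pbc_plus_io = 0.20,
                other_chemo = 0.10),
    other_chemo = c(osimertinib_mono = 0.50, pbc_no_io = 0.20, pbc_plus_io = 0.20,
                    io_mono = 0.10))
}

SIM_CLASS_TO_REGIMEN_CLASS <- c(
  osimertinib_mono = "osimertinib_based", osimertinib_plus_chemo = "osimertinib_based",
  other_egfr_tki = "other_egfr_tki", pbc_no_io = "pbc_regimen", pbc_plus_io = "pbc_regimen",
  io_mono = "io_mono", other_chemo = "other_chemo", sclc = "other_chemo",
  pre_approval_tki = "other_egfr_tki")

rlnorm1 <- function(n, par) stats::rlnorm(n, meanlog = par[["meanlog"]], sdlog = par[["sdlog"]])

sample1 <- function(x, prob = NULL) x[sample.int(length(x), 1L, prob = prob)]

icd10_era <- function(date) date >= as.Date("2015-10-01")

sim_lc_code <- function(date) ifelse(icd10_era(date), "C3490", "16290")

sim_met_code <- function(date, brain = FALSE) {
  if (brain) return(if (icd10_era(date)) "C7931" else "1983")
  if (icd10_era(date)) sample1(c("C779", "C7800", "C787", "C7951"))
  else sample1(c("1970", "1977", "1985"))
}

sim_benign_code <- function(date) sample1(c("I10", "E785", "J069", "M545", "R05", "Z0000"))

sim_comorbidity_code <- function(date) {
  if (icd10_era(date)) sample1(c("J449", "I509", "E119", "E112", "N189", "K740",
                                 "I639", "I709", "M059", "K259"))
  else sample1(c("496", "42800", "25000", "5859", "5712"))
}

PROVIDER_TYPES <- c("acute_care_hospital", "oncologist", "radiologist",
                    "general_physician", "laboratory")

# realize an agent set for a simulated regimen class; guarantees at least one
# agent not in `prior` so the next line is detectable as a new regimen
realize_regimen <- function(class, prior = character(0)) {
  pick <- function() switch(class,
    osimertinib_mono = "osimertinib",
    osimertinib_plus_chemo = c("osimertinib", sample1(c("carboplatin", "cisplatin")), "pemetrexed"),
    other_egfr_tki = sample1(c("erlotinib", "gefitinib", "afatinib", "dacomitinib")),
    pbc_no_io = c(sample1(c("carboplatin", "cisplatin")),
                  sample1(c("pemetrexed", "paclitaxel", "gemcitabine", "docetaxel"))),
    pbc_plus_io = c(sample1(c("carboplatin", "cisplatin")), "pemetrexed",
                    sample1(c("pembrolizumab", "nivolumab", "atezolizumab"))),
    io_mono = sample1(c("pembrolizumab", "nivolumab", "atezolizumab")),
    other_chemo = sample1(c("docetaxel", "gemcitabine", "vinorelbine")),
    sclc = c(sample1(c("carboplatin", "cisplatin")), "etoposide"),
    pre_approval_tki = sample1(c("erlotinib", "gefitinib")),
    stop("unknown regimen class: ", class, call. = FALSE))
  for (try in 1:20) {
    r <- unique(pick())
    if (length(setdiff(r, prior)) > 0L && !setequal(r, prior)) return(sort(r))
  }
  spare <- setdiff(c("vinorelbine", "docetaxel", "gemcitabine", "paclitaxel"), prior)
  sort(unique(c(pick(), spare[1L])))
}

med_rows <- function(pid, dates, end_dates, setting, dx1, proc1 = "", proc2 = "",
                     provider, paid) {
  n <- length(dates)
  if (n == 0L) return(NULL)
  data.table::data.table(
    patient_id = pid, service_date = dates, end_date = end_dates, setting = setting,
    dx1 = rep_len(dx1, n), dx2 = "", dx3 = "", dx4 = "",
    proc1 = rep_len(proc1, n), proc2 = rep_len(proc2, n), proc3 = "", proc4 = "",
    provider_type = rep_len(provider, n), paid_amount = round(paid, 2))
}

pha_rows <- function(pid, dates, drug, days_supply, paid) {
  n <- length(dates)
  if (n == 0L) return(NULL)
  data.table::data.table(patient_id = pid, fill_date = dates,
                         drug_code = rep_len(drug, n),
                         days_supply = as.integer(rep_len(days_supply, n)),
                         paid_amount = round(paid, 2))
}

# claims for one line's regimen: oral TKIs as 30-day-supply fills, everything
# else as 21-day-cycle outpatient infusion claims carrying the drug key plus
# an administration procedure code
emit_regimen_claims <- function(pid, regimen, s, u, cfg, codes) {
  med <- list(); pha <- list()
  if (u < s) u <- s
  for (agent in regimen) {
    cls <- drug_class(agent, codes)
    if (identical(cls, "egfr_tki")) {
      dates <- seq(s, u, by = 30L)
      pha[[length(pha) + 1L]] <- pha_rows(pid, dates, agent, 30L,
                                          rlnorm1(length(dates), cfg$cost_lognormal$pharmacy_fill))
    } else {
      dates <- seq(s, u, by = 21L)
      med[[length(med) + 1L]] <- med_rows(pid, dates, dates, "outpatient",
                                          sim_lc_code(s), proc1 = agent,
                                          proc2 = codes$admin_procedure_codes[3L],
                                          provider = "oncologist",
                                          paid = rlnorm1(length(dates), cfg$cost_lognormal$infusion_admin))
    }
  }
  list(med = med, pha = pha)
}

# background utilization over [s, e]: outpatient visits, admissions, ED visits
emit_hru_claims <- function(pid, s, e, rate_out, rate_inp, rate_ed, cfg, obs_end,
                            dx_pool_lc = TRUE) {
  med <- list()
  months <- as.numeric(e - s + 1L) / MONTH_DAYS
  if (months <= 0) return(med)
  span <- as.integer(e - s)
  rand_dates <- function(n) s + sample.int(span + 1L, n, replace = TRUE) - 1L
  n_out <- stats::rpois(1L, rate_out * months)
  if (n_out > 0L) {
    dates <- rand_dates(n_out)
    dx <- vapply(seq_len(n_out), function(i)
      if (dx_pool_lc && stats::runif(1) < 0.5) sim_lc_code(dates[i]) else sim_benign_code(dates[i]),
      character(1))
    med[[length(med) + 1L]] <- med_rows(pid, dates, dates, "outpatient", dx,
                                        provider = sample(PROVIDER_TYPES, n_out, replace = TRUE),
                                        paid = rlnorm1(n_out, cfg$cost_lognormal$outpatient_visit))
  }
  n_adm <- stats::rpois(1L, rate_inp * months)
  if (n_adm > 0L) {
    admit <- rand_dates(n_adm)
    los <- 1L + stats::rpois(n_adm, cfg$inpatient_los_extra_mean)
    discharge <- pmin(admit + los - 1L, obs_end)
    days <- as.integer(discharge - admit + 1L)
    med[[length(med) + 1L]] <- med_rows(pid, admit, discharge, "inpatient",
                                        if (dx_pool_lc) vapply(admit, sim_lc_code, character(1))
                                        else vapply(admit, sim_benign_code, character(1)),
                                        provider = "acute_care_hospital",
                                        paid = days * rlnorm1(n_adm, cfg$cost_lognormal$inpatient_day))
  }
  n_ed <- stats::rpois(1L, rate_ed * months)
  if (n_ed > 0L) {
    dates <- rand_dates(n_ed)
    med[[length(med) + 1L]] <- med_rows(pid, dates, dates, "emergency",
                                        vapply(dates, sim_benign_code, character(1)),
                                        provider = "acute_care_hospital",
                                        paid = rlnorm1(n_ed, cfg$cost_lognormal$ed_visit))
  }
  med
}

#' Generate a synthetic claims dataset with ground truth
#'
#' Simulates patient-level journeys (enrollment spans with washout history,
#' lung-cancer and metastatic diagnoses, treatment lines with oral
#' 30-day-supply fills and 21-day infusion cycles, background utilization
#' with log-normal per-event costs, supportive care, and rule-violating
#' decoy archetypes) and returns both the resulting [claims_dataset()] and
#' the generating truth, so cohort selection and line derivation can be
#' verified against known labels. Deterministic for a fixed
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @param codes a [code_config()] (the default dictionary).
#' @return A list of class `oncolot_sim` with elements `dataset`
#'   ([claims_dataset()]), `truth` (list of `patients` and `lines`
#'   `data.table`s) and `config`.
#' @export
generate_claims <- function(config = sim_config(), codes = code_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(config$seed)
  }
  n <- config$n_patients
  pats <- vector("list", n); enr <- vector("list", n)
  med <- vector("list", n); pha <- vector("list", n)
  truth_p <- vector("list", n); truth_l <- vector("list", n)
  for (i in seq_len(n)) {
    p <- sim_patient(sprintf("P%05d", i), config, codes)
    pats[[i]] <- p$patient; enr[[i]] <- p$enrollment
    med[[i]] <- p$medical; pha[[i]] <- p$pharmacy
    truth_p[[i]] <- p$truth_patient; truth_l[[i]] <- p$truth_lines
  }
  empty_med <- med_rows("x", as.Date("2000-01-01"), as.Date("2000-01-01"),
                        "outpatient", "", provider = "", paid = 0)[0L]
  empty_pha <- pha_rows("x", as.Date("2000-01-01"), "x", 1L, 0)[0L]
  dataset <- claims_dataset(
    patients = if (n > 0L) data.table::rbindlist(pats) else data.table::data.table(
      patient_id = character(), birth_year = integer(), sex = character()),
    enrollment = if (n > 0L) data.table::rbindlist(enr) else data.table::data.table(
      patient_id = character(), start_date = as.Date(character()),
      end_date = as.Date(character()), plan_type = character()),
    medical = if (n > 0L) data.table::rbindlist(med) else empty_med,
    pharmacy = if (n > 0L) data.table::rbindlist(pha, fill = TRUE) else empty_pha)
  truth <- list(patients = data.table::rbindlist(truth_p, fill = TRUE),
                lines = data.table::rbindlist(truth_l, fill = TRUE))
  structure(list(dataset = dataset, truth = truth, config = config), class = "oncolot_sim")
}

sim_patient <- function(pid, cfg, codes) {
  archetype <- sample1(names(cfg$archetype_mix), prob = cfg$archetype_mix)
  sex <- if (stats::runif(1) < cfg$prob_female) "F" else "M"
  plan <- sample1(names(cfg$plan_mix), prob = cfg$plan_mix)

  if (archetype == "pre_approval_tki") {
    t1l <- as.Date("2014-01-01") + sample.int(912L, 1L) - 1L   # 2014-01-01 .. 2016-06-30
  } else {
    w <- as_date(cfg$first_line_window)
    t1l <- w[1L] + sample.int(as.integer(w[2L] - w[1L]) + 1L, 1L) - 1L
  }
  age <- max(18L, min(90L, round(stats::rnorm(1, cfg$age_mean, cfg$age_sd))))
  birth_year <- as.integer(format(t1l, "%Y")) - age

  dx_gap <- max(7L, min(365L, round(stats::rlnorm(1, log(30), 0.6))))
  dx <- t1l - dx_gap
  span_start <- if (archetype == "washout") dx - sample(30:330, 1L) else dx - 365L - sample(0:365, 1L)
  follow_days <- max(60L, round(stats::rexp(1, rate = cfg$enrollment_dropout_hazard / MONTH_DAYS)))
  obs_end <- min(t1l + follow_days, cfg$data_end)

  enrollment <- data.table::data.table(patient_id = pid, start_date = span_start,
                                       end_date = obs_end, plan_type = plan)
  if (stats::runif(1) < cfg$prob_extra_enrollment_span) {
    enrollment <- rbind(data.table::data.table(
      patient_id = pid, start_date = span_start - 900L, end_date = span_start - 400L,
      plan_type = plan), enrollment)
  }

  med <- list(); pha <- list()

  # two lung-cancer diagnoses on distinct days
  dx2 <- dx + sample(5:20, 1L)
  med[[length(med) + 1L]] <- med_rows(pid, c(dx, dx2), c(dx, dx2), "outpatient",
                                      c(sim_lc_code(dx), sim_lc_code(dx2)),
                                      provider = "oncologist",
                                      paid = rlnorm1(2L, cfg$cost_lognormal$outpatient_visit))

  # metastatic qualifier
  no_met30 <- archetype %in% c("no_advanced", "surgery_excluded")
  has_met30 <- !no_met30 && stats::runif(1) < cfg$prob_metastatic_dx_within_30d
  brain_met <- FALSE
  if (has_met30) {
    # inside the 30-day window and before first-line initiation, so the
    # metastasis is visible in the baseline period
    met_date <- dx + sample(0:min(30L, as.integer(t1l - dx) - 1L), 1L)
    brain_met <- stats::runif(1) < cfg$prob_brain_met
    med[[length(med) + 1L]] <- med_rows(pid, met_date, met_date, "outpatient",
                                        sim_met_code(met_date, brain_met),
                                        provider = "oncologist",
                                        paid = rlnorm1(1L, cfg$cost_lognormal$outpatient_visit))
  } else if (no_met30 && stats::runif(1) < 0.5) {
    late_met <- dx + sample(32:60, 1L)  # strictly outside the 30-day window
    if (late_met < obs_end) {
      med[[length(med) + 1L]] <- med_rows(pid, late_met, late_met, "outpatient",
                                          sim_met_code(late_met), provider = "oncologist",
                                          paid = rlnorm1(1L, cfg$cost_lognormal$outpatient_visit))
    }
  }

  # prior-malignancy decoy
  if (archetype == "other_cancer") {
    oc_date <- dx - sample(50:300, 1L)
    oc_code <- if (icd10_era(oc_date)) sample1(c("C509", "C61", "C189")) else sample1(c("174", "185", "153"))
    med[[length(med) + 1L]] <- med_rows(pid, oc_date, oc_date, "outpatient", oc_code,
                                        provider = "general_physician",
                                        paid = rlnorm1(1L, cfg$cost_lognormal$outpatient_visit))
  }

  # baseline comorbidities (non-malignant codes only)
  n_com <- min(3L, stats::rpois(1L, cfg$comorbidity_mean))
  if (n_com > 0L) {
    dates <- t1l - sample(30:300, n_com, replace = TRUE)
    dates <- pmax(dates, span_start)
    med[[length(med) + 1L]] <- med_rows(pid, dates, dates, "outpatient",
                                        vapply(dates, sim_comorbidity_code, character(1)),
                                        provider = "general_physician",
                                        paid = rlnorm1(n_com, cfg$cost_lognormal$outpatient_visit))
  }

  # baseline background utilization over the year before 1L
  base_start <- max(span_start, t1l - 365L)
  med <- c(med, emit_hru_claims(pid, base_start, t1l - 1L,
                                cfg$baseline_outpatient_rate_pppm,
                                cfg$baseline_inpatient_rate_pppm,
                                cfg$baseline_ed_rate_pppm, cfg, obs_end,
                                dx_pool_lc = FALSE))

  # pre-1L lung-cancer-directed treatment
  if (stats::runif(1) < cfg$prob_pre1l_corticosteroid) {
    cdate <- max(span_start, t1l - sample(10:120, 1L))
    pha[[length(pha) + 1L]] <- pha_rows(pid, cdate, "dexamethasone", 10L,
                                        rlnorm1(1L, cfg$cost_lognormal$supportive_fill))
  }
  if (t1l - dx >= 4L && stats::runif(1) < cfg$prob_pre1l_radiotherapy) {
    rdate <- dx + sample.int(as.integer(t1l - dx) - 1L, 1L)
    med[[length(med) + 1L]] <- med_rows(pid, rdate, rdate, "outpatient", sim_lc_code(rdate),
                                        proc1 = sample1(codes$radiotherapy_procedure_codes),
                                        provider = "radiologist",
                                        paid = rlnorm1(1L, cfg$cost_lognormal$outpatient_visit))
  }
  has_surgery <- archetype == "surgery_excluded" ||
    (has_met30 && stats::runif(1) < cfg$prob_pre1l_surgery_given_met)
  if (has_surgery && t1l - dx >= 4L) {
    sdate <- dx + sample.int(as.integer(t1l - dx) - 1L, 1L)
    med[[length(med) + 1L]] <- med_rows(pid, sdate, sdate, "outpatient", sim_lc_code(sdate),
                                        proc1 = sample1(codes$lc_surgery_procedure_codes),
                                        provider = "acute_care_hospital",
                                        paid = rlnorm1(1L, cfg$cost_lognormal$outpatient_visit))
  } else if (archetype == "surgery_excluded") {
    # the decoy needs the surgery claim even for short dx-to-1L gaps
    med[[length(med) + 1L]] <- med_rows(pid, dx + 1L, dx + 1L, "outpatient", sim_lc_code(dx),
                                        proc1 = codes$lc_surgery_procedure_codes[2L],
                                        provider = "acute_care_hospital",
                                        paid = rlnorm1(1L, cfg$cost_lognormal$outpatient_visit))
    has_surgery <- TRUE
  }

  # ---- treatment lines -----------------------------------------------------
  sim_classes <- character(0); regimens <- list(); starts <- as.Date(character(0))
  end_reasons <- character(0)
  progressed_2l <- NA; progressed_3l <- NA
  if (archetype == "sclc") {
    sim_classes <- "sclc"; regimens <- list(realize_regimen("sclc")); starts <- t1l
  } else if (archetype == "pre_approval_tki") {
    sim_classes <- "pre_approval_tki"; regimens <- list(realize_regimen("pre_approval_tki"))
    starts <- t1l
  } else if (archetype != "no_advanced") {
    c1 <- if (archetype == "surgery_excluded") "osimertinib_mono"
          else sample1(names(cfg$first_line_mix), prob = cfg$first_line_mix)
    r1 <- realize_regimen(c1)
    d1 <- max(28L, round(stats::rlnorm(1, cfg$line_duration_months[[c1]][["meanlog"]],
                                       cfg$line_duration_months[[c1]][["sdlog"]]) * MONTH_DAYS))
    sim_classes <- c1; regimens <- list(r1); starts <- t1l
    progressed_2l <- stats::runif(1) < cfg$prob_progress_to_2l
    if (progressed_2l) {
      s2 <- t1l + d1
      if (s2 <= obs_end) {
        mix2 <- cfg$second_line_mix[[c1]]
        c2 <- sample1(names(mix2), prob = mix2)
        r2 <- realize_regimen(c2, prior = r1)
        sim_classes <- c(sim_classes, c2); regimens <- c(regimens, list(r2))
        starts <- c(starts, s2)
        progressed_3l <- stats::runif(1) < cfg$prob_progress_to_3l
        if (progressed_3l) {
          d2 <- max(28L, round(stats::rlnorm(1, cfg$line_duration_months[[c2]][["meanlog"]],
                                             cfg$line_duration_months[[c2]][["sdlog"]]) * MONTH_DAYS))
          s3 <- s2 + d2
          if (s3 <= obs_end) {
            mix3 <- cfg$third_line_mix[[c2]]
            c3 <- sample1(names(mix3), prob = mix3)
            r3 <- realize_regimen(c3, prior = r2)
            sim_classes <- c(sim_classes, c3); regimens <- c(regimens, list(r3))
            starts <- c(starts, s3)
          }
        }
      }
    } else if (stats::runif(1) < cfg$prob_retreatment_gap) {
      # stop, then resume the same regimen after a >90-day gap
      stop_claims <- t1l + d1
      supply_tail <- if (any(drug_class(r1, codes) == "egfr_tki")) 29L else 0L
      resume <- stop_claims + supply_tail + 91L + sample(0:60, 1L)
      if (resume <= obs_end - 14L) {
        sim_classes <- c(c1, c1); regimens <- list(r1, r1); starts <- c(t1l, resume)
        attr(starts, "retreat_stop") <- stop_claims
      }
    }
  }

  n_lines <- length(starts)
  ends <- as.Date(character(0)); claim_until <- as.Date(character(0))
  if (n_lines > 0L) {
    ends <- if (n_lines > 1L) c(starts[-1L] - 1L, obs_end) else obs_end
    retreat_stop <- attr(starts, "retreat_stop")
    planned_last <- {
      cl <- sim_classes[n_lines]
      par <- cfg$line_duration_months[[if (cl %in% names(cfg$line_duration_months)) cl else "other_chemo"]]
      max(28L, round(stats::rlnorm(1, par[["meanlog"]], par[["sdlog"]]) * MONTH_DAYS))
    }
    claim_until <- ends
    claim_until[n_lines] <- min(starts[n_lines] + planned_last, obs_end)
    if (!is.null(retreat_stop)) claim_until[1L] <- min(retreat_stop, obs_end)
    end_reasons <- c(if (n_lines > 1L) {
      if (!is.null(retreat_stop)) "retreatment_gap" else rep("new_agent", n_lines - 1L)
    }, "end_of_observation")
    if (n_lines == 3L) end_reasons <- c("new_agent", "new_agent", "end_of_observation")

    for (k in seq_len(n_lines)) {
      rc <- emit_regimen_claims(pid, regimens[[k]], starts[k], claim_until[k], cfg, codes)
      med <- c(med, rc$med); pha <- c(pha, rc$pha)
      cl <- sim_classes[k]
      rate_key <- if (cl %in% names(cfg$outpatient_visit_rate_pppm)) cl else "other_chemo"
      med <- c(med, emit_hru_claims(pid, starts[k], ends[k],
                                    cfg$outpatient_visit_rate_pppm[[rate_key]],
                                    cfg$inpatient_admission_rate_pppm[[rate_key]],
                                    cfg$ed_visit_rate_pppm[[rate_key]], cfg, obs_end))
      # supportive care during the line
      span_days <- as.integer(ends[k] - starts[k])
      rand_date <- function() starts[k] + sample.int(span_days + 1L, 1L) - 1L
      if (stats::runif(1) < cfg$prob_supportive_pain) {
        nfill <- sample(1:3, 1L)
        pha[[length(pha) + 1L]] <- pha_rows(pid, starts[k] + sample.int(span_days + 1L, nfill, replace = TRUE) - 1L,
                                            sample1(supportive_agents(codes, "pain")), 14L,
                                            rlnorm1(nfill, cfg$cost_lognormal$supportive_fill))
      }
      if (stats::runif(1) < cfg$prob_supportive_respiratory) {
        pha[[length(pha) + 1L]] <- pha_rows(pid, rand_date(), sample1(supportive_agents(codes, "respiratory")),
                                            30L, rlnorm1(1L, cfg$cost_lognormal$supportive_fill))
      }
      p_gcsf <- if (grepl("pbc|chemo", cl)) cfg$prob_supportive_gcsf_chemo else cfg$prob_supportive_gcsf_other
      if (stats::runif(1) < p_gcsf) {
        pha[[length(pha) + 1L]] <- pha_rows(pid, rand_date(), sample1(supportive_agents(codes, "gcsf")),
                                            1L, rlnorm1(1L, cfg$cost_lognormal$supportive_fill) * 20)
      }
      if (stats::runif(1) < cfg$prob_supportive_esa) {
        pha[[length(pha) + 1L]] <- pha_rows(pid, rand_date(), sample1(supportive_agents(codes, "esa")),
                                            1L, rlnorm1(1L, cfg$cost_lognormal$supportive_fill) * 10)
      }
    }

    # optional non-regimen decoy claim (noise knob; breaks exact recovery)
    if (stats::runif(1) < cfg$prob_non_regimen_decoy_claim) {
      k <- sample.int(n_lines, 1L)
      pool <- setdiff(antineoplastic_agents(codes), unlist(regimens))
      if (length(pool) && ends[k] - starts[k] > 25L) {
        ddate <- starts[k] + 22L + sample.int(as.integer(ends[k] - starts[k]) - 22L, 1L)
        med[[length(med) + 1L]] <- med_rows(pid, ddate, ddate, "outpatient", sim_lc_code(ddate),
                                            proc1 = sample1(pool), proc2 = codes$admin_procedure_codes[3L],
                                            provider = "oncologist",
                                            paid = rlnorm1(1L, cfg$cost_lognormal$infusion_admin))
      }
    }
  }

  # ---- truth ---------------------------------------------------------------
  tki_starts <- if (n_lines > 0L) {
    starts[vapply(regimens, function(r) any(r %in% codes$egfr_tki_agents), logical(1))]
  } else as.Date(character(0))
  tki_ok <- tki_starts[tki_starts >= codes$osimertinib_approval_date]
  index_date <- if (length(tki_ok)) min(tki_ok) else as.Date(NA)

  fail_step <- NA_character_
  if (archetype == "sclc") fail_step <- "sclc_exclusion"
  else if (archetype == "washout") fail_step <- "washout"
  else if (n_lines == 0L) fail_step <- "advanced_qualifier"
  else if (is.na(index_date)) fail_step <- "egfr_tki_index"
  else if (archetype == "other_cancer") fail_step <- "other_cancer"
  else if (!has_met30 && has_surgery) fail_step <- "surgery_before_index"

  truth_patient <- data.table::data.table(
    patient_id = pid, archetype = archetype, sex = sex, birth_year = birth_year,
    plan_type = plan, enrollment_start = span_start, observation_end = obs_end,
    first_lc_dx_date = dx, met_within_30d = has_met30, brain_met = brain_met,
    first_line_start = if (n_lines > 0L) starts[1L] else as.Date(NA),
    index_date = index_date, n_lines = n_lines,
    progressed_2l = progressed_2l, progressed_3l = progressed_3l,
    eligible = is.na(fail_step), fail_step = fail_step)

  truth_lines <- if (n_lines > 0L) data.table::data.table(
    patient_id = pid, line_number = seq_len(n_lines),
    start_date = as.Date(starts, origin = "1970-01-01"), end_date = ends,
    regimen = vapply(regimens, function(r) paste(sort(r), collapse = ";"), character(1)),
    sim_class = sim_classes,
    regimen_class = unname(SIM_CLASS_TO_REGIMEN_CLASS[sim_classes]),
    end_reason = end_reasons) else NULL

  list(patient = data.table::data.table(patient_id = pid, birth_year = birth_year, sex = sex),
       enrollment = enrollment,
       medical = data.table::rbindlist(med),
       pharmacy = if (length(pha)) data.table::rbindlist(pha) else
         data.table::data.table(patient_id = character(), fill_date = as.Date(character()),
                                drug_code = character(), days_supply = integer(),
                                paid_amount = numeric()),
       truth_patient = truth_patient, truth_lines = truth_lines)
}

#' Write a simulated dataset (claims CSVs plus truth tables)
#'
#' @param sim result of [generate_claims()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "oncolot_sim"))
  write_claims(sim$dataset, dir)
  data.table::fwrite(sim$truth$patients, file.path(dir, "truth_patients.csv"))
  data.table::fwrite(sim$truth$lines, file.path(dir, "truth_lines.csv"))
  invisible(dir)
}
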