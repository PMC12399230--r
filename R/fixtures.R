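# Hand-constructed micro-datasets pinning the tricky selection and
# line-derivation rules. Each fixture is a single patient (or pair) built
# around a common template: enrollment 2017-01-01..2022-12-31, first
# lung-cancer diagnosis 2019-01-10 with a confirmatory diagnosis ten days
# later, metastatic diagnosis 2019-01-15, first line starting 2019-02-01.

FIXTURE_NAMES <- c("gap90", "gap91", "window_day21", "window_day22",
                   "combo_retreatment", "partial_resume",
                   "met_day30", "met_day31", "sclc", "washout_boundary")

fx_med <- function(pid, dates, dx1 = "C3490", proc1 = "", setting = "outpatient",
                   paid = 100, end_dates = dates, proc2 = "") {
  med_rows(pid, as.Date(dates), as.Date(end_dates), setting, dx1,
           proc1 = proc1, proc2 = proc2, provider = "oncologist", paid = paid)
}

fx_fills <- function(pid, dates, drug = "osimertinib", paid = 15000) {
  pha_rows(pid, as.Date(dates), drug, 30L, paid)
}

fx_infusions <- function(pid, dates, drug) {
  fx_med(pid, dates, proc1 = drug, proc2 = "96413", paid = 4000)
}

fx_base <- function(pid, span_start = "2017-01-01", dx = "2019-01-10",
                    met_date = "2019-01-15") {
  dx <- as.Date(dx)
  med <- list(fx_med(pid, c(dx, dx + 10L)))
  if (!is.null(met_date)) med <- c(med, list(fx_med(pid, as.Date(met_date), dx1 = "C780")))
  list(patients = data.table::data.table(patient_id = pid, birth_year = 1960L, sex = "F"),
       enrollment = data.table::data.table(patient_id = pid,
                                           start_date = as.Date(span_start),
                                           end_date = as.Date("2022-12-31"),
                                           plan_type = "commercial"),
       medical = med, pharmacy = list())
}

fx_assemble <- function(parts, truth_patients, truth_lines = NULL) {
  ds <- claims_dataset(
    data.table::rbindlist(lapply(parts, `[[`, "patients")),
    data.table::rbindlist(lapply(parts, `[[`, "enrollment")),
    data.table::rbindlist(unlist(lapply(parts, `[[`, "medical"), recursive = FALSE)),
    {
      ph <- unlist(lapply(parts, `[[`, "pharmacy"), recursive = FALSE)
      if (length(ph)) data.table::rbindlist(ph) else
        pha_rows("x", as.Date("2000-01-01"), "x", 1L, 0)[0L]
    })
  list(dataset = ds,
       truth = list(patients = truth_patients, lines = truth_lines),
       data_end = as.Date("2022-12-31"))
}

fx_lines <- function(pid, starts, ends, regimens, reasons) {
  data.table::data.table(patient_id = pid, line_number = seq_along(starts),
                         start_date = as.Date(starts), end_date = as.Date(ends),
                         regimen = regimens, end_reason = reasons)
}

fx_truth_pat <- function(pid, eligible, fail_step = NA_character_) {
  data.table::data.table(patient_id = pid, eligible = eligible, fail_step = fail_step)
}

#' Hand-constructed rule-pinning fixtures
#'
#' Returns small single-patient datasets (with expected truth) that pin the
#' boundary behavior of the selection and line-derivation rules: the 90- vs
#' 91-day re-treatment gap, the inclusive 21-day regimen window (day 21
#' joins, day 22 starts a new line), exact-set re-treatment vs partial
#' resumption of a combination, the 30- vs 31-day metastatic window combined
#' with the pre-index surgery exclusion, the small-cell exclusion, and the
#' 12-month washout boundary.
#'
#' @param name one of `"gap90"`, `"gap91"`, `"window_day21"`,
#'   `"window_day22"`, `"combo_retreatment"`, `"partial_resume"`,
#'   `"met_day30"`, `"met_day31"`, `"sclc"`, `"washout_boundary"`.
#' @return A list with `dataset` (a [claims_dataset()]), `truth`
#'   (`patients` eligibility and, where relevant, expected `lines`) and
#'   `data_end`.
#' @export
make_fixture <- function(name) {
  if (!name %in% FIXTURE_NAMES) {
    stop("unknown fixture '", name, "'; available: ",
         paste(FIXTURE_NAMES, collapse = ", "), call. = FALSE)
  }
  obs_end <- "2022-12-31"
  switch(name,
    gap90 = {
      p <- fx_base("F01")
      # last supply day 2019-04-01; resumption exactly 90 days later
      p$pharmacy <- list(fx_fills("F01", c("2019-02-01", "2019-03-03", "2019-06-30", "2019-07-30")))
      fx_assemble(list(p), fx_truth_pat("F01", TRUE),
                  fx_lines("F01", "2019-02-01", obs_end, "osimertinib", "end_of_observation"))
    },
    gap91 = {
      p <- fx_base("F01")
      p$pharmacy <- list(fx_fills("F01", c("2019-02-01", "2019-03-03", "2019-07-01", "2019-07-31")))
      fx_assemble(list(p), fx_truth_pat("F01", TRUE),
                  fx_lines("F01", c("2019-02-01", "2019-07-01"), c("2019-06-30", obs_end),
                           c("osimertinib", "osimertinib"),
                           c("retreatment_gap", "end_of_observation")))
    },
    window_day21 = {
      p <- fx_base("F01")
      p$pharmacy <- list(fx_fills("F01", c("2019-02-01", "2019-03-03")))
      p$medical <- c(p$medical, list(fx_infusions("F01", c("2019-02-22", "2019-03-15"), "carboplatin")))
      fx_assemble(list(p), fx_truth_pat("F01", TRUE),
                  fx_lines("F01", "2019-02-01", obs_end, "carboplatin;osimertinib",
                           "end_of_observation"))
    },
    window_day22 = {
      p <- fx_base("F01")
      p$pharmacy <- list(fx_fills("F01", c("2019-02-01", "2019-03-01")))
      p$medical <- c(p$medical, list(fx_infusions("F01", c("2019-02-23", "2019-03-16"), "carboplatin")))
      fx_assemble(list(p), fx_truth_pat("F01", TRUE),
                  fx_lines("F01", c("2019-02-01", "2019-02-23"), c("2019-02-22", obs_end),
                           c("osimertinib", "carboplatin;osimertinib"),
                           c("new_agent", "end_of_observation")))
    },
    combo_retreatment = {
      p <- fx_base("F01")
      cyc <- c("2019-02-01", "2019-02-22", "2019-03-15")
      p$medical <- c(p$medical, list(fx_infusions("F01", cyc, "carboplatin"),
                                     fx_infusions("F01", cyc, "pemetrexed"),
                                     fx_infusions("F01", "2019-06-15", "carboplatin"),
                                     fx_infusions("F01", "2019-06-15", "pemetrexed")))
      # not TKI-indexed; selection truth is not the point of this fixture
      fx_assemble(list(p), fx_truth_pat("F01", FALSE, "egfr_tki_index"),
                  fx_lines("F01", c("2019-02-01", "2019-06-15"), c("2019-06-14", obs_end),
                           rep("carboplatin;pemetrexed", 2),
                           c("retreatment_gap", "end_of_observation")))
    },
    partial_resume = {
      p <- fx_base("F01")
      cyc <- c("2019-02-01", "2019-02-22", "2019-03-15")
      p$medical <- c(p$medical, list(fx_infusions("F01", cyc, "carboplatin"),
                                     fx_infusions("F01", cyc, "pemetrexed"),
                                     fx_infusions("F01", c("2019-06-15", "2019-07-06"), "carboplatin")))
      fx_assemble(list(p), fx_truth_pat("F01", FALSE, "egfr_tki_index"),
                  fx_lines("F01", "2019-02-01", obs_end, "carboplatin;pemetrexed",
                           "end_of_observation"))
    },
    met_day30 = {
      p <- fx_base("F01", met_date = "2019-02-09")  # day 30 after 2019-01-10: still qualifies
      p$medical <- c(p$medical, list(fx_med("F01", "2019-01-25", proc1 = "32480")))
      p$pharmacy <- list(fx_fills("F01", c("2019-02-11", "2019-03-13")))
      fx_assemble(list(p), fx_truth_pat("F01", TRUE),
                  fx_lines("F01", "2019-02-11", obs_end, "osimertinib", "end_of_observation"))
    },
    met_day31 = {
      p <- fx_base("F01", met_date = "2019-02-10")  # day 31: metastatic qualifier missed
      p$medical <- c(p$medical, list(fx_med("F01", "2019-01-25", proc1 = "32480")))
      p$pharmacy <- list(fx_fills("F01", c("2019-02-11", "2019-03-13")))
      fx_assemble(list(p), fx_truth_pat("F01", FALSE, "surgery_before_index"),
                  fx_lines("F01", "2019-02-11", obs_end, "osimertinib", "end_of_observation"))
    },
    sclc = {
      p <- fx_base("F01")
      p$medical <- c(p$medical, list(fx_infusions("F01", c("2019-02-01", "2019-02-22"), "carboplatin"),
                                     fx_infusions("F01", c("2019-02-01", "2019-02-22"), "etoposide")))
      fx_assemble(list(p), fx_truth_pat("F01", FALSE, "sclc_exclusion"),
                  fx_lines("F01", "2019-02-01", obs_end, "carboplatin;etoposide",
                           "end_of_observation"))
    },
    washout_boundary = {
      a <- fx_base("W365", span_start = "2018-01-10")  # exactly 365 days before dx: passes
      a$pharmacy <- list(fx_fills("W365", c("2019-02-01", "2019-03-03")))
      b <- fx_base("W364", span_start = "2018-01-11")  # 364 days: fails the washout
      b$pharmacy <- list(fx_fills("W364", c("2019-02-01", "2019-03-03")))
      fx_assemble(list(a, b),
                  rbind(fx_truth_pat("W365", TRUE), fx_truth_pat("W364", FALSE, "washout")),
                  rbind(fx_lines("W365", "2019-02-01", obs_end, "osimertinib", "end_of_observation"),
                        fx_lines("W364", "2019-02-01", obs_end, "osimertinib", "end_of_observation")))
    })
}
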