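#' Extract antineoplastic treatment episodes from claims
#'
#' Builds the exposure records the line-of-therapy engine consumes. Oral
#' agents come from pharmacy claims (`drug_code` keyed into the drug
#' dictionary; exposure runs from the fill date through
#' `fill_date + days_supply - 1`). Infused/injected agents come from medical
#' claims whose procedure-code slots carry a dictionary drug key (exposure is
#' the service date). Supportive-care agents and corticosteroids are never
#' episodes: only dictionary agents classed as antineoplastic count.
#'
#' @param dataset a [claims_dataset()].
#' @param codes a [code_config()].
#' @return `data.table` with `patient_id, agent, start_date, supply_end_date,
#'   source`.
#' @export
treatment_episodes <- function(dataset, codes) {
  anti <- antineoplastic_agents(codes)
  pha <- dataset$pharmacy
  eps_p <- if (nrow(pha)) {
    keep <- pha$drug_code %in% anti
    data.table::data.table(
      patient_id = pha$patient_id[keep],
      agent = pha$drug_code[keep],
      start_date = pha$fill_date[keep],
      supply_end_date = pha$fill_date[keep] + pha$days_supply[keep] - 1L,
      source = "pharmacy")
  } else NULL
  proc <- medical_proc_long(dataset$medical)
  eps_m <- if (nrow(proc)) {
    keep <- proc$code %in% anti
    data.table::data.table(
      patient_id = proc$patient_id[keep],
      agent = proc$code[keep],
      start_date = proc$service_date[keep],
      supply_end_date = proc$service_date[keep],
      source = "medical")
  } else NULL
  out <- data.table::rbindlist(c(list(eps_p), list(eps_m)), use.names = TRUE)
  if (is.null(out) || nrow(out) == 0L) {
    return(data.table::data.table(patient_id = character(), agent = character(),
                                  start_date = as.Date(character()),
                                  supply_end_date = as.Date(character()),
                                  source = character()))
  }
  data.table::setorderv(out, c("patient_id", "start_date", "agent", "supply_end_date"))
  out[]
}

#' Derive lines of therapy for one patient
#'
#' Implements the claims-based line-of-therapy rules. The first qualifying
#' antineoplastic claim on or after the first lung-cancer diagnosis starts
#' the first line; the regimen is the set of agents first observed within the
#' 21-day window following (and including) the line start. A line ends the
#' day before the initiation of an antineoplastic agent that is not part of
#' its regimen (`new_agent`), the day before the resumption of the same
#' regimen (exact agent-set equality, assessed over the 21-day window at the
#' resumption) after a gap of more than 90 days (`retreatment_gap`), or at
#' the end of the observation period (`end_of_observation`). Later lines are
#' built by the same rules with their own 21-day windows.
#'
#' The gap is measured from the latest exposure end of the regimen agents
#' (pharmacy supply end; medical service date) to the next claim of a regimen
#' agent when `codes$gap_reference == "supply_end"` (the default), or
#' claim-date to claim-date when it is `"claim_date"`. A regimen-agent claim
#' after a long gap that does not resume the full regimen continues the
#' current line: it is neither a new agent nor a resumption of the same
#' regimen.
#'
#' @param episodes treatment episodes of a single patient (see
#'   [treatment_episodes()]).
#' @param first_lc_dx_date date of the first lung-cancer diagnosis; episodes
#'   before it are ignored.
#' @param observation_end last observed date; episodes after it are dropped
#'   with a warning and the final line ends here.
#' @param codes a [code_config()].
#' @return `data.table` with `patient_id, line_number, start_date, end_date,
#'   regimen` (`;`-joined, sorted), `regimen_class, end_reason` plus the
#'   subgroup flags `osimertinib_monotherapy` and `pbc_without_io`.
#' @export
derive_lines <- function(episodes, first_lc_dx_date, observation_end, codes) {
  eps <- data.table::as.data.table(episodes)
  empty <- empty_lines_table()
  if (nrow(eps) == 0L) return(empty)
  if (length(unique(eps$patient_id)) > 1L)
    stop("derive_lines() expects episodes of a single patient", call. = FALSE)
  late <- eps$start_date > observation_end
  if (any(late)) {
    warning(sprintf("ignoring %d episode(s) after the observation end", sum(late)),
            call. = FALSE)
    eps <- eps[!late]
  }
  eps <- eps[eps$start_date >= first_lc_dx_date]
  if (nrow(eps) == 0L) return(empty)
  data.table::setorderv(eps, c("start_date", "agent", "supply_end_date"))

  window <- as.integer(codes$combo_window_days)
  gap_max <- as.integer(codes$retreatment_gap_days)
  use_supply <- identical(codes$gap_reference, "supply_end")
  start <- as.integer(eps$start_date)
  supply_end <- as.integer(eps$supply_end_date)
  agent <- eps$agent
  n <- nrow(eps)

  lines <- list()
  i <- 1L
  line_start <- start[1L]
  repeat {
    win_end <- line_start + window
    in_win <- start >= line_start & start <= win_end
    regimen <- unique(agent[in_win])
    exposure_end <- max(if (use_supply) supply_end[in_win] else start[in_win])
    brk <- NA_integer_; reason <- NA_character_
    j <- which(start > win_end & start >= line_start)
    for (k in j) {
      if (!agent[k] %in% regimen) {
        brk <- start[k]; reason <- "new_agent"; break
      }
      gap <- start[k] - exposure_end
      if (gap > gap_max) {
        resumed <- unique(agent[start >= start[k] & start <= start[k] + window])
        if (setequal(resumed, regimen)) {
          brk <- start[k]; reason <- "retreatment_gap"; break
        }
      }
      exposure_end <- max(exposure_end, if (use_supply) supply_end[k] else start[k])
    }
    line_end <- if (is.na(brk)) as.integer(observation_end) else brk - 1L
    lines[[length(lines) + 1L]] <- list(start = line_start, end = line_end,
                                        regimen = sort(regimen),
                                        reason = if (is.na(brk)) "end_of_observation" else reason)
    if (is.na(brk)) break
    # drop episodes consumed by this line; the next line starts at the break
    keep <- start >= brk
    start <- start[keep]; supply_end <- supply_end[keep]; agent <- agent[keep]
    line_start <- brk
    if (length(start) == 0L) break
  }

  cls <- lapply(lines, function(l) classify_regimen(l$regimen, codes))
  data.table::data.table(
    patient_id = eps$patient_id[1L],
    line_number = seq_along(lines),
    start_date = as.Date(vapply(lines, `[[`, integer(1), "start"), origin = "1970-01-01"),
    end_date = as.Date(vapply(lines, `[[`, integer(1), "end"), origin = "1970-01-01"),
    regimen = vapply(lines, function(l) paste(l$regimen, collapse = ";"), character(1)),
    regimen_class = vapply(cls, `[[`, character(1), "regimen_class"),
    end_reason = vapply(lines, `[[`, character(1), "reason"),
    osimertinib_monotherapy = vapply(cls, `[[`, logical(1), "osimertinib_monotherapy"),
    pbc_without_io = vapply(cls, `[[`, logical(1), "pbc_without_io"))
}

#' Derive lines of therapy for a selected cohort
#'
#' Applies [derive_lines()] to every patient of a cohort, using each
#' patient's first lung-cancer diagnosis date and observation end from the
#' cohort record.
#'
#' @param dataset a [claims_dataset()].
#' @param cohort cohort records from [select_cohort()].
#' @param codes a [code_config()].
#' @return One `data.table` of lines for all cohort patients.
#' @export
derive_lines_cohort <- function(dataset, cohort, codes) {
  eps <- treatment_episodes(dataset, codes)
  eps_split <- split(eps, eps$patient_id)
  out <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    pid <- cohort$patient_id[i]
    pe <- eps_split[[pid]]
    if (is.null(pe)) next
    out[[i]] <- derive_lines(pe, cohort$first_lc_dx_date[i],
                             cohort$observation_end[i], codes)
  }
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0L) empty_lines_table() else res
}

empty_lines_table <- function() {
  data.table::data.table(
    patient_id = character(), line_number = integer(),
    start_date = as.Date(character()), end_date = as.Date(character()),
    regimen = character(), regimen_class = character(), end_reason = character(),
    osimertinib_monotherapy = logical(), pbc_without_io = logical())
}

#' Classify a regimen
#'
#' Assigns the regimen class by precedence: any osimertinib makes the line
#' `osimertinib_based`; otherwise any other EGFR-TKI makes it
#' `other_egfr_tki`; otherwise any platinum agent makes it `pbc_regimen`;
#' otherwise a regimen of immunotherapy agents only is `io_mono`; otherwise
#' any chemotherapy agent gives `other_chemo`; anything else is `other`.
#' Also reports the subgroup flags used throughout the reporting tables:
#' osimertinib monotherapy (regimen exactly `{osimertinib}`) and
#' platinum-based chemotherapy without immunotherapy, plus `pbc_with_io`.
#'
#' @param regimen character vector of agent keys (non-empty).
#' @param codes a [code_config()].
#' @return A list with `regimen_class`, `osimertinib_monotherapy`,
#'   `pbc_with_io`, `pbc_without_io`.
#' @export
classify_regimen <- function(regimen, codes) {
  if (length(regimen) == 0L) stop("regimen must be non-empty", call. = FALSE)
  cls <- drug_class(regimen, codes)
  has_io <- any(cls == "immunotherapy", na.rm = TRUE)
  has_platinum <- any(cls == "platinum", na.rm = TRUE)
  regimen_class <-
    if ("osimertinib" %in% regimen) "osimertinib_based"
    else if (any(regimen %in% codes$egfr_tki_agents)) "other_egfr_tki"
    else if (has_platinum) "pbc_regimen"
    else if (!anyNA(cls) && all(cls == "immunotherapy")) "io_mono"
    else if (any(cls %in% c("nonplatinum_chemo", "other_antineoplastic"), na.rm = TRUE)) "other_chemo"
    else "other"
  list(regimen_class = regimen_class,
       osimertinib_monotherapy = identical(sort(regimen), "osimertinib"),
       pbc_with_io = has_platinum && has_io,
       pbc_without_io = has_platinum && !has_io)
}

#' Treatment-sequencing summary
#'
#' Tabulates, for each line depth, the distribution of regimen classes among
#' patients reaching that depth (proportions use the number of patients still
#' treated at the depth as denominator), the class-to-class transition counts
#' from first to second and second to third line, and the progression
#' proportions (share of patients at each depth reaching the next).
#'
#' @param lines line table from [derive_lines_cohort()].
#' @param max_depth deepest line to tabulate (default 3).
#' @return A list with `class_distribution`, `transitions` (list of
#'   `data.table`s `1L_to_2L`, `2L_to_3L`) and `progression`.
#' @export
sequencing_matrix <- function(lines, max_depth = 3L) {
  ln <- data.table::as.data.table(lines)
  depth_n <- vapply(seq_len(max_depth), function(d)
    length(unique(ln$patient_id[ln$line_number == d])), integer(1))
  dist <- data.table::rbindlist(lapply(seq_len(max_depth), function(d) {
    sub <- ln[ln$line_number == d]
    if (nrow(sub) == 0L) {
      return(data.table::data.table(line_number = integer(), regimen_class = character(),
                                    n = integer(), pct = numeric()))
    }
    tab <- sub[, list(n = .N), by = "regimen_class"]
    tab[, `:=`(line_number = d, pct = round(100 * tab$n / depth_n[d], 1))]
    tab[, c("line_number", "regimen_class", "n", "pct"), with = FALSE]
  }))
  transition <- function(d) {
    a <- ln[ln$line_number == d, c("patient_id", "regimen_class"), with = FALSE]
    b <- ln[ln$line_number == d + 1L, c("patient_id", "regimen_class"), with = FALSE]
    data.table::setnames(a, "regimen_class", "from_class")
    data.table::setnames(b, "regimen_class", "to_class")
    m <- merge(a, b, by = "patient_id")
    if (nrow(m) == 0L) {
      return(data.table::data.table(from_class = character(), to_class = character(),
                                    n = integer()))
    }
    m[, list(n = .N), by = c("from_class", "to_class")][order(from_class, to_class)]
  }
  progression <- data.table::data.table(
    from_depth = seq_len(max_depth - 1L),
    n_at_depth = depth_n[seq_len(max_depth - 1L)],
    n_next = depth_n[seq_len(max_depth - 1L) + 1L])
  progression[, "pct" := ifelse(progression$n_at_depth > 0,
                                round(100 * progression$n_next / progression$n_at_depth, 1), 0)]
  list(class_distribution = dist,
       transitions = list(`1L_to_2L` = transition(1L), `2L_to_3L` = transition(2L)),
       progression = progression[])
}
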