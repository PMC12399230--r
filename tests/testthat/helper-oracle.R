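# Independent brute-force oracle for the line-of-therapy rules: walks the
# calendar day by day and applies the three line-ending rules literally.
# Deliberately structured differently from the event-driven engine.
oracle_derive_lines <- function(eps, first_dx, obs_end, window = 21L, gap_max = 90L) {
  eps <- as.data.frame(eps)
  eps <- eps[eps$start_date >= first_dx & eps$start_date <= obs_end, ]
  eps <- eps[order(eps$start_date, eps$agent, eps$supply_end_date), ]
  empty <- data.frame(line_number = integer(), start_date = as.Date(character()),
                      end_date = as.Date(character()), regimen = character(),
                      end_reason = character(), stringsAsFactors = FALSE)
  if (nrow(eps) == 0L) return(empty)

  regimen_at <- function(day) {
    sort(unique(eps$agent[eps$start_date >= day & eps$start_date <= day + window]))
  }
  exposure_at <- function(day) {
    max(eps$supply_end_date[eps$start_date >= day & eps$start_date <= day + window])
  }

  lines <- list()
  line_start <- min(eps$start_date)
  regimen <- regimen_at(line_start)
  expo <- exposure_at(line_start)
  day <- line_start + window + 1L
  while (day <= obs_end) {
    todays <- eps[eps$start_date == day, ]
    brk_reason <- NULL
    if (nrow(todays)) {
      for (j in seq_len(nrow(todays))) {
        ag <- todays$agent[j]
        if (!(ag %in% regimen)) { brk_reason <- "new_agent"; break }
        if (as.integer(day - expo) > gap_max && setequal(regimen_at(day), regimen)) {
          brk_reason <- "retreatment_gap"; break
        }
        expo <- max(expo, todays$supply_end_date[j])
      }
    }
    if (!is.null(brk_reason)) {
      lines[[length(lines) + 1L]] <- data.frame(
        start_date = line_start, end_date = day - 1L,
        regimen = paste(regimen, collapse = ";"), end_reason = brk_reason,
        stringsAsFactors = FALSE)
      line_start <- day
      regimen <- regimen_at(day)
      expo <- exposure_at(day)
      day <- line_start + window + 1L
    } else {
      day <- day + 1L
    }
  }
  lines[[length(lines) + 1L]] <- data.frame(
    start_date = line_start, end_date = obs_end,
    regimen = paste(regimen, collapse = ";"), end_reason = "end_of_observation",
    stringsAsFactors = FALSE)
  out <- do.call(rbind, lines)
  out$line_number <- seq_len(nrow(out))
  out[, c("line_number", "start_date", "end_date", "regimen", "end_reason")]
}

# random small claim streams for property tests
random_episode_stream <- function(max_agents = 4L, max_claims = 18L, horizon = 200L) {
  n_agents <- sample.int(max_agents, 1L)
  agents <- sample(letters[1:6], n_agents)
  n_claims <- sample(3:max_claims, 1L)
  start <- as.Date("2020-01-01") + sample(0:horizon, n_claims, replace = TRUE)
  data.table::data.table(
    patient_id = "X",
    agent = sample(agents, n_claims, replace = TRUE),
    start_date = start,
    supply_end_date = start + sample(0:29, n_claims, replace = TRUE),
    source = "pharmacy")
}

expect_lines_equal_oracle <- function(eps, first_dx, obs_end, codes) {
  got <- derive_lines(eps, first_dx, obs_end, codes)
  exp <- oracle_derive_lines(eps, first_dx, obs_end,
                             window = codes$combo_window_days,
                             gap_max = codes$retreatment_gap_days)
  expect_equal(nrow(got), nrow(exp))
  if (nrow(got)) {
    expect_equal(as.integer(got$start_date), as.integer(exp$start_date))
    expect_equal(as.integer(got$end_date), as.integer(exp$end_date))
    expect_equal(got$regimen, exp$regimen)
    expect_equal(got$end_reason, exp$end_reason)
  }
}

# independent enumeration oracle for the Quan-Charlson score
oracle_quan_cci <- function(codes_vec, map) {
  norm <- function(x) toupper(gsub(".", "", x, fixed = TRUE))
  codes_vec <- norm(codes_vec)
  present <- character(0)
  for (i in seq_len(nrow(map))) {
    prefixes <- norm(c(map$icd9[[i]], map$icd10[[i]]))
    hit <- FALSE
    for (cd in codes_vec) for (p in prefixes) {
      if (substr(cd, 1, nchar(p)) == p) { hit <- TRUE; break }
    }
    if (hit) present <- c(present, map$condition[i])
  }
  w <- function(cond) map$weight[map$condition == cond]
  score <- 0L
  # hierarchy: metastatic supersedes malignancy; severe supersedes mild
  # liver; complicated supersedes uncomplicated diabetes
  if ("metastatic_solid_tumor" %in% present) present <- setdiff(present, "malignancy")
  if ("severe_liver" %in% present) present <- setdiff(present, "mild_liver")
  if ("diabetes_complicated" %in% present) present <- setdiff(present, "diabetes_uncomplicated")
  for (cond in present) score <- score + w(cond)
  score
}

# one shared mid-size simulated dataset reused across test files
.shared <- new.env()
shared_sim <- function() {
  if (is.null(.shared$sim)) {
    .shared$sim <- generate_claims(sim_config(n_patients = 250, seed = 424242L))
    .shared$codes <- code_config()
    .shared$cpi <- cpi_table()
    .shared$sel <- select_cohort(.shared$sim$dataset, .shared$codes,
                                 .shared$sim$config$data_end)
    .shared$lines <- derive_lines_cohort(.shared$sim$dataset, .shared$sel$cohort,
                                         .shared$codes)
    .shared$summaries <- summarize_lines(.shared$lines, .shared$sim$dataset,
                                         .shared$codes, .shared$cpi)
  }
  .shared
}
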