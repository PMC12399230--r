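codes <- code_config()

eps_row <- function(agent, start, supply_days = 30L, pid = "X") {
  start <- as.Date(start)
  data.table::data.table(patient_id = pid, agent = agent, start_date = start,
                         supply_end_date = start + supply_days - 1L,
                         source = "pharmacy")
}

test_that("a single agent filled to observation end forms one line", {
  eps <- data.table::rbindlist(lapply(seq(0, 300, by = 30), function(d)
    eps_row("osimertinib", as.Date("2020-01-01") + d)))
  ln <- derive_lines(eps, as.Date("2019-12-01"), as.Date("2020-12-31"), codes)
  expect_equal(nrow(ln), 1L)
  expect_equal(ln$regimen, "osimertinib")
  expect_equal(ln$end_reason, "end_of_observation")
  expect_equal(ln$start_date, as.Date("2020-01-01"))
  expect_equal(ln$end_date, as.Date("2020-12-31"))
})

test_that("an agent beyond the 21-day window starts the next line", {
  d0 <- as.Date("2020-01-01")
  eps <- rbind(eps_row("a", d0), eps_row("b", d0 + 15), eps_row("c", d0 + 40))
  ln <- derive_lines(eps, d0 - 10, d0 + 200, codes)
  expect_equal(nrow(ln), 2L)
  expect_equal(ln$regimen[1], "a;b")
  expect_equal(ln$end_date[1], d0 + 39)
  expect_equal(ln$start_date[2], d0 + 40)
  expect_true(grepl("c", ln$regimen[2]))
  expect_equal(ln$end_reason[1], "new_agent")
})

test_that("hand fixtures reproduce their expected lines exactly", {
  for (nm in c("gap90", "gap91", "window_day21", "window_day22",
               "combo_retreatment", "partial_resume", "sclc")) {
    fx <- make_fixture(nm)
    eps <- treatment_episodes(fx$dataset, codes)
    ln <- derive_lines(eps, as.Date("2019-01-10"), fx$data_end, codes)
    exp <- fx$truth$lines
    expect_equal(nrow(ln), nrow(exp), info = nm)
    expect_equal(ln$start_date, exp$start_date, info = nm)
    expect_equal(ln$end_date, exp$end_date, info = nm)
    expect_equal(ln$regimen, exp$regimen, info = nm)
    expect_equal(ln$end_reason, exp$end_reason, info = nm)
  }
})

test_that("line derivation matches the day-by-day oracle on random streams", {
  set.seed(303)
  for (rep in 1:300) {
    eps <- random_episode_stream()
    expect_lines_equal_oracle(eps, as.Date("2019-12-01"), as.Date("2020-10-27"), codes)
  }
})

test_that("lines are disjoint, ordered, and cover every claim date", {
  set.seed(71)
  for (rep in 1:50) {
    eps <- random_episode_stream()
    obs_end <- as.Date("2020-10-27")
    ln <- derive_lines(eps, as.Date("2019-12-01"), obs_end, codes)
    expect_equal(ln$line_number, seq_len(nrow(ln)))
    if (nrow(ln) > 1L) {
      expect_true(all(ln$start_date[-1L] == ln$end_date[-nrow(ln)] + 1L))
    }
    expect_true(all(ln$start_date <= ln$end_date))
    expect_equal(ln$end_date[nrow(ln)], obs_end)
    for (d in eps$start_date) {
      expect_true(any(d >= ln$start_date & d <= ln$end_date))
    }
  }
})

test_that("derive_lines is invariant to episode row order and warns on late episodes", {
  set.seed(13)
  eps <- random_episode_stream()
  a <- derive_lines(eps, as.Date("2019-12-01"), as.Date("2020-10-27"), codes)
  b <- derive_lines(eps[sample(nrow(eps))], as.Date("2019-12-01"), as.Date("2020-10-27"), codes)
  expect_equal(a, b)
  late <- rbind(eps, eps_row("a", "2021-06-01"))
  expect_warning(derive_lines(late, as.Date("2019-12-01"), as.Date("2020-10-27"), codes),
                 "observation end")
})

test_that("the gap reference convention is configurable", {
  # fills 95 days apart with 30-day supplies: claim-to-claim gap 95 (>90),
  # supply-end-to-claim gap 66 (<=90)
  d0 <- as.Date("2020-01-01")
  eps <- rbind(eps_row("osimertinib", d0), eps_row("osimertinib", d0 + 95))
  ln_supply <- derive_lines(eps, d0, d0 + 300, codes)
  expect_equal(nrow(ln_supply), 1L)
  ln_claim <- derive_lines(eps, d0, d0 + 300, code_config(gap_reference = "claim_date"))
  expect_equal(nrow(ln_claim), 2L)
  expect_equal(ln_claim$end_reason[1], "retreatment_gap")
})

test_that("classify_regimen applies the precedence rules and subgroup flags", {
  r <- classify_regimen("osimertinib", codes)
  expect_equal(r$regimen_class, "osimertinib_based")
  expect_true(r$osimertinib_monotherapy)
  r <- classify_regimen(c("osimertinib", "carboplatin", "pemetrexed"), codes)
  expect_equal(r$regimen_class, "osimertinib_based")
  expect_false(r$osimertinib_monotherapy)
  r <- classify_regimen(c("carboplatin", "pemetrexed", "pembrolizumab"), codes)
  expect_equal(r$regimen_class, "pbc_regimen")
  expect_true(r$pbc_with_io)
  expect_false(r$pbc_without_io)
  r <- classify_regimen(c("carboplatin", "pemetrexed"), codes)
  expect_true(r$pbc_without_io)
  expect_equal(classify_regimen("erlotinib", codes)$regimen_class, "other_egfr_tki")
  expect_equal(classify_regimen("pembrolizumab", codes)$regimen_class, "io_mono")
  expect_equal(classify_regimen("docetaxel", codes)$regimen_class, "other_chemo")
  expect_error(classify_regimen(character(0), codes), "non-empty")
})

test_that("classify_regimen agrees with an independent rule table on random regimens", {
  dd <- codes$drug_dictionary
  anti <- dd$drug[dd$class %in% c("egfr_tki", "platinum", "nonplatinum_chemo",
                                  "immunotherapy", "other_antineoplastic")]
  oracle <- function(reg) {
    cls <- dd$class[match(reg, dd$drug)]
    if ("osimertinib" %in% reg) "osimertinib_based"
    else if (any(cls == "egfr_tki")) "other_egfr_tki"
    else if (any(cls == "platinum")) "pbc_regimen"
    else if (all(cls == "immunotherapy")) "io_mono"
    else if (any(cls %in% c("nonplatinum_chemo", "other_antineoplastic"))) "other_chemo"
    else "other"
  }
  set.seed(55)
  for (rep in 1:200) {
    reg <- sample(anti, sample(1:4, 1))
    expect_equal(classify_regimen(reg, codes)$regimen_class, oracle(reg))
  }
})

test_that("sequencing_matrix counts transitions and uses per-depth denominators", {
  ln <- data.table::data.table(
    patient_id = c("a", "a", "b", "c", "c", "c", "d"),
    line_number = c(1L, 2L, 1L, 1L, 2L, 3L, 1L),
    regimen_class = c("osimertinib_based", "pbc_regimen", "osimertinib_based",
                      "pbc_regimen", "osimertinib_based", "io_mono",
                      "other_egfr_tki"))
  sq <- sequencing_matrix(ln)
  expect_equal(sq$progression$n_at_depth, c(4L, 2L))
  expect_equal(sq$progression$n_next, c(2L, 1L))
  expect_equal(sq$progression$pct, c(50, 50))
  d1 <- sq$class_distribution[sq$class_distribution$line_number == 1L]
  expect_equal(sum(d1$n), 4L)
  expect_equal(d1$n[d1$regimen_class == "osimertinib_based"], 2L)
  expect_equal(d1$pct[d1$regimen_class == "osimertinib_based"], 50)
  tr <- sq$transitions$`1L_to_2L`
  expect_equal(sum(tr$n), 2L)
  expect_equal(tr$n[tr$from_class == "osimertinib_based" & tr$to_class == "pbc_regimen"], 1L)

  nobody <- ln[ln$line_number == 1L]
  sq0 <- sequencing_matrix(nobody)
  expect_equal(sq0$progression$n_next, c(0L, 0L))
  expect_equal(sq0$progression$pct, c(0, 0))
})
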