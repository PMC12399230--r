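codes <- code_config()
cpi <- cpi_table()

test_that("pppm scales by the 30.4375-day month", {
  s <- as.Date("2020-01-01")
  # 487 days is exactly 16 months of 30.4375 days
  expect_equal(pppm(32000, s, s + 486), 2000)
  expect_equal(pppm(0, s, s + 100), 0)
  expect_equal(pppm(16, s, s + 486), 1)
  expect_error(pppm(1, s, s - 1), "after")
})

test_that("cpi_adjust applies the service-year deflator", {
  expect_equal(cpi_adjust(100, 2022, cpi), 100)
  tab <- data.table::data.table(year = c(2019L, 2022L), deflator_to_2022 = c(1.10, 1))
  expect_equal(cpi_adjust(100, 2019, tab), 110)
  expect_equal(cpi_adjust(110, 2019, tab) / tab$deflator_to_2022[1], 110)
  expect_error(cpi_adjust(100, 1999, cpi), "1999")
})

test_that("quan_cci scores conditions with hierarchy and is monotone", {
  map <- quan_cci_map()
  expect_equal(quan_cci(character(0), map), 0L)
  # metastatic solid tumor supersedes malignancy within the cancer group
  expect_equal(quan_cci(c("C3490", "C780"), map), 6L)
  expect_equal(quan_cci("C3490", map), 2L)
  expect_equal(quan_cci(c("E119", "E112"), map), 2L)   # complicated supersedes
  expect_equal(quan_cci(c("K740", "K721"), map), 3L)   # severe liver supersedes mild
  expect_equal(quan_cci(c("I21", "I509", "J449"), map), 3L)
  # adding codes never decreases the score
  set.seed(9)
  pool <- c("C3490", "C780", "E119", "E112", "K740", "K721", "I21", "I509",
            "J449", "N189", "B20", "G81", "M059", "I10", "Z0000")
  for (rep in 1:25) {
    base <- sample(pool, 3)
    more <- c(base, sample(pool, 2))
    expect_gte(quan_cci(more, map), quan_cci(base, map))
  }
})

test_that("quan_cci equals an independent enumeration oracle on random code bags", {
  map <- quan_cci_map()
  pool <- c("C3490", "C780", "C509", "E119", "E112", "K740", "K721", "I21",
            "I509", "J449", "N189", "B20", "G81", "M059", "I10", "Z0000",
            "410", "42800", "25000", "2504", "5712", "4560", "196", "162")
  set.seed(42)
  for (rep in 1:50) {
    bag <- sample(pool, sample(1:6, 1), replace = TRUE)
    expect_equal(quan_cci(bag, map), oracle_quan_cci(bag, map), info = paste(bag, collapse = ","))
  }
})

test_that("line summaries: distinct-date rule, empty lines, ED-within-admission", {
  pid <- "S01"
  pat <- data.table::data.table(patient_id = pid, birth_year = 1960L, sex = "F")
  enr <- data.table::data.table(patient_id = pid, start_date = as.Date("2019-01-01"),
                                end_date = as.Date("2020-12-31"), plan_type = "commercial")
  mk <- function(date, setting, paid, end = date) {
    data.table::data.table(patient_id = pid, service_date = as.Date(date),
                           end_date = as.Date(end), setting = setting, dx1 = "C3490",
                           dx2 = "", dx3 = "", dx4 = "", proc1 = "", proc2 = "",
                           proc3 = "", proc4 = "", provider_type = "x", paid_amount = paid)
  }
  med <- rbind(mk("2020-02-01", "outpatient", 100), mk("2020-02-01", "outpatient", 50),
               mk("2020-03-10", "inpatient", 5000, end = "2020-03-14"),
               mk("2020-03-12", "emergency", 700),   # inside the admission
               mk("2020-04-02", "emergency", 800),
               mk("2020-04-20", "other", 60))
  pha <- data.table::data.table(patient_id = pid, fill_date = as.Date("2020-02-05"),
                                drug_code = "osimertinib", days_supply = 30L,
                                paid_amount = 15000)
  ds <- claims_dataset(pat, enr, med, pha)
  line <- data.table::data.table(patient_id = pid, line_number = 1L,
                                 start_date = as.Date("2020-02-01"),
                                 end_date = as.Date("2020-04-30"))
  sm <- summarize_line(line, ds, codes, cpi)
  months <- as.numeric(line$end_date - line$start_date + 1) / 30.4375
  expect_equal(sm$outpatient_service_days_pppm * months, 1)   # two same-day rows, one day
  expect_equal(sm$inpatient_admissions_pppm * months, 1)
  expect_equal(sm$inpatient_days_pppm * months, 5)
  expect_equal(sm$ed_visit_days_pppm * months, 1)              # in-admission ED not counted
  d <- cpi$deflator_to_2022[cpi$year == 2020]
  expect_equal(sm$cost_inpatient_pppm * months, (5000 + 700) * d)
  expect_equal(sm$cost_ed_plus_other_pppm * months, (800 + 60) * d)
  expect_equal(sm$cost_pharmacy_pppm * months, 15000 * d)
  expect_equal(sm$cost_total_pppm, sm$cost_medical_pppm + sm$cost_pharmacy_pppm)

  empty_line <- data.table::data.table(patient_id = pid, line_number = 2L,
                                       start_date = as.Date("2020-08-01"),
                                       end_date = as.Date("2020-08-31"))
  sm0 <- summarize_line(empty_line, ds, codes, cpi)
  expect_equal(sm0$cost_total_pppm, 0)
  expect_false(sm0$any_outpatient || sm0$any_inpatient || sm0$any_ed)
})

test_that("cost additivity holds on every generated patient-line", {
  sh <- shared_sim()
  sm <- sh$summaries
  expect_gt(nrow(sm), 100)
  expect_equal(sm$cost_total_pppm, sm$cost_medical_pppm + sm$cost_pharmacy_pppm,
               tolerance = 1e-6)
  expect_equal(sm$cost_medical_pppm,
               sm$cost_inpatient_pppm + sm$cost_outpatient_total_pppm +
                 sm$cost_ed_plus_other_pppm, tolerance = 1e-6)
  expect_equal(sm$cost_outpatient_total_pppm,
               sm$cost_outpatient_anti_pppm + sm$cost_outpatient_other_pppm,
               tolerance = 1e-6)
  expect_true(all(sm[, grep("^cost_", names(sm)), with = FALSE] >= 0))
})

test_that("scaling all paid amounts scales every cost component linearly", {
  sh <- shared_sim()
  ds <- sh$sim$dataset
  scaled <- claims_dataset(ds$patients, ds$enrollment,
                           data.table::copy(ds$medical)[, paid_amount := paid_amount * 3],
                           data.table::copy(ds$pharmacy)[, paid_amount := paid_amount * 3])
  ln <- sh$lines[1:25]
  a <- summarize_lines(ln, ds, codes, cpi)
  b <- summarize_lines(ln, scaled, codes, cpi)
  for (col in grep("^cost_", names(a), value = TRUE)) {
    expect_equal(b[[col]], 3 * a[[col]], tolerance = 1e-9, info = col)
  }
  expect_equal(b$outpatient_service_days_pppm, a$outpatient_service_days_pppm)
})

test_that("supportive-care flags respect line boundaries (inclusive end date)", {
  pid <- "S02"
  pat <- data.table::data.table(patient_id = pid, birth_year = 1960L, sex = "F")
  enr <- data.table::data.table(patient_id = pid, start_date = as.Date("2019-01-01"),
                                end_date = as.Date("2020-12-31"), plan_type = "commercial")
  med <- data.table::data.table(patient_id = pid, service_date = as.Date("2020-01-05"),
                                end_date = as.Date("2020-01-05"), setting = "outpatient",
                                dx1 = "C3490", dx2 = "", dx3 = "", dx4 = "", proc1 = "",
                                proc2 = "", proc3 = "", proc4 = "", provider_type = "x",
                                paid_amount = 10)
  pha <- data.table::data.table(
    patient_id = pid,
    fill_date = as.Date(c("2020-03-31", "2020-05-10")),
    drug_code = c("filgrastim", "oxycodone"), days_supply = c(1L, 14L),
    paid_amount = c(4000, 20))
  ds <- claims_dataset(pat, enr, med, pha)
  line1 <- data.frame(patient_id = pid, start_date = as.Date("2020-01-01"),
                      end_date = as.Date("2020-03-31"))
  line2 <- data.frame(patient_id = pid, start_date = as.Date("2020-04-01"),
                      end_date = as.Date("2020-06-30"))
  f1 <- supportive_care_flags(line1, ds, codes)
  f2 <- supportive_care_flags(line2, ds, codes)
  expect_true(f1$gcsf)    # claim on the line end date counts
  expect_false(f1$pain)
  expect_true(f2$pain)    # pain claim in the second line only
  expect_false(f2$gcsf)
  expect_false(f1$esa || f2$esa || f1$respiratory || f2$respiratory)
})
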