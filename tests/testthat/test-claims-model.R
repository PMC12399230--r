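test_that("write then read reproduces a dataset field by field", {
  sim <- generate_claims(sim_config(n_patients = 30, seed = 77L))
  dir <- withr::local_tempdir()
  write_claims(sim$dataset, dir)
  ds2 <- read_claims(dir)
  expect_equal(as.data.frame(ds2$patients), as.data.frame(sim$dataset$patients))
  expect_equal(as.data.frame(ds2$enrollment), as.data.frame(sim$dataset$enrollment))
  expect_equal(as.data.frame(ds2$medical), as.data.frame(sim$dataset$medical))
  expect_equal(as.data.frame(ds2$pharmacy), as.data.frame(sim$dataset$pharmacy))
  expect_equal(nrow(validation_report(ds2)), 0L)
})

test_that("malformed rows are dropped and reported with row numbers", {
  dir <- withr::local_tempdir()
  sim <- generate_claims(sim_config(n_patients = 3, seed = 5L))
  write_claims(sim$dataset, dir)
  ph <- data.table::fread(file.path(dir, "pharmacy.csv"), colClasses = "character")
  stopifnot(nrow(ph) >= 2L)
  ph$fill_date[2] <- "not-a-date"
  data.table::fwrite(ph, file.path(dir, "pharmacy.csv"))
  ds <- read_claims(dir)
  rep <- validation_report(ds)
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$row, 2L)
  expect_match(rep$problem, "not-a-date")
  expect_equal(nrow(ds$pharmacy), nrow(ph) - 1L)
})

test_that("missing required columns raise a schema error; empty files give empty tables", {
  dir <- withr::local_tempdir()
  sim <- generate_claims(sim_config(n_patients = 2, seed = 6L))
  write_claims(sim$dataset, dir)
  enr <- data.table::fread(file.path(dir, "enrollment.csv"))
  enr$plan_type <- NULL
  data.table::fwrite(enr, file.path(dir, "enrollment.csv"))
  expect_error(read_claims(dir), "plan_type")

  dir2 <- withr::local_tempdir()
  write_claims(sim$dataset, dir2)
  file.create(file.path(dir2, "medical.csv"))  # truncate to an empty file
  writeLines(character(0), file.path(dir2, "medical.csv"))
  ds <- read_claims(dir2)
  expect_equal(nrow(ds$medical), 0L)
})

test_that("unknown extra columns are ignored with a warning", {
  dir <- withr::local_tempdir()
  sim <- generate_claims(sim_config(n_patients = 2, seed = 8L))
  write_claims(sim$dataset, dir)
  ph <- data.table::fread(file.path(dir, "pharmacy.csv"))
  ph$mystery <- 1
  data.table::fwrite(ph, file.path(dir, "pharmacy.csv"))
  expect_warning(ds <- read_claims(dir), "mystery")
  expect_false("mystery" %in% names(ds$pharmacy))
})

test_that("normalize_enrollment merges adjacent spans and preserves gaps", {
  sp <- data.frame(patient_id = "A",
                   start_date = as.Date(c("2019-01-01", "2019-07-01")),
                   end_date = as.Date(c("2019-06-30", "2019-12-31")),
                   plan_type = "commercial")
  out <- normalize_enrollment(sp)
  expect_equal(nrow(out), 1L)
  expect_equal(out$start_date, as.Date("2019-01-01"))
  expect_equal(out$end_date, as.Date("2019-12-31"))

  sp2 <- data.frame(patient_id = "A",
                    start_date = as.Date(c("2019-01-01", "2019-06-01")),
                    end_date = as.Date(c("2019-03-31", "2019-12-31")),
                    plan_type = "commercial")
  out2 <- normalize_enrollment(sp2)
  expect_equal(nrow(out2), 2L)
  expect_equal(out2$start_date, sp2$start_date)
  expect_equal(normalize_enrollment(sp2[0, ])$start_date, as.Date(character(0)))
})

test_that("normalize_enrollment equals a brute-force day-set union", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(1:8, 1)
    s <- as.Date("2019-01-01") + sample(0:300, n, replace = TRUE)
    e <- s + sample(0:120, n, replace = TRUE)
    sp <- data.frame(patient_id = "A", start_date = s, end_date = e, plan_type = "x")
    out <- normalize_enrollment(sp)
    days <- sort(unique(unlist(mapply(function(a, b) a:b, as.integer(s), as.integer(e)))))
    runs <- split(days, cumsum(c(1, diff(days) > 1)))
    expect_equal(as.integer(out$start_date), vapply(runs, min, numeric(1), USE.NAMES = FALSE))
    expect_equal(as.integer(out$end_date), vapply(runs, max, numeric(1), USE.NAMES = FALSE))
    # the output covers exactly the same calendar-day set
    got_days <- unlist(mapply(function(a, b) a:b, as.integer(out$start_date),
                              as.integer(out$end_date)))
    expect_equal(sort(got_days), days)
  }
})

test_that("build_admissions merges overlapping stays and matches a day-set oracle", {
  mk <- function(s, e, paid = 1000) {
    data.table::data.table(patient_id = "A", service_date = as.Date(s),
                           end_date = as.Date(e), setting = "inpatient",
                           dx1 = "C3490", dx2 = "", dx3 = "", dx4 = "",
                           proc1 = "", proc2 = "", proc3 = "", proc4 = "",
                           provider_type = "h", paid_amount = paid,
                           service_year = 2020L)
  }
  two <- rbind(mk("2020-01-10", "2020-01-12"), mk("2020-01-12", "2020-01-15"))
  adm <- build_admissions(two)
  expect_equal(nrow(adm), 1L)
  expect_equal(adm$days, 6L)
  expect_equal(adm$paid_total, 2000)

  sep <- rbind(mk("2020-01-10", "2020-01-12"), mk("2020-01-20", "2020-01-21"))
  expect_equal(nrow(build_admissions(sep)), 2L)

  set.seed(21)
  for (rep in 1:60) {
    n <- sample(1:7, 1)
    s <- as.Date("2020-01-01") + sample(0:60, n, replace = TRUE)
    e <- s + sample(0:10, n, replace = TRUE)
    claims <- do.call(rbind, lapply(seq_len(n), function(i) mk(s[i], e[i])))
    adm <- build_admissions(claims)
    days <- sort(unique(unlist(mapply(function(a, b) a:b, as.integer(s), as.integer(e)))))
    runs <- split(days, cumsum(c(1, diff(days) > 1)))
    expect_equal(nrow(adm), length(runs))
    expect_equal(sum(adm$days), length(days))
  }
})

test_that("downstream results are invariant to claim-row input order", {
  sim <- generate_claims(sim_config(n_patients = 40, seed = 99L))
  codes <- code_config()
  ds <- sim$dataset
  set.seed(1)
  shuffled <- claims_dataset(
    ds$patients[sample(.N)], ds$enrollment[sample(.N)],
    ds$medical[sample(.N)], ds$pharmacy[sample(.N)])
  a <- select_cohort(ds, codes, sim$config$data_end)
  b <- select_cohort(shuffled, codes, sim$config$data_end)
  expect_equal(a$cohort, b$cohort)
  expect_equal(derive_lines_cohort(ds, a$cohort, codes),
               derive_lines_cohort(shuffled, b$cohort, codes))
})
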