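codes <- code_config()

test_that("selection on generated data reproduces the ground-truth labels", {
  sh <- shared_sim()
  truth_elig <- sort(sh$sim$truth$patients$patient_id[sh$sim$truth$patients$eligible])
  expect_equal(sort(sh$sel$cohort$patient_id), truth_elig)
})

test_that("attrition is monotone, ordered, and accounts for every exclusion", {
  sh <- shared_sim()
  at <- sh$sel$attrition
  expect_equal(at$step[1], "two_lc_diagnoses_in_continuous_eligibility")
  expect_equal(at$step[7], "no_surgery_before_index")
  expect_true(all(at$n_after <= at$n_before))
  expect_equal(at$n_before[-1L], at$n_after[-nrow(at)])
  n_excluded <- vapply(at$excluded_patient_ids, function(x)
    if (nzchar(x)) length(strsplit(x, ";", fixed = TRUE)[[1]]) else 0L, integer(1),
    USE.NAMES = FALSE)
  expect_equal(at$n_before - at$n_after, n_excluded)
  expect_equal(at$n_after[nrow(at)], nrow(sh$sel$cohort))
  expect_equal(at$n_before[1], nrow(sh$sim$dataset$patients))
})

test_that("the 30-day metastatic window is inclusive and gates the surgery exclusion", {
  for (nm in c("met_day30", "met_day31")) {
    fx <- make_fixture(nm)
    sel <- select_cohort(fx$dataset, codes, fx$data_end)
    if (nm == "met_day30") {
      expect_equal(sel$cohort$patient_id, "F01")
      expect_equal(sel$cohort$advanced_qualifier, "metastatic_dx_within_30d")
    } else {
      expect_equal(nrow(sel$cohort), 0L)
      excl <- sel$attrition$excluded_patient_ids[
        sel$attrition$step == "no_surgery_before_index"]
      expect_equal(excl, "F01")
    }
  }
})

test_that("small-cell and washout decoys are excluded at their own steps", {
  fx <- make_fixture("sclc")
  sel <- select_cohort(fx$dataset, codes, fx$data_end)
  expect_equal(sel$attrition$excluded_patient_ids[sel$attrition$step == "sclc_exclusion"],
               "F01")
  expect_equal(nrow(sel$cohort), 0L)

  fx <- make_fixture("washout_boundary")
  sel <- select_cohort(fx$dataset, codes, fx$data_end)
  expect_equal(sel$cohort$patient_id, "W365")
  expect_equal(sel$attrition$excluded_patient_ids[sel$attrition$step == "washout_12m"],
               "W364")
})

test_that("cohort records satisfy their date invariants", {
  sh <- shared_sim()
  co <- sh$sel$cohort
  expect_true(all(co$index_date >= codes$osimertinib_approval_date))
  expect_true(all(co$first_lc_dx_date <= co$first_line_start_date))
  expect_true(all(co$baseline_end - co$baseline_start + 1 == 365))
  expect_true(all(co$observation_end >= co$first_line_start_date))
  truth <- sh$sim$truth$patients[match(co$patient_id, sh$sim$truth$patients$patient_id)]
  expect_equal(co$first_lc_dx_date, truth$first_lc_dx_date)
  expect_equal(co$first_line_start_date, truth$first_line_start)
  expect_equal(co$index_date, truth$index_date)
})

test_that("baseline characteristics handle boundary timing and empty histories", {
  # hand-built patient: radiotherapy 29 days before 1L, osimertinib from 1L
  pid <- "B01"
  pat <- data.table::data.table(patient_id = pid, birth_year = 1958L, sex = "M")
  enr <- data.table::data.table(patient_id = pid, start_date = as.Date("2017-01-01"),
                                end_date = as.Date("2022-12-31"), plan_type = "commercial")
  dx <- as.Date("2019-01-10")
  s1 <- as.Date("2019-03-01")
  med <- rbind(
    data.table::data.table(patient_id = pid, service_date = c(dx, dx + 10),
                           end_date = c(dx, dx + 10), setting = "outpatient",
                           dx1 = "C3490", dx2 = "", dx3 = "", dx4 = "", proc1 = "",
                           proc2 = "", proc3 = "", proc4 = "", provider_type = "onc",
                           paid_amount = 100),
    data.table::data.table(patient_id = pid, service_date = dx + 5, end_date = dx + 5,
                           setting = "outpatient", dx1 = "C780", dx2 = "", dx3 = "",
                           dx4 = "", proc1 = "", proc2 = "", proc3 = "", proc4 = "",
                           provider_type = "onc", paid_amount = 100),
    data.table::data.table(patient_id = pid, service_date = s1 - 29, end_date = s1 - 29,
                           setting = "outpatient", dx1 = "C3490", dx2 = "", dx3 = "",
                           dx4 = "", proc1 = "77385", proc2 = "", proc3 = "", proc4 = "",
                           provider_type = "rad", paid_amount = 500))
  pha <- data.table::data.table(patient_id = pid,
                                fill_date = seq(s1, s1 + 90, by = 30),
                                drug_code = "osimertinib", days_supply = 30L,
                                paid_amount = 15000)
  ds <- claims_dataset(pat, enr, med, pha)
  sel <- select_cohort(ds, codes, as.Date("2022-12-31"))
  expect_equal(sel$cohort$patient_id, pid)
  bl <- baseline_characteristics(sel$cohort, ds, codes, cpi_table())
  expect_true(bl$radiotherapy_ever)
  expect_true(bl$radiotherapy_30d)
  expect_false(bl$surgery_ever)
  expect_false(bl$corticosteroid_ever)
  expect_false(bl$brain_met)
  expect_equal(bl$months_dx_to_1l, as.numeric(s1 - dx) / 30.4375)
  # Quan-CCI from the baseline window: metastatic (6) supersedes malignancy (2)
  expect_equal(bl$quan_cci, 6L)
})

test_that("baseline utilization is zero for patients without baseline claims", {
  sh <- shared_sim()
  bl <- baseline_characteristics(sh$sel$cohort[1:20], sh$sim$dataset, sh$codes, sh$cpi)
  expect_true(all(bl$bl_total_cost_pppm >= 0))
  expect_equal(bl$bl_total_cost_pppm,
               bl$bl_medical_cost_pppm + bl$bl_pharmacy_cost_pppm, tolerance = 1e-9)
  # flags line up with the generator's archetype construction
  truth <- sh$sim$truth$patients
  bm <- truth$brain_met[match(bl$patient_id, truth$patient_id)]
  expect_equal(bl$brain_met, bm)
})
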