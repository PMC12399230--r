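#' Construct a claims dataset
#'
#' Bundles the four tables of an administrative-claims extract into a
#' validated `claims_dataset`:
#'
#' * `patients`: `patient_id, birth_year, sex`
#' * `enrollment`: `patient_id, start_date, end_date, plan_type` (closed
#'   calendar-date spans; `plan_type` one of `commercial`,
#'   `medicare_supplemental`, `medicaid`)
#' * `medical`: `patient_id, service_date, end_date, setting, dx1..dx4,
#'   proc1..proc4, provider_type, paid_amount` (`setting` one of `inpatient`,
#'   `outpatient`, `emergency`, `other`; `end_date` equals `service_date` for
#'   point events; `dx1` is the principal diagnosis)
#' * `pharmacy`: `patient_id, fill_date, drug_code, days_supply, paid_amount`
#'   (`drug_code` is a generic-name key into the drug dictionary)
#'
#' A `service_year` column (used for CPI adjustment) is derived from the
#' claim date. Tables are stored in a canonical sort order so that all
#' downstream results are invariant to the row order of the input.
#'
#' @param patients,enrollment,medical,pharmacy data.frames with the columns
#'   above.
#' @return An object of class `claims_dataset`.
#' @export
claims_dataset <- function(patients, enrollment, medical, pharmacy) {
  patients <- data.table::as.data.table(patients)
  enrollment <- data.table::as.data.table(enrollment)
  medical <- data.table::as.data.table(medical)
  pharmacy <- data.table::as.data.table(pharmacy)

  stop_if_missing_cols(patients, c("patient_id", "birth_year", "sex"), "patients")
  stop_if_missing_cols(enrollment, c("patient_id", "start_date", "end_date", "plan_type"),
                       "enrollment")
  stop_if_missing_cols(medical, c("patient_id", "service_date", "end_date", "setting",
                                  paste0("dx", 1:4), paste0("proc", 1:4),
                                  "provider_type", "paid_amount"), "medical")
  stop_if_missing_cols(pharmacy, c("patient_id", "fill_date", "drug_code",
                                   "days_supply", "paid_amount"), "pharmacy")

  for (col in c("start_date", "end_date")) data.table::set(enrollment, j = col, value = as_date(enrollment[[col]]))
  for (col in c("service_date", "end_date")) data.table::set(medical, j = col, value = as_date(medical[[col]]))
  data.table::set(pharmacy, j = "fill_date", value = as_date(pharmacy$fill_date))
  medical[, "service_year" := as.integer(format(medical$service_date, "%Y"))]
  pharmacy[, "service_year" := as.integer(format(pharmacy$fill_date, "%Y"))]

  if (nrow(enrollment) && any(enrollment$start_date > enrollment$end_date))
    stop("enrollment spans must satisfy start_date <= end_date", call. = FALSE)
  if (nrow(medical) && any(medical$service_date > medical$end_date))
    stop("medical claims must satisfy service_date <= end_date", call. = FALSE)
  if (nrow(medical) && any(medical$paid_amount < 0))
    stop("medical paid_amount must be nonnegative", call. = FALSE)
  if (nrow(pharmacy) && any(pharmacy$paid_amount < 0))
    stop("pharmacy paid_amount must be nonnegative", call. = FALSE)
  if (nrow(pharmacy) && any(pharmacy$days_supply < 1))
    stop("pharmacy days_supply must be >= 1", call. = FALSE)
  claim_ids <- unique(c(enrollment$patient_id, medical$patient_id, pharmacy$patient_id))
  orphans <- setdiff(claim_ids, patients$patient_id)
  if (length(orphans))
    stop("claims reference patient_id(s) absent from the patients table: ",
         paste(utils::head(orphans, 5), collapse = ", "), call. = FALSE)

  data.table::setorderv(patients, "patient_id")
  data.table::setorderv(enrollment, c("patient_id", "start_date", "end_date", "plan_type"))
  data.table::setorderv(medical, c("patient_id", "service_date", "end_date", "setting",
                                   "dx1", "proc1", "paid_amount"))
  data.table::setorderv(pharmacy, c("patient_id", "fill_date", "drug_code",
                                    "days_supply", "paid_amount"))
  structure(list(patients = patients, enrollment = enrollment,
                 medical = medical, pharmacy = pharmacy),
            class = "claims_dataset")
}

#' @export
print.claims_dataset <- function(x, ...) {
  cat("<claims_dataset>\n")
  cat(sprintf("  patients:   %d\n", nrow(x$patients)))
  cat(sprintf("  enrollment: %d spans\n", nrow(x$enrollment)))
  cat(sprintf("  medical:    %d claims\n", nrow(x$medical)))
  cat(sprintf("  pharmacy:   %d claims\n", nrow(x$pharmacy)))
  rep <- attr(x, "validation")
  if (!is.null(rep) && nrow(rep)) cat(sprintf("  validation: %d row(s) dropped\n", nrow(rep)))
  invisible(x)
}

empty_table <- function(cols) {
  out <- data.table::as.data.table(stats::setNames(rep(list(character()), length(cols)), cols))
  out
}

read_one_csv <- function(path, required, what) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(empty_table(required))
  dt <- data.table::fread(path, colClasses = "character")
  stop_if_missing_cols(dt, required, paste0(what, " (", basename(path), ")"))
  extra <- setdiff(names(dt), required)
  if (length(extra)) {
    warning(sprintf("%s: ignoring unknown column(s): %s", basename(path),
                    paste(extra, collapse = ", ")), call. = FALSE)
    dt <- dt[, required, with = FALSE]
  }
  dt
}

# parse a date column, collecting unparsable rows into the report
parse_date_col <- function(dt, col, file, report) {
  parsed <- as.Date(dt[[col]], format = "%Y-%m-%d")
  bad <- which(is.na(parsed) & !is.na(dt[[col]]) & nzchar(dt[[col]]))
  if (length(bad)) {
    report$rows <- rbind(report$rows, data.table::data.table(
      file = file, row = bad, field = col,
      problem = paste0("unparsable date: ", dt[[col]][bad])))
  }
  data.table::set(dt, j = col, value = parsed)
  report
}

parse_num_col <- function(dt, col, file, report) {
  parsed <- suppressWarnings(as.numeric(dt[[col]]))
  bad <- which(is.na(parsed) & !is.na(dt[[col]]) & nzchar(dt[[col]]))
  if (length(bad)) {
    report$rows <- rbind(report$rows, data.table::data.table(
      file = file, row = bad, field = col,
      problem = paste0("unparsable number: ", dt[[col]][bad])))
  }
  data.table::set(dt, j = col, value = parsed)
  report
}

#' Read a claims dataset from CSV files
#'
#' Reads the four documented CSV schemas (see [claims_dataset()]) with
#' row-level validation: rows with unparsable dates or numbers are dropped
#' and reported (with their file, row number and offending value) in the
#' validation report attached to the result; a missing required column is an
#' error; an empty file yields an empty table. Unknown extra columns are
#' ignored with a warning.
#'
#' @param dir directory containing `enrollment.csv`, `medical.csv`,
#'   `pharmacy.csv` and (optionally) `patients.csv`. Alternatively give the
#'   four paths explicitly.
#' @param enrollment_path,medical_path,pharmacy_path,patients_path explicit
#'   file paths overriding `dir`. `patients_path` may be `NULL`, in which
#'   case the patients table is built from the ids observed in the claims
#'   with missing demographics.
#' @return A [claims_dataset()] with a `validation` attribute; retrieve it
#'   with [validation_report()].
#' @export
read_claims <- function(dir = NULL,
                        enrollment_path = file.path(dir, "enrollment.csv"),
                        medical_path = file.path(dir, "medical.csv"),
                        pharmacy_path = file.path(dir, "pharmacy.csv"),
                        patients_path = {
                          p <- file.path(dir %||% ".", "patients.csv")
                          if (file.exists(p)) p else NULL
                        }) {
  report <- list(rows = data.table::data.table(
    file = character(), row = integer(), field = character(), problem = character()))

  enr <- read_one_csv(enrollment_path, c("patient_id", "start_date", "end_date", "plan_type"),
                      "enrollment")
  med <- read_one_csv(medical_path, c("patient_id", "service_date", "end_date", "setting",
                                      paste0("dx", 1:4), paste0("proc", 1:4),
                                      "provider_type", "paid_amount"), "medical")
  pha <- read_one_csv(pharmacy_path, c("patient_id", "fill_date", "drug_code",
                                       "days_supply", "paid_amount"), "pharmacy")

  report <- parse_date_col(enr, "start_date", "enrollment.csv", report)
  report <- parse_date_col(enr, "end_date", "enrollment.csv", report)
  report <- parse_date_col(med, "service_date", "medical.csv", report)
  report <- parse_date_col(med, "end_date", "medical.csv", report)
  report <- parse_num_col(med, "paid_amount", "medical.csv", report)
  report <- parse_date_col(pha, "fill_date", "pharmacy.csv", report)
  report <- parse_num_col(pha, "days_supply", "pharmacy.csv", report)
  report <- parse_num_col(pha, "paid_amount", "pharmacy.csv", report)

  # drop reported rows
  drop_rows <- function(dt, file) {
    bad <- unique(report$rows$row[report$rows$file == file])
    if (length(bad)) dt[-bad] else dt
  }
  enr <- drop_rows(enr, "enrollment.csv")
  med <- drop_rows(med, "medical.csv")
  pha <- drop_rows(pha, "pharmacy.csv")
  pha[, "days_supply" := as.integer(pha$days_supply)]

  if (!is.null(patients_path)) {
    pat <- read_one_csv(patients_path, c("patient_id", "birth_year", "sex"), "patients")
    report <- parse_num_col(pat, "birth_year", "patients.csv", report)
    pat <- drop_rows(pat, "patients.csv")
    pat[, "birth_year" := as.integer(pat$birth_year)]
  } else {
    ids <- unique(c(enr$patient_id, med$patient_id, pha$patient_id))
    pat <- data.table::data.table(patient_id = ids, birth_year = NA_integer_,
                                  sex = NA_character_)
  }

  ds <- claims_dataset(pat, enr, med, pha)
  attr(ds, "validation") <- report$rows
  ds
}

#' @rdname read_claims
#' @param x a `claims_dataset` returned by [read_claims()].
#' @export
validation_report <- function(x) {
  attr(x, "validation") %||% data.table::data.table(
    file = character(), row = integer(), field = character(), problem = character())
}

#' Write a claims dataset to CSV files
#'
#' Writes `patients.csv`, `enrollment.csv`, `medical.csv` and `pharmacy.csv`
#' in the documented schemas (ISO-8601 dates). Reading them back with
#' [read_claims()] reproduces the dataset field by field.
#'
#' @param dataset a [claims_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_claims <- function(dataset, dir) {
  stopifnot(inherits(dataset, "claims_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  data.table::fwrite(dataset$patients, file.path(dir, "patients.csv"))
  data.table::fwrite(dataset$enrollment, file.path(dir, "enrollment.csv"))
  med <- data.table::copy(dataset$medical)[, "service_year" := NULL]
  pha <- data.table::copy(dataset$pharmacy)[, "service_year" := NULL]
  data.table::fwrite(med, file.path(dir, "medical.csv"))
  data.table::fwrite(pha, file.path(dir, "pharmacy.csv"))
  invisible(dir)
}

#' Normalize enrollment spans
#'
#' Merges overlapping or adjacent (gap of at most one day, plus any
#' configured bridging allowance) enrollment spans per patient into sorted,
#' disjoint spans covering exactly the same calendar days. The `plan_type`
#' of a merged span is taken from its earliest constituent.
#'
#' @param spans data.frame with `start_date`, `end_date` and optionally
#'   `patient_id` and `plan_type`.
#' @param bridge_days additional gap length (days) to bridge; the default 0
#'   merges only overlapping or directly adjacent spans.
#' @return A `data.table` of disjoint spans sorted by patient and start date.
#' @export
normalize_enrollment <- function(spans, bridge_days = 0L) {
  spans <- data.table::as.data.table(spans)
  if (nrow(spans) == 0L) {
    return(data.table::data.table(patient_id = character(), start_date = as.Date(character()),
                                  end_date = as.Date(character()), plan_type = character()))
  }
  if (!"patient_id" %in% names(spans)) spans[, "patient_id" := "_one_"]
  if (!"plan_type" %in% names(spans)) spans[, "plan_type" := NA_character_]
  spans <- spans[order(spans$patient_id, spans$start_date, spans$end_date)]
  merged <- spans[, {
    s <- as.integer(.SD$start_date); e <- as.integer(.SD$end_date)
    ce <- cummax(e)
    grp <- cumsum(c(TRUE, s[-1] > utils::head(ce, -1) + 1L + as.integer(bridge_days)))
    data.table::data.table(grp = grp, s = s, e = e, plan_type = .SD$plan_type)[, list(
      start_date = as.Date(min(s), origin = "1970-01-01"),
      end_date = as.Date(max(e), origin = "1970-01-01"),
      plan_type = plan_type[1L]), by = "grp"][, "grp" := NULL]
  }, by = "patient_id"]
  merged[]
}

#' Collapse inpatient claims into admissions
#'
#' Inpatient claims whose day intervals overlap, share a day (discharge date
#' equal to the next admit date) or sit on consecutive days (interim bills
#' split at midnight) are merged into a single admission, so admissions are
#' exactly the contiguous runs of the union of inpatient days; an
#' admission's day count is `discharge - admit + 1`.
#'
#' @param medical_claims medical claims (any settings; only
#'   `setting == "inpatient"` rows are used).
#' @return `data.table` with `patient_id, admit_date, discharge_date, days,
#'   paid_total` sorted by patient and admit date.
#' @export
build_admissions <- function(medical_claims) {
  mc <- data.table::as.data.table(medical_claims)
  out_cols <- c("patient_id", "admit_date", "discharge_date", "days", "paid_total")
  if (nrow(mc) == 0L || !any(mc$setting == "inpatient")) {
    return(data.table::data.table(patient_id = character(),
                                  admit_date = as.Date(character()),
                                  discharge_date = as.Date(character()),
                                  days = integer(), paid_total = numeric()))
  }
  inp <- mc[mc$setting == "inpatient"]
  inp <- inp[order(inp$patient_id, inp$service_date, inp$end_date)]
  adm <- inp[, {
    s <- as.integer(.SD$service_date); e <- as.integer(.SD$end_date)
    ce <- cummax(e)
    grp <- cumsum(c(TRUE, s[-1] > utils::head(ce, -1) + 1L))
    data.table::data.table(grp = grp, s = s, e = e, paid = .SD$paid_amount)[, list(
      admit_date = as.Date(min(s), origin = "1970-01-01"),
      discharge_date = as.Date(max(e), origin = "1970-01-01"),
      days = as.integer(max(e) - min(s) + 1L),
      paid_total = sum(paid)), by = "grp"][, "grp" := NULL]
  }, by = "patient_id"]
  adm[]
}

# long views of the diagnosis / procedure slots ------------------------------

medical_dx_long <- function(medical) {
  med <- data.table::as.data.table(medical)
  if (nrow(med) == 0L) {
    return(data.table::data.table(patient_id = character(),
                                  service_date = as.Date(character()),
                                  code = character(), principal = logical()))
  }
  pieces <- lapply(1:4, function(i) {
    code <- med[[paste0("dx", i)]]
    keep <- !is.na(code) & nzchar(code)
    data.table::data.table(patient_id = med$patient_id[keep],
                           service_date = med$service_date[keep],
                           code = code[keep], principal = i == 1L)
  })
  data.table::rbindlist(pieces)
}

medical_proc_long <- function(medical) {
  med <- data.table::as.data.table(medical)
  if (nrow(med) == 0L) {
    return(data.table::data.table(patient_id = character(),
                                  service_date = as.Date(character()),
                                  code = character()))
  }
  pieces <- lapply(1:4, function(i) {
    code <- med[[paste0("proc", i)]]
    keep <- !is.na(code) & nzchar(code)
    data.table::data.table(patient_id = med$patient_id[keep],
                           service_date = med$service_date[keep],
                           code = code[keep])
  })
  data.table::rbindlist(pieces)
}
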