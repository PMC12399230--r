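#' Code sets and drug dictionary for claims-based NSCLC analyses
#'
#' `code_config()` assembles the diagnosis-code sets, procedure-code sets,
#' drug dictionary and algorithm constants used by cohort selection, the
#' line-of-therapy engine and the outcome summaries. Every element can be
#' overridden, and a whole configuration can be serialized to / restored from
#' YAML with [write_code_config()] / [read_code_config()], so that users with
#' access to proprietary code lists can substitute them without touching code.
#'
#' Diagnosis codes are matched dot-free by prefix: lung cancer is ICD-9-CM
#' 162.2x-162.9x / ICD-10-CM C34.x; metastatic disease is ICD-9-CM 196.x,
#' 197.x, 198.x, 209.7 / ICD-10-CM C77.x, C78.x, C79.x, C7B.x; "any other
#' cancer" is any malignancy code (ICD-9 140-209, ICD-10 C00-C96) outside the
#' lung-cancer set.
#'
#' The drug dictionary keys agents by generic name and assigns each a single
#' class: `egfr_tki`, `platinum`, `nonplatinum_chemo`, `immunotherapy`,
#' `other_antineoplastic`, the supportive-care classes
#' (`supportive_pain`, `supportive_respiratory`, `supportive_gcsf`,
#' `supportive_esa`) or `corticosteroid`. The `guideline` flag marks agents
#' that form guideline-recommended regimens for advanced NSCLC; the
#' small-cell agents (etoposide, irinotecan, topotecan) are classed as
#' antineoplastic but not guideline, so they can form a first-line regimen
#' and trigger the small-cell exclusion.
#'
#' @param ... named overrides of any default element.
#' @return A list of class `oncolot_codes`.
#' @examples
#' codes <- code_config()
#' codes$egfr_tki_agents
#' @export
code_config <- function(...) {
  cfg <- list(
    lc_dx_icd9       = c("1622", "1623", "1624", "1625", "1626", "1627", "1628", "1629"),
    lc_dx_icd10      = "C34",
    metastatic_icd9  = c("196", "197", "198", "2097"),
    metastatic_icd10 = c("C77", "C78", "C79", "C7B"),
    brain_met_icd9   = c("1983", "1984"),
    brain_met_icd10  = "C793",
    sclc_agents      = c("etoposide", "irinotecan", "topotecan"),
    egfr_tki_agents  = c("gefitinib", "erlotinib", "afatinib", "osimertinib", "dacomitinib"),
    drug_dictionary  = default_drug_dictionary(),
    lc_surgery_procedure_codes   = c("32440", "32480", "32484", "32505", "32663", "32666", "32671"),
    radiotherapy_procedure_codes = c("77301", "77385", "77386", "77402", "77407", "77412", "77427"),
    admin_procedure_codes        = c("96360", "96365", "96413", "96415", "96417"),
    osimertinib_approval_date = as.Date("2018-04-18"),
    combo_window_days    = 21L,   # regimen accrual window after line start (inclusive)
    retreatment_gap_days = 90L,   # a gap must strictly exceed this to split a line
    metastatic_window_days = 30L, # metastatic dx within this many days of first LC dx (inclusive)
    washout_days  = 365L,
    baseline_days = 365L,
    month_days    = MONTH_DAYS,
    eligibility_bridge_days = 0L, # enrollment gaps <= this many days are bridged
    gap_reference = "supply_end"  # or "claim_date"
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) {
      stop("unknown code_config element(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    cfg[names(dots)] <- dots
  }
  validate_code_config(cfg)
}

validate_code_config <- function(cfg) {
  for (nm in c("lc_dx_icd9", "lc_dx_icd10", "metastatic_icd9", "metastatic_icd10")) {
    if (length(cfg[[nm]]) == 0L) stop("code set '", nm, "' must be non-empty", call. = FALSE)
  }
  dd <- data.table::as.data.table(cfg$drug_dictionary)
  stop_if_missing_cols(dd, c("drug", "class", "guideline"), "drug_dictionary")
  if (anyDuplicated(dd$drug)) {
    stop("drug dictionary assigns more than one class to: ",
         paste(unique(dd$drug[duplicated(dd$drug)]), collapse = ", "), call. = FALSE)
  }
  if (!cfg$gap_reference %in% c("supply_end", "claim_date")) {
    stop("gap_reference must be 'supply_end' or 'claim_date'", call. = FALSE)
  }
  cfg$drug_dictionary <- dd
  structure(cfg, class = "oncolot_codes")
}

# Shipped default dictionary: the agents named in the selection algorithm plus
# common partner agents for platinum-based and immunotherapy regimens.
default_drug_dictionary <- function() {
  dd <- rbind(
    data.table::data.table(
      drug = c("gefitinib", "erlotinib", "afatinib", "osimertinib", "dacomitinib"),
      class = "egfr_tki", guideline = TRUE),
    data.table::data.table(
      drug = c("carboplatin", "cisplatin"),
      class = "platinum", guideline = TRUE),
    data.table::data.table(
      drug = c("pemetrexed", "paclitaxel", "docetaxel", "gemcitabine", "vinorelbine"),
      class = "nonplatinum_chemo", guideline = TRUE),
    data.table::data.table(
      drug = c("etoposide", "irinotecan", "topotecan"),
      class = "nonplatinum_chemo", guideline = FALSE),
    data.table::data.table(
      drug = c("pembrolizumab", "nivolumab", "atezolizumab", "durvalumab", "ipilimumab"),
      class = "immunotherapy", guideline = TRUE),
    data.table::data.table(
      drug = c("amivantamab", "bevacizumab"),
      class = "other_antineoplastic", guideline = TRUE),
    data.table::data.table(
      drug = c("oxycodone", "morphine", "hydrocodone", "fentanyl", "tramadol"),
      class = "supportive_pain", guideline = FALSE),
    data.table::data.table(
      drug = c("albuterol", "ipratropium", "tiotropium"),
      class = "supportive_respiratory", guideline = FALSE),
    data.table::data.table(
      drug = c("filgrastim", "pegfilgrastim", "sargramostim"),
      class = "supportive_gcsf", guideline = FALSE),
    data.table::data.table(
      drug = c("epoetin_alfa", "darbepoetin_alfa"),
      class = "supportive_esa", guideline = FALSE),
    data.table::data.table(
      drug = c("dexamethasone", "prednisone", "methylprednisolone"),
      class = "corticosteroid", guideline = FALSE)
  )
  dd
}

ANTINEOPLASTIC_CLASSES <- c("egfr_tki", "platinum", "nonplatinum_chemo",
                            "immunotherapy", "other_antineoplastic")

# drug -> class lookup; unknown drugs return NA
drug_class <- function(drugs, codes) {
  dd <- codes$drug_dictionary
  dd$class[match(drugs, dd$drug)]
}

antineoplastic_agents <- function(codes) {
  dd <- codes$drug_dictionary
  dd$drug[dd$class %in% ANTINEOPLASTIC_CLASSES]
}

guideline_agents <- function(codes) {
  dd <- codes$drug_dictionary
  dd$drug[dd$guideline]
}

supportive_agents <- function(codes, category) {
  dd <- codes$drug_dictionary
  dd$drug[dd$class == paste0("supportive_", category)]
}

is_lc_code <- function(x, codes) {
  match_prefix(x, c(codes$lc_dx_icd9, codes$lc_dx_icd10))
}

is_metastatic_code <- function(x, codes) {
  match_prefix(x, c(codes$metastatic_icd9, codes$metastatic_icd10))
}

is_brain_met_code <- function(x, codes) {
  match_prefix(x, c(codes$brain_met_icd9, codes$brain_met_icd10))
}

# any malignancy code (ICD-9 140-209, ICD-10 C00-C96) outside the LC set
is_other_cancer_code <- function(x, codes) {
  x <- normalize_code(x)
  icd10 <- grepl("^C[0-9]", x) & substr(x, 2, 3) <= "96"
  num3 <- suppressWarnings(as.integer(substr(x, 1, 3)))
  icd9 <- grepl("^[0-9]", x) & !is.na(num3) & num3 >= 140L & num3 <= 209L
  (icd10 | icd9) & !is_lc_code(x, codes)
}

#' Serialize / restore a code configuration
#'
#' @param codes an `oncolot_codes` object.
#' @param path file path for the YAML configuration.
#' @return `read_code_config()` returns an `oncolot_codes` object;
#'   `write_code_config()` returns `path` invisibly.
#' @export
write_code_config <- function(codes, path) {
  out <- unclass(codes)
  out$osimertinib_approval_date <- format(out$osimertinib_approval_date)
  out$drug_dictionary <- lapply(seq_len(nrow(codes$drug_dictionary)), function(i)
    as.list(codes$drug_dictionary[i]))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_code_config
#' @export
read_code_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$osimertinib_approval_date <- as.Date(raw$osimertinib_approval_date)
  raw$drug_dictionary <- data.table::rbindlist(raw$drug_dictionary)
  do.call(code_config, raw)
}

#' Consumer-price-index deflators for cost adjustment
#'
#' Loads a `year -> deflator-to-2022` table. The packaged default
#' (`inst/extdata/cpi.csv`) is derived from the annual-average US medical-care
#' CPI series, with `deflator_to_2022 = index(2022) / index(year)`; replace it
#' with your own series if you need different reference values.
#'
#' @param path CSV with columns `year, deflator_to_2022`; defaults to the
#'   packaged table.
#' @return A `data.table` with columns `year` and `deflator_to_2022`.
#' @export
cpi_table <- function(path = system.file("extdata", "cpi.csv", package = "oncolot")) {
  cpi <- data.table::fread(path)
  stop_if_missing_cols(cpi, c("year", "deflator_to_2022"), "CPI table")
  if (any(cpi$deflator_to_2022 <= 0)) stop("CPI deflators must be positive", call. = FALSE)
  i2022 <- cpi$deflator_to_2022[cpi$year == 2022]
  if (length(i2022) == 1L && abs(i2022 - 1) > 1e-9) {
    stop("deflator for the 2022 reference year must be 1.0", call. = FALSE)
  }
  cpi[]
}

#' Quan coding of the Charlson comorbidity index
#'
#' Loads the condition map used by [quan_cci()]: one row per Charlson
#' condition with its ICD-9/ICD-10 code prefixes (Quan's coding algorithms,
#' simplified to dot-free prefixes), the original Charlson weight, and a
#' hierarchy group. Within a hierarchy group only the highest-weight
#' condition present contributes (metastatic solid tumor supersedes
#' malignancy, severe liver disease supersedes mild, complicated diabetes
#' supersedes uncomplicated). The map is a data file so alternative weights
#' (for example Quan's 2011 update) can be substituted.
#'
#' @param path CSV with columns
#'   `condition, icd9_prefixes, icd10_prefixes, weight, hierarchy_group`
#'   (prefix lists are `;`-separated); defaults to the packaged map.
#' @return A `data.table` with list-columns `icd9` and `icd10`.
#' @export
quan_cci_map <- function(path = system.file("extdata", "quan_cci_map.csv", package = "oncolot")) {
  map <- data.table::fread(path)
  stop_if_missing_cols(map, c("condition", "icd9_prefixes", "icd10_prefixes",
                              "weight", "hierarchy_group"), "Quan-CCI map")
  map$icd9 <- strsplit(map$icd9_prefixes, ";", fixed = TRUE)
  map$icd10 <- strsplit(map$icd10_prefixes, ";", fixed = TRUE)
  if (any(map$weight <= 0 | map$weight != round(map$weight))) {
    stop("Charlson weights must be positive integers", call. = FALSE)
  }
  map[]
}
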