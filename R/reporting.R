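#' Mean difference with a Welch confidence interval
#'
#' Point estimate `mean(a) - mean(b)` with an unpaired, unequal-variance
#' (Welch) interval: the standard error is `sqrt(var(a)/n_a + var(b)/n_b)`
#' and the quantile is Student t with Welch-Satterthwaite degrees of freedom
#' (default) or standard normal. When both groups have zero variance the
#' interval degenerates to the point estimate. The cohorts compared in the
#' cost tables overlap across lines of therapy but are treated as
#' independent groups; no multiplicity adjustment is applied (the analysis
#' is descriptive).
#'
#' @param values_a,values_b numeric vectors, each of length at least 2.
#' @param alpha two-sided significance level (default 0.05 for a 95% CI).
#' @param ci_quantile `"t"` (Welch-Satterthwaite) or `"normal"`.
#' @return List with `md`, `ci_low`, `ci_high`, `se`.
#' @export
mean_difference_ci <- function(values_a, values_b, alpha = 0.05,
                               ci_quantile = c("t", "normal")) {
  ci_quantile <- match.arg(ci_quantile)
  na <- length(values_a); nb <- length(values_b)
  if (na < 2L || nb < 2L) stop("each group needs n >= 2", call. = FALSE)
  md <- mean(values_a) - mean(values_b)
  va <- stats::var(values_a) / na
  vb <- stats::var(values_b) / nb
  se <- sqrt(va + vb)
  if (se == 0) return(list(md = md, ci_low = md, ci_high = md, se = 0))
  q <- if (ci_quantile == "t") {
    df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
    stats::qt(1 - alpha / 2, df)
  } else stats::qnorm(1 - alpha / 2)
  list(md = md, ci_low = md - q * se, ci_high = md + q * se, se = se)
}

#' Share of a total attributable to a component
#'
#' `100 * component_mean / total_mean`, reported to one decimal — used for
#' cost shares (for example inpatient costs as a percentage of total PPPM
#' costs) and for simple proportions such as progression percentages.
#'
#' @param component_mean component value (same units as `total_mean`).
#' @param total_mean strictly positive total.
#' @return Percentage rounded to one decimal.
#' @export
cost_share <- function(component_mean, total_mean) {
  if (any(total_mean <= 0)) stop("total must be positive", call. = FALSE)
  round(100 * component_mean / total_mean, 1)
}

#' Convert a per-month rate to a per-year rate
#'
#' @param rate_pppm nonnegative per-patient-per-month rate.
#' @return `rate_pppm * 12`, rounded to one decimal.
#' @export
pppm_to_pppy <- function(rate_pppm) {
  if (any(rate_pppm < 0)) stop("rate must be nonnegative", call. = FALSE)
  round(rate_pppm * 12, 1)
}

group_summary <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  list(n = n, mean = if (n) mean(x) else NA_real_,
       sd = if (n >= 2L) stats::sd(x) else NA_real_,
       median = if (n) stats::median(x) else NA_real_)
}

HRU_MEASURES <- c("duration_months", "outpatient_service_days_pppm",
                  "inpatient_admissions_pppm", "inpatient_days_pppm",
                  "ed_visit_days_pppm")
COST_MEASURES <- c("cost_total_pppm", "cost_medical_pppm",
                   "cost_outpatient_total_pppm", "cost_outpatient_anti_pppm",
                   "cost_outpatient_other_pppm", "cost_inpatient_pppm",
                   "cost_ed_plus_other_pppm", "cost_pharmacy_pppm")
FLAG_MEASURES <- c("any_outpatient", "any_inpatient", "any_ed",
                   "supportive_pain", "supportive_respiratory",
                   "supportive_gcsf", "supportive_esa")

#' Build the report bundle
#'
#' Assembles the analysis tables from the upstream outputs: baseline
#' characteristics (when supplied), utilization by line of therapy and
#' group, cost components by line with mean differences and 95% CIs across
#' successive lines and between the first-line osimertinib-monotherapy and
#' first-line platinum-without-immunotherapy subgroups, the
#' treatment-sequencing summary, cost shares and per-patient-per-year
#' conversions. Every derived cell is recomputable from the `summaries`
#' input.
#'
#' @param cohort cohort table from [select_cohort()].
#' @param lines line table from [derive_lines_cohort()].
#' @param summaries per-line summaries from [summarize_lines()].
#' @param baseline optional baseline table from [baseline_characteristics()].
#' @param alpha significance level for the CIs.
#' @param ci_quantile passed to [mean_difference_ci()].
#' @param max_depth deepest line to report (default 3).
#' @return A list of `data.table`s: `table1`, `table2`, `table3`, `table4`,
#'   `sequencing` (class distribution), `transitions`, `progression`,
#'   `cost_shares`, `pppy`.
#' @export
build_report <- function(cohort, lines, summaries, baseline = NULL,
                         alpha = 0.05, ci_quantile = "t", max_depth = 3L) {
  ln <- data.table::as.data.table(lines)
  sm <- data.table::as.data.table(summaries)
  first <- ln[ln$line_number == 1L]
  groups <- list(
    overall = cohort$patient_id,
    osimertinib_mono_1l = first$patient_id[first$osimertinib_monotherapy],
    pbc_without_io_1l = first$patient_id[first$pbc_without_io])

  # ---- table 1: baseline ---------------------------------------------------
  table1 <- data.table::rbindlist(lapply(names(groups), function(g) {
    ids <- groups[[g]]
    co <- cohort[cohort$patient_id %in% ids]
    rows <- list(data.table::data.table(
      group = g, measure = "n_patients", n = nrow(co),
      mean = NA_real_, sd = NA_real_, median = NA_real_, pct = NA_real_))
    add_cont <- function(measure, x) {
      s <- group_summary(x)
      rows[[length(rows) + 1L]] <<- data.table::data.table(
        group = g, measure = measure, n = s$n, mean = s$mean, sd = s$sd,
        median = s$median, pct = NA_real_)
    }
    add_bin <- function(measure, x) {
      rows[[length(rows) + 1L]] <<- data.table::data.table(
        group = g, measure = measure, n = sum(x, na.rm = TRUE),
        mean = NA_real_, sd = NA_real_, median = NA_real_,
        pct = if (nrow(co)) round(100 * mean(x, na.rm = TRUE), 1) else NA_real_)
    }
    add_cont("age_at_1l", co$age_at_1l)
    add_bin("female", co$sex == "F")
    for (pt in c("commercial", "medicare_supplemental", "medicaid")) {
      add_bin(paste0("plan_", pt), co$plan_type == pt)
    }
    for (yr in 2018:2022) add_bin(paste0("index_year_", yr),
                                  format(co$index_date, "%Y") == yr)
    if (!is.null(baseline)) {
      bl <- data.table::as.data.table(baseline)[baseline$patient_id %in% ids]
      add_cont("quan_cci", bl$quan_cci)
      add_cont("months_dx_to_1l", bl$months_dx_to_1l)
      add_cont("months_dx_to_tki", bl$months_dx_to_tki)
      for (m in c("corticosteroid_ever", "radiotherapy_ever", "surgery_ever",
                  "radiotherapy_30d", "surgery_30d", "brain_met")) add_bin(m, bl[[m]])
      for (m in c("bl_outpatient_days_pppm", "bl_inpatient_admissions_pppm",
                  "bl_ed_days_pppm", "bl_total_cost_pppm", "bl_medical_cost_pppm",
                  "bl_inpatient_cost_pppm", "bl_outpatient_cost_pppm",
                  "bl_ed_other_cost_pppm", "bl_pharmacy_cost_pppm")) add_cont(m, bl[[m]])
    }
    data.table::rbindlist(rows)
  }))

  # ---- tables 2-4: per-line summaries by group -----------------------------
  sub_sm <- function(g, depth) {
    sm[sm$patient_id %in% groups[[g]] & sm$line_number == depth]
  }
  table2 <- data.table::rbindlist(lapply(names(groups), function(g) {
    data.table::rbindlist(lapply(seq_len(max_depth), function(d) {
      s <- sub_sm(g, d)
      cont <- data.table::rbindlist(lapply(HRU_MEASURES, function(m) {
        gs <- group_summary(s[[m]])
        data.table::data.table(group = g, line_number = d, measure = m, n = gs$n,
                               mean = gs$mean, sd = gs$sd, median = gs$median,
                               pct = NA_real_)
      }))
      amongadm <- {
        x <- s$inpatient_days_pppm[s$any_inpatient]
        gs <- group_summary(x)
        data.table::data.table(group = g, line_number = d,
                               measure = "inpatient_days_pppm_among_admitted",
                               n = gs$n, mean = gs$mean, sd = gs$sd,
                               median = gs$median, pct = NA_real_)
      }
      bin <- data.table::rbindlist(lapply(FLAG_MEASURES, function(m)
        data.table::data.table(group = g, line_number = d, measure = m,
                               n = sum(s[[m]]), mean = NA_real_, sd = NA_real_,
                               median = NA_real_,
                               pct = if (nrow(s)) round(100 * mean(s[[m]]), 1) else NA_real_)))
      rbind(cont, amongadm, bin)
    }))
  }))

  cost_summary <- function(g, d) {
    s <- sub_sm(g, d)
    data.table::rbindlist(lapply(c("duration_months", COST_MEASURES), function(m) {
      gs <- group_summary(s[[m]])
      data.table::data.table(group = g, line_number = d, measure = m, n = gs$n,
                             mean = gs$mean, sd = gs$sd, median = gs$median)
    }))
  }
  md_cols <- function(a, b) {
    if (length(a) >= 2L && length(b) >= 2L) {
      r <- mean_difference_ci(a, b, alpha = alpha, ci_quantile = ci_quantile)
      data.table::data.table(md = r$md, ci_low = r$ci_low, ci_high = r$ci_high)
    } else data.table::data.table(md = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
  }

  table3 <- data.table::rbindlist(lapply(c("duration_months", COST_MEASURES), function(m) {
    row <- data.table::data.table(measure = m)
    for (d in seq_len(max_depth)) {
      s <- sub_sm("overall", d)
      gs <- group_summary(s[[m]])
      row[[paste0("n_", d, "l")]] <- gs$n
      row[[paste0("mean_", d, "l")]] <- gs$mean
      row[[paste0("sd_", d, "l")]] <- gs$sd
      row[[paste0("median_", d, "l")]] <- gs$median
    }
    if (m != "duration_months") {
      md21 <- md_cols(sub_sm("overall", 2L)[[m]], sub_sm("overall", 1L)[[m]])
      md32 <- md_cols(sub_sm("overall", 3L)[[m]], sub_sm("overall", 2L)[[m]])
      row <- cbind(row, data.table::data.table(
        md_2l_vs_1l = md21$md, ci_low_2l_vs_1l = md21$ci_low,
        ci_high_2l_vs_1l = md21$ci_high,
        md_3l_vs_2l = md32$md, ci_low_3l_vs_2l = md32$ci_low,
        ci_high_3l_vs_2l = md32$ci_high))
    }
    row
  }), fill = TRUE)

  table4 <- data.table::rbindlist(lapply(seq_len(max_depth), function(d) {
    data.table::rbindlist(lapply(c("duration_months", COST_MEASURES), function(m) {
      a <- sub_sm("osimertinib_mono_1l", d)[[m]]
      b <- sub_sm("pbc_without_io_1l", d)[[m]]
      ga <- group_summary(a); gb <- group_summary(b)
      row <- data.table::data.table(
        line_number = d, measure = m,
        n_osi = ga$n, mean_osi = ga$mean, sd_osi = ga$sd, median_osi = ga$median,
        n_pbc = gb$n, mean_pbc = gb$mean, sd_pbc = gb$sd, median_pbc = gb$median)
      if (m != "duration_months") cbind(row, md_cols(a, b)) else row
    }), fill = TRUE)
  }), fill = TRUE)

  seqm <- sequencing_matrix(ln, max_depth = max_depth)

  cost_shares <- data.table::rbindlist(lapply(names(groups), function(g) {
    data.table::rbindlist(lapply(seq_len(max_depth), function(d) {
      s <- sub_sm(g, d)
      if (nrow(s) == 0L || mean(s$cost_total_pppm) <= 0) return(NULL)
      total <- mean(s$cost_total_pppm)
      comp <- c("cost_inpatient_pppm", "cost_outpatient_total_pppm",
                "cost_outpatient_anti_pppm", "cost_ed_plus_other_pppm",
                "cost_pharmacy_pppm")
      data.table::data.table(group = g, line_number = d, component = comp,
                             mean_pppm = vapply(comp, function(m) mean(s[[m]]), numeric(1)),
                             share_pct = vapply(comp, function(m)
                               cost_share(mean(s[[m]]), total), numeric(1)))
    }))
  }))

  pppy <- data.table::rbindlist(lapply(names(groups), function(g) {
    data.table::rbindlist(lapply(seq_len(max_depth), function(d) {
      s <- sub_sm(g, d)
      if (nrow(s) == 0L) return(NULL)
      data.table::data.table(
        group = g, line_number = d,
        inpatient_admissions_pppy = pppm_to_pppy(mean(s$inpatient_admissions_pppm)),
        inpatient_days_pppy = pppm_to_pppy(mean(s$inpatient_days_pppm)),
        ed_visit_days_pppy = pppm_to_pppy(mean(s$ed_visit_days_pppm)))
    }))
  }))

  list(table1 = table1, table2 = table2, table3 = table3, table4 = table4,
       sequencing = seqm$class_distribution, transitions = seqm$transitions,
       progression = seqm$progression, cost_shares = cost_shares, pppy = pppy)
}

#' Write a report bundle to CSV files
#'
#' @param report list returned by [build_report()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  flat <- report
  flat$transitions_1l_2l <- report$transitions$`1L_to_2L`
  flat$transitions_2l_3l <- report$transitions$`2L_to_3L`
  flat$transitions <- NULL
  for (nm in names(flat)) {
    data.table::fwrite(flat[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}
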