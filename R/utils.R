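# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# average month length in days (365.25 / 12); used for every PPPM denominator
MONTH_DAYS <- 30.4375

as_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x, format = "%Y-%m-%d")
}

# ICD codes are compared dot-free and case-insensitively
normalize_code <- function(x) {
  toupper(gsub(".", "", as.character(x), fixed = TRUE))
}

# TRUE where a normalized code starts with any of the (normalized) prefixes
match_prefix <- function(codes, prefixes) {
  if (length(codes) == 0L) return(logical(0))
  if (length(prefixes) == 0L) return(rep(FALSE, length(codes)))
  codes <- normalize_code(codes)
  prefixes <- normalize_code(prefixes)
  out <- rep(FALSE, length(codes))
  for (p in prefixes) out <- out | startsWith(codes, p)
  out
}

assert_prob_vector <- function(p, name, tol = 1e-9) {
  if (any(p < 0) || abs(sum(p) - 1) > tol) {
    stop(sprintf("'%s' must be a nonnegative probability vector summing to 1 (got sum %.12f)",
                 name, sum(p)), call. = FALSE)
  }
  invisible(p)
}

# number of calendar days in the intersection of closed interval [s1,e1] with [s2,e2]
overlap_days <- function(s1, e1, s2, e2) {
  pmax(0, as.integer(pmin(e1, e2)) - as.integer(pmax(s1, s2)) + 1L)
}

stop_if_missing_cols <- function(dt, cols, what) {
  miss <- setdiff(cols, names(dt))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
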