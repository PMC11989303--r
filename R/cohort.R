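#' Apply the study's inclusion and exclusion criteria
#'
#' Retains admissions of adult (age >= 18) in-county patients with informed
#' consent, a length of stay of at least half a day (the "12 h of
#' hospitalization or longer" inpatient rule applied on the day-resolution
#' stay field) and an asthma (`J45`) discharge code. Each excluded admission
#' is tallied under the *first* failing rule, in the order
#' `invalid, age, county, consent, los, no_asthma_code`, which makes the tally
#' deterministic and auditable.
#'
#' @param records Admission records as returned by [generate_cohort()] or
#'   [read_admissions()]; codes are normalized internally.
#' @return A list with `records` (the retained subset, codes canonicalized)
#'   and `exclusions` (named integer tally).
#' @export
filter_cohort <- function(records) {
  records <- as_admission_records(records)
  tally <- c(invalid = 0L, age = 0L, county = 0L, consent = 0L,
             los = 0L, no_asthma_code = 0L)
  n <- nrow(records)
  if (n == 0L) return(list(records = records, exclusions = tally))

  codes <- lapply(records$codes, function(cc) {
    tryCatch(unique(normalize_code(cc)), asthmanet_validation_error = function(e) NULL)
  })
  invalid <- vapply(codes, is.null, logical(1)) |
    is.na(records$birth_date) | is.na(records$admission_date) |
    is.na(records$los_days) |
    records$birth_date >= records$admission_date
  age <- rep(NA_integer_, n)
  age[!invalid] <- compute_age(records$birth_date[!invalid], records$admission_date[!invalid])

  fail <- rep(NA_character_, n)
  has_j45 <- vapply(codes, function(cc) !is.null(cc) && "J45" %in% cc, logical(1))
  fail[!has_j45] <- "no_asthma_code"
  fail[records$los_days < 0.5] <- "los"
  fail[!records$consent] <- "consent"
  fail[!records$in_county] <- "county"
  fail[!is.na(age) & age < 18L] <- "age"
  fail[invalid] <- "invalid"

  keep <- is.na(fail)
  tab <- table(factor(fail[!keep], levels = names(tally)))
  tally[names(tab)] <- as.integer(tab)
  out <- records[keep, , drop = FALSE]
  out$codes <- codes[keep]
  rownames(out) <- NULL
  list(records = out, exclusions = tally)
}

.sample_sd <- function(x) if (length(x) < 2L) 0 else stats::sd(x)

.named_pct <- function(tab) stats::setNames(100 * as.numeric(tab) / sum(tab), names(tab))

# population-moment (biased) skewness and excess kurtosis, the conventions of
# the usual scientific-python/R moment estimators without bias correction
.moment_skewness <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(0)
  mean((x - mean(x))^3) / m2^1.5
}

.moment_excess_kurtosis <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(0)
  mean((x - mean(x))^4) / m2^2 - 3
}

#' Baseline cohort characteristics
#'
#' Computes the baseline-characteristics summary of an admission cohort:
#' admission counts, age and length-of-stay moments, female share, the share
#' of admissions per age category and per calendar year, and the shape of the
#' age distribution (population-moment skewness and excess kurtosis, plus
#' quartiles).
#'
#' @param records Retained admission records (see [filter_cohort()]); ages are
#'   derived per admission from `birth_date` and `admission_date`.
#' @param scheme An [age_group_scheme()].
#' @return Object of class `cohort_summary`.
#' @export
cohort_summary <- function(records, scheme = age_group_scheme()) {
  records <- as_admission_records(records)
  if (nrow(records) == 0L) stop_validation("cannot summarise an empty cohort")
  age <- compute_age(records$birth_date, records$admission_date)
  grp <- assign_age_group(age, scheme)
  year <- as.integer(format(records$admission_date, "%Y"))
  structure(list(
    n = nrow(records),
    mean_age = mean(age),
    sd_age = .sample_sd(age),
    median_age = unname(stats::median(age)),
    age_quartiles = unname(stats::quantile(age, c(0.25, 0.5, 0.75))),
    pct_female = 100 * mean(records$sex == "F"),
    mean_los = mean(records$los_days),
    sd_los = .sample_sd(records$los_days),
    pct_by_age_group = .named_pct(table(grp)),
    pct_by_year = .named_pct(table(year)),
    skewness = .moment_skewness(age),
    excess_kurtosis = .moment_excess_kurtosis(age)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, digits = 2, ...) {
  cat("Cohort summary:", x$n, "admissions\n")
  cat(sprintf("  Age (years, mean +/- SD): %.1f +/- %.1f (quartiles %s)\n",
              x$mean_age, x$sd_age, paste(round(x$age_quartiles, 1), collapse = "/")))
  cat(sprintf("  Age skewness %.2f, excess kurtosis %.2f\n", x$skewness, x$excess_kurtosis))
  cat(sprintf("  Female: %.2f%%\n", x$pct_female))
  cat(sprintf("  Length of stay (days, mean +/- SD): %.1f +/- %.1f\n", x$mean_los, x$sd_los))
  cat("  Admissions by age category (%):\n")
  print(round(x$pct_by_age_group, digits))
  cat("  Admissions by year (%):\n")
  print(round(x$pct_by_year, digits))
  invisible(x)
}

#' Flatten a cohort summary to a two-column table
#'
#' @param x A `cohort_summary`.
#' @return A data frame with `criteria` and `value` columns, one row per
#'   reported statistic (the shape of a baseline-characteristics table).
#' @export
as.data.frame.cohort_summary <- function(x, ...) {
  rows <- c(
    "Admissions (n)" = x$n,
    "Age (years, mean)" = x$mean_age,
    "Age (years, SD)" = x$sd_age,
    "Age (years, median)" = x$median_age,
    "Female (%)" = x$pct_female,
    "Length of stay (days, mean)" = x$mean_los,
    "Length of stay (days, SD)" = x$sd_los,
    "Age skewness" = x$skewness,
    "Age excess kurtosis" = x$excess_kurtosis,
    stats::setNames(as.numeric(x$pct_by_age_group),
                    paste0("Age category ", names(x$pct_by_age_group), " (%)")),
    stats::setNames(as.numeric(x$pct_by_year),
                    paste0("Year ", names(x$pct_by_year), " (%)"))
  )
  data.frame(criteria = names(rows), value = unname(rows), stringsAsFactors = FALSE)
}
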