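#' Monthly admission counts
#'
#' Tallies admissions per calendar month over the study window, optionally for
#' one sex. Months with no admissions are stored as 0 and flagged as gaps.
#'
#' @param records Admission records.
#' @param sex `"all"`, `"F"` or `"M"`.
#' @param window Length-2 `Date` vector delimiting the series; defaults to the
#'   study window (see [study_window()]).
#' @return Object of class `monthly_series`: list with `start = c(year,
#'   month)`, integer `values` (one per calendar month, named `"YYYY-MM"`),
#'   `sex`, and `gap_months` (indices of zero-count months).
#' @export
monthly_series <- function(records, sex = c("all", "F", "M"), window = study_window()) {
  sex <- match.arg(sex)
  records <- as_admission_records(records)
  window <- as.Date(window)
  if (length(window) != 2L || is.na(window[1L]) || window[1L] > window[2L]) {
    stop_validation("window must be two ordered dates")
  }
  if (sex != "all") records <- records[records$sex == sex, , drop = FALSE]
  first <- as.POSIXlt(window[1L]); last <- as.POSIXlt(window[2L])
  n_months <- (last$year - first$year) * 12L + (last$mon - first$mon) + 1L
  lab_year <- first$year + 1900L + ((first$mon + seq_len(n_months) - 1L) %/% 12L)
  lab_month <- (first$mon + seq_len(n_months) - 1L) %% 12L + 1L
  labels <- sprintf("%d-%02d", lab_year, lab_month)
  key <- format(records$admission_date, "%Y-%m")
  counts <- stats::setNames(integer(n_months), labels)
  tab <- table(key)
  hit <- intersect(names(tab), labels)
  counts[hit] <- as.integer(tab[hit])
  structure(list(start = c(lab_year[1L], lab_month[1L]), values = counts,
                 sex = sex, gap_months = unname(which(counts == 0L))),
            class = "monthly_series")
}

#' @export
print.monthly_series <- function(x, ...) {
  cat(sprintf("Monthly admission series (%s): %d months from %d-%02d, total %d\n",
              x$sex, length(x$values), x$start[1L], x$start[2L], sum(x$values)))
  if (length(x$gap_months)) cat("  zero-count months:", length(x$gap_months), "\n")
  invisible(x)
}

#' Flatten a monthly series to a tidy data frame
#' @param x A `monthly_series`.
#' @return Data frame with columns `year`, `month`, `sex`, `count`.
#' @export
as.data.frame.monthly_series <- function(x, ...) {
  ym <- strsplit(names(x$values), "-", fixed = TRUE)
  data.frame(year = as.integer(vapply(ym, `[`, "", 1L)),
             month = as.integer(vapply(ym, `[`, "", 2L)),
             sex = x$sex, count = as.integer(x$values), stringsAsFactors = FALSE)
}

#' Linear trend of yearly admission counts
#'
#' Ordinary least-squares fit of yearly counts on the year index, with
#' `R^2 = 1 - SSres/SStot` (by convention 0 for a constant series), plus the
#' overall and pre-pandemic (2013-2019) mean yearly counts used to gauge the
#' pandemic's impact on admissions.
#'
#' @param yearly_counts Numeric vector of counts named by calendar year (at
#'   least 3 years).
#' @return Object of class `yearly_trend`: `slope` (admissions/year),
#'   `intercept`, `r_squared`, `overall_mean`, `pre_covid_mean`.
#' @export
yearly_trend <- function(yearly_counts) {
  if (length(yearly_counts) < 3L) stop_validation("need at least 3 yearly counts")
  y <- as.numeric(yearly_counts)
  yrs <- suppressWarnings(as.integer(names(yearly_counts)))
  x <- seq_along(y) - 1
  fit <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  pre <- if (!anyNA(yrs)) y[yrs <= 2019L] else y
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 overall_mean = mean(y),
                 pre_covid_mean = if (length(pre)) mean(pre) else NA_real_),
            class = "yearly_trend")
}

#' @export
print.yearly_trend <- function(x, ...) {
  cat(sprintf("Yearly admission trend: slope %.2f admissions/year (R^2 = %.3f)\n",
              x$slope, x$r_squared))
  cat(sprintf("  mean admissions/year: overall %.1f, pre-pandemic (<=2019) %.1f\n",
              x$overall_mean, x$pre_covid_mean))
  invisible(x)
}

#' Chi-squared test of the overall gender balance
#'
#' One-degree-of-freedom goodness-of-fit test of the observed female/male
#' admission counts against a 50:50 split (no continuity correction).
#'
#' @param n_female,n_male Nonnegative counts.
#' @return Object of class `gender_test`: `statistic`, `p_value`, `test_name`.
#' @export
gender_chi2 <- function(n_female, n_male) {
  if (n_female < 0 || n_male < 0) stop_validation("counts must be nonnegative")
  if (n_female + n_male == 0) stop_validation("need at least one admission")
  # the asymptotic one-df statistic is wanted even at small counts
  ht <- suppressWarnings(stats::chisq.test(c(n_female, n_male), p = c(0.5, 0.5)))
  structure(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                 test_name = "chi-squared goodness of fit (50:50)"),
            class = "gender_test")
}

#' Mann-Whitney test of a between-year shift in the female admission share
#'
#' Compares the 12 monthly female shares (female / total admissions per
#' calendar month) of two years with a two-sided Mann-Whitney U test (normal
#' approximation with tie correction). Months in which neither sex had an
#' admission have an undefined share and are dropped with a warning; fewer
#' than 3 usable months in a year is an error.
#'
#' @param series_f,series_m [monthly_series()] objects for females and males
#'   covering both years.
#' @param year_a,year_b The two calendar years to compare.
#' @return Object of class `gender_test` with the U `statistic`, `p_value`,
#'   `test_name` and the monthly `shares_a`, `shares_b` used.
#' @export
gender_shift_test <- function(series_f, series_m, year_a, year_b) {
  stopifnot(inherits(series_f, "monthly_series"), inherits(series_m, "monthly_series"))
  if (!identical(names(series_f$values), names(series_m$values))) {
    stop_validation("female and male series must cover the same months")
  }
  shares_for <- function(year) {
    sel <- grepl(sprintf("^%d-", year), names(series_f$values))
    if (sum(sel) != 12L) stop_validation(sprintf("year %d is not fully covered by the series", year))
    f <- as.numeric(series_f$values[sel]); m <- as.numeric(series_m$values[sel])
    tot <- f + m
    if (any(tot == 0)) {
      warning(sprintf("dropping %d month(s) of %d with no admissions (undefined share)",
                      sum(tot == 0), year))
    }
    (f / tot)[tot > 0]
  }
  a <- shares_for(year_a); b <- shares_for(year_b)
  if (length(a) < 3L || length(b) < 3L) stop_validation("fewer than 3 usable months in a year")
  if (stats::sd(c(a, b)) == 0) {
    u <- length(a) * length(b) / 2; p <- 1
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = FALSE))
    u <- unname(ht$statistic); p <- ht$p.value
  }
  structure(list(statistic = u, p_value = p,
                 test_name = "Mann-Whitney U (monthly female shares)",
                 shares_a = a, shares_b = b),
            class = "gender_test")
}

#' @export
print.gender_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$test_name, x$statistic, x$p_value))
  invisible(x)
}
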