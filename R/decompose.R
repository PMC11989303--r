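#' Classical additive seasonal decomposition of a monthly series
#'
#' Splits a monthly admission series into `observed = trend + seasonal +
#' residual`:
#' * **trend** - centered 2x12 moving average (undefined for the first and
#'   last 6 months, which are reported as `NA` rather than extrapolated);
#' * **seasonal** - for each calendar month, the mean of the detrended values
#'   of that month (over however many observations exist, so an incomplete
#'   final year is handled as-is), with the 12 effects recentered to sum to
#'   zero;
#' * **residual** - whatever remains where the trend is defined.
#'
#' `seasonal_pct` rescales the 12 monthly effects as a percentage of the
#' series mean: the deviation from average monthly admissions attributable to
#' the season.
#'
#' @param series A [monthly_series()] of length >= 24. Zero-count (gap)
#'   months trigger a warning: the additive model treats them as observed
#'   zeros.
#' @return Object of class `seasonal_decomposition` with vectors `observed`,
#'   `trend`, `seasonal`, `residual` (per month of the series),
#'   `seasonal_effects` and `seasonal_pct` (length 12, January..December),
#'   and `start`, `sex`.
#' @export
additive_decompose <- function(series) {
  stopifnot(inherits(series, "monthly_series"))
  x <- as.numeric(series$values)
  n <- length(x)
  if (n < 24L) stop_validation("decomposition needs at least 24 months")
  if (length(series$gap_months)) {
    warning("series has zero-count months; they enter the additive model as zeros")
  }
  trend <- as.numeric(stats::filter(x, c(0.5, rep(1, 11), 0.5) / 12, sides = 2))
  detrended <- x - trend
  month_of <- (series$start[2L] - 1L + seq_len(n) - 1L) %% 12L + 1L
  eff <- vapply(1:12, function(m) mean(detrended[month_of == m], na.rm = TRUE), numeric(1))
  eff <- eff - mean(eff)
  seasonal <- eff[month_of]
  structure(list(observed = x,
                 trend = trend,
                 seasonal = seasonal,
                 residual = x - trend - seasonal,
                 seasonal_effects = stats::setNames(eff, month.abb),
                 seasonal_pct = stats::setNames(100 * eff / mean(x), month.abb),
                 start = series$start, sex = series$sex),
            class = "seasonal_decomposition")
}

#' @export
print.seasonal_decomposition <- function(x, ...) {
  cat(sprintf("Additive seasonal decomposition (%s), %d months from %d-%02d\n",
              x$sex, length(x$observed), x$start[1L], x$start[2L]))
  cat("  seasonal effect, % of mean monthly admissions:\n")
  print(round(x$seasonal_pct, 1))
  invisible(x)
}

#' Plot a seasonal decomposition
#'
#' Four stacked panels (observed, trend, seasonal, residual) plus the monthly
#' seasonal effect in percent of the series mean.
#'
#' @param x A `seasonal_decomposition`.
#' @param ... Passed to [graphics::plot.default()] for the panels.
#' @export
plot.seasonal_decomposition <- function(x, ...) {
  old <- graphics::par(mfrow = c(5, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  t <- seq_along(x$observed)
  graphics::plot(t, x$observed, type = "l", ylab = "observed", xlab = "", ...)
  graphics::plot(t, x$trend, type = "l", ylab = "trend", xlab = "", ...)
  graphics::plot(t, x$seasonal, type = "l", ylab = "seasonal", xlab = "", ...)
  graphics::plot(t, x$residual, type = "h", ylab = "residual", xlab = "month index", ...)
  graphics::barplot(x$seasonal_pct, ylab = "% of mean")
  invisible(x)
}
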