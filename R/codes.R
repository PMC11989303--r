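#' Canonicalize raw ICD-10 code strings
#'
#' Hospital exports mix dotted (`"J96.0"`) and undotted (`"J960"`) ICD-10
#' spellings, lower and upper case, and sometimes carry the dagger/asterisk
#' cross-reference markers (`"B37.7!"`, `"D63.8*"`). This function reduces all
#' of them to a single canonical dotted, uppercase form. To remove registrar
#' bias in how asthma itself is coded, every code whose three-character root is
#' `J45` (any asthma subtype) collapses to plain `"J45"`.
#'
#' @param raw Character vector of raw code strings.
#' @return Character vector of canonical codes matching
#'   `[A-Z][0-9]{2}(\.[0-9A-Z]{1,4})?`.
#' @examples
#' normalize_code(c("j450", "I10", "D63.8*", "B37.7!"))
#' @export
normalize_code <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  if (!is.character(raw)) stop_validation("codes must be a character vector")
  x <- toupper(trimws(raw))
  x <- sub("[!*]+$", "", x)
  # re-dot undotted forms after the third character ("J960" -> "J96.0")
  undotted <- !grepl(".", x, fixed = TRUE) & nchar(x) > 3L
  x[undotted] <- paste0(substr(x[undotted], 1L, 3L), ".", substring(x[undotted], 4L))
  x <- sub("\\.$", "", x)
  ok <- grepl("^[A-Z][0-9]{2}(\\.[0-9A-Z]{1,4})?$", x)
  if (any(!ok)) {
    bad <- unique(raw[!ok])
    stop_validation(
      sprintf("not parseable as ICD-10 code(s): %s",
              paste(utils::head(bad, 5L), collapse = ", ")),
      raw = bad
    )
  }
  x[substr(x, 1L, 3L) == "J45"] <- "J45"
  x
}

#' Age in completed years at a reference date
#'
#' Birthday-aware integer age: the number of whole years of life completed at
#' `ref_date` (the admission date), i.e. the floor of the elapsed age.
#'
#' @param birth_date,ref_date `Date` vectors (recycled to a common length).
#' @return Integer vector of completed years.
#' @examples
#' compute_age(as.Date("2000-03-15"), as.Date("2018-03-14")) # 17
#' compute_age(as.Date("2000-03-15"), as.Date("2018-03-15")) # 18
#' @export
compute_age <- function(birth_date, ref_date) {
  birth_date <- as.Date(birth_date)
  ref_date <- as.Date(ref_date)
  if (any(birth_date >= ref_date, na.rm = TRUE)) {
    stop_validation("birth_date must precede the admission date")
  }
  b <- as.POSIXlt(birth_date)
  r <- as.POSIXlt(ref_date)
  age <- r$year - b$year
  before_birthday <- (r$mon < b$mon) | (r$mon == b$mon & r$mday < b$mday)
  as.integer(age - before_birthday)
}

#' Age-grouping scheme
#'
#' Ordered half-open age bins used throughout the analysis. The default mirrors
#' the quartile-anchored adult grouping `[18,50) [50,60) [60,70) [70,Inf)`,
#' with special attention to the 50- and 60-year thresholds.
#'
#' @param lower Strictly increasing integer lower bounds; the first must be 18
#'   (adult inclusion).
#' @param labels Optional labels, one per bin.
#' @return An object of class `age_group_scheme`.
#' @export
age_group_scheme <- function(lower = c(18L, 50L, 60L, 70L), labels = NULL) {
  if (any(diff(lower) <= 0)) stop_validation("age-group bounds must be strictly increasing")
  if (lower[1L] != 18L) stop_validation("first age-group bound must be 18 (adult cohort)")
  if (is.null(labels)) {
    upper <- c(lower[-1L] - 1L, NA)
    labels <- ifelse(is.na(upper), paste0(lower, "+"), paste0(lower, "-", upper))
  }
  if (length(labels) != length(lower)) stop_validation("one label per age-group bound required")
  structure(list(labels = labels, lower = as.integer(lower)), class = "age_group_scheme")
}

#' Assign ages to age groups
#'
#' @param age Integer vector of ages (completed years), all `>= 18`.
#' @param scheme An [age_group_scheme()].
#' @return Factor with the scheme's labels, in scheme order.
#' @export
assign_age_group <- function(age, scheme = age_group_scheme()) {
  if (any(age < scheme$lower[1L], na.rm = TRUE)) {
    stop_validation(sprintf("age below the scheme's lower bound (%d)", scheme$lower[1L]))
  }
  idx <- findInterval(age, scheme$lower)
  factor(scheme$labels[idx], levels = scheme$labels)
}
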