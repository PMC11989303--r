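#' @keywords internal
as_admission_records <- function(records) {
  needed <- c("patient_id", "birth_date", "sex", "admission_date",
              "los_days", "in_county", "consent", "codes")
  if (!is.data.frame(records) || !all(needed %in% names(records))) {
    stop_validation(sprintf("admission records need columns: %s",
                            paste(needed, collapse = ", ")))
  }
  records$birth_date <- as.Date(records$birth_date)
  records$admission_date <- as.Date(records$admission_date)
  if (!is.list(records$codes)) {
    records$codes <- strsplit(as.character(records$codes), ";", fixed = TRUE)
  }
  records
}

#' Write admission records to CSV
#'
#' Writes the canonical admission CSV dialect: header
#' `patient_id,birth_date,sex,admission_date,los_days,in_county,consent,codes`,
#' ISO-8601 dates, and the diagnosis code list joined with `;`.
#'
#' @param records Admission records (data frame with a `codes` list-column).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_admissions <- function(records, path) {
  records <- as_admission_records(records)
  out <- records[, c("patient_id", "birth_date", "sex", "admission_date",
                     "los_days", "in_county", "consent")]
  out$birth_date <- format(out$birth_date, "%Y-%m-%d")
  out$admission_date <- format(out$admission_date, "%Y-%m-%d")
  out$codes <- vapply(records$codes, paste, character(1), collapse = ";")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read admission records from CSV
#'
#' Inverse of [write_admissions()]. Codes are kept raw (split on `;`);
#' canonicalization happens in [filter_cohort()] / [aggregate_network()].
#'
#' @param path CSV file path.
#' @return Admission-records data frame with a `codes` list-column.
#' @export
read_admissions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character", codes = "character"))
  as_admission_records(df)
}

#' Read a diagnosis category map
#'
#' Reads a two-column CSV (`category,code`) mapping clinician-defined disease
#' categories to canonical ICD-10 codes. The anchor category
#' `asthma = {J45}` must be present.
#'
#' @param path CSV file path.
#' @return Named list: category label -> character vector of canonical codes.
#' @export
read_category_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("category", "code") %in% names(df))) {
    stop_validation("category map needs 'category' and 'code' columns")
  }
  mapping <- lapply(split(df$code, df$category), function(cc) unique(normalize_code(cc)))
  if (!"asthma" %in% names(mapping) || !"J45" %in% mapping$asthma) {
    stop_validation("category map must contain the anchor category asthma = {J45}")
  }
  mapping
}

#' The packaged diagnosis category map
#'
#' Clinician-style grouping of ICD-10 codes into disease categories
#' (hypertension, respiratory failure, candidiasis, obesity, smoking,
#' respiratory infections, cardiovascular, neurological, ...) used by
#' [relative_influence()]. The packaged map is disjoint: a code appearing in
#' several published community lists is kept in the category of its first,
#' clinically primary mention.
#'
#' @return Named list: category label -> character vector of canonical codes.
#' @export
default_category_map <- function() {
  read_category_map(system.file("extdata", "category_map.csv", package = "asthmanet"))
}
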