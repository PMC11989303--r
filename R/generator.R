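#' @keywords internal
.study_window <- function() c(as.Date("2013-01-01"), as.Date("2023-11-30"))

#' Study window of the admission analysis
#'
#' @return Length-2 `Date` vector: first and last admission date covered.
#' @export
study_window <- function() .study_window()

# one named RNG substream per sampling concern: adding a concern never
# perturbs the draws of existing ones
.substream_seed <- function(seed, name) {
  v <- utf8ToInt(name)
  h <- sum(v * seq_along(v)) * 1009
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483629)
}

.days_in_month <- function(year, month) {
  first <- as.Date(sprintf("%d-%02d-01", year, month))
  nxt <- ifelse(month == 12L, sprintf("%d-01-01", year + 1L),
                sprintf("%d-%02d-01", year, month + 1L))
  as.integer(as.Date(nxt) - first)
}

.check_prob <- function(x, field) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_config(field, "must be a probability in [0, 1]")
  }
}

#' Build a synthetic-cohort generator configuration
#'
#' Full stochastic specification of a synthetic admission cohort: cohort size,
#' sex balance, a truncated-Gaussian age mixture on \[18, 100\] years, yearly
#' admission weights, per-sex monthly multipliers (mean 1), a lognormal length
#' of stay, a repeat-admission rate, per-age-group planted comorbidity blocks
#' and background codes. See [baseline_config()] for the packaged calibrated
#' configuration.
#'
#' @param n_admissions Number of admission records to generate.
#' @param p_female Probability that a patient is female.
#' @param age_mixture List of components, each `list(weight, mean, sd)` in
#'   years; weights must sum to 1; draws are truncated to \[18, 100\].
#' @param year_weights Named numeric, year -> probability (must sum to 1).
#' @param month_weights_by_sex List with elements `F` and `M`, each 12
#'   nonnegative multipliers with mean 1.
#' @param los_lognormal `list(mu, sigma)` of log-days.
#' @param repeat_admission_rate Expected extra admissions per patient (>= 0).
#' @param blocks_by_age_group Named list (age-group label -> list of blocks);
#'   each block is `list(label, codes, p_active, p_code_given_active,
#'   p_code_background)` with `p_code_given_active > p_code_background` (the
#'   planted co-occurrence signal). `J45` may not appear inside a block: it is
#'   added to every admission.
#' @param background_codes List of `list(code, p)` marginal inclusion
#'   probabilities applied to every admission.
#' @param seed Integer root seed; every sampling concern derives a named
#'   substream from it.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_admissions,
                             p_female = 0.5,
                             age_mixture = list(list(weight = 1, mean = 60, sd = 15)),
                             year_weights = stats::setNames(rep(1 / 11, 11), 2013:2023),
                             month_weights_by_sex = list(F = rep(1, 12), M = rep(1, 12)),
                             los_lognormal = list(mu = 1, sigma = 1),
                             repeat_admission_rate = 0,
                             blocks_by_age_group = list(),
                             background_codes = list(),
                             seed = 1L) {
  cfg <- structure(list(
    n_admissions = n_admissions, p_female = p_female, age_mixture = age_mixture,
    year_weights = year_weights, month_weights_by_sex = month_weights_by_sex,
    los_lognormal = los_lognormal, repeat_admission_rate = repeat_admission_rate,
    blocks_by_age_group = blocks_by_age_group, background_codes = background_codes,
    seed = seed
  ), class = "generator_config")
  validate_generator_config(cfg)
}

#' Validate a generator configuration
#'
#' Checks every invariant of the configuration (normalized weights, probability
#' ranges, canonical block codes, planted-signal ordering) and fails with an
#' error naming the offending field.
#'
#' @param config A `generator_config` or a plain named list with the same
#'   fields (e.g. read from YAML).
#' @return The validated configuration (invisibly coerced to
#'   `generator_config`).
#' @export
validate_generator_config <- function(config) {
  cfg <- unclass(config)
  if (!is.numeric(cfg$n_admissions) || length(cfg$n_admissions) != 1L ||
      is.na(cfg$n_admissions) || cfg$n_admissions < 0 || cfg$n_admissions %% 1 != 0) {
    stop_config("n_admissions", "must be a nonnegative integer count")
  }
  .check_prob(cfg$p_female, "p_female")
  if (length(cfg$age_mixture) == 0L) stop_config("age_mixture", "must have at least one component")
  w <- vapply(cfg$age_mixture, function(co) co$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-9) stop_config("age_mixture", "component weights must sum to 1")
  if (any(vapply(cfg$age_mixture, function(co) co$sd < 0, logical(1)))) {
    stop_config("age_mixture", "component sds must be nonnegative")
  }
  yw <- unlist(cfg$year_weights)
  if (is.null(names(yw)) || anyNA(suppressWarnings(as.integer(names(yw))))) {
    stop_config("year_weights", "must be named by calendar year")
  }
  if (any(yw < 0) || abs(sum(yw) - 1) > 1e-9) stop_config("year_weights", "must be nonnegative and sum to 1")
  for (sx in c("F", "M")) {
    mw <- unlist(cfg$month_weights_by_sex[[sx]])
    if (length(mw) != 12L) stop_config("month_weights_by_sex", sprintf("for sex %s must have 12 entries", sx))
    if (any(mw < 0)) stop_config("month_weights_by_sex", "multipliers must be nonnegative")
    if (abs(mean(mw) - 1) > 1e-9) {
      stop_config("month_weights_by_sex", sprintf("for sex %s must have mean 1", sx))
    }
  }
  if (!is.finite(cfg$los_lognormal$mu) || !is.finite(cfg$los_lognormal$sigma) ||
      cfg$los_lognormal$sigma < 0) {
    stop_config("los_lognormal", "must give finite mu and nonnegative sigma")
  }
  if (!is.numeric(cfg$repeat_admission_rate) || cfg$repeat_admission_rate < 0) {
    stop_config("repeat_admission_rate", "must be >= 0")
  }
  labels <- age_group_scheme()$labels
  if (length(cfg$blocks_by_age_group) &&
      !all(names(cfg$blocks_by_age_group) %in% labels)) {
    stop_config("blocks_by_age_group", sprintf("keys must be age-group labels (%s)",
                                               paste(labels, collapse = ", ")))
  }
  for (g in names(cfg$blocks_by_age_group)) {
    for (b in cfg$blocks_by_age_group[[g]]) {
      codes <- normalize_code(unlist(b$codes))
      if ("J45" %in% codes) stop_config("blocks_by_age_group", "blocks may not contain J45 (added to every admission)")
      .check_prob(b$p_active, "blocks_by_age_group$p_active")
      .check_prob(b$p_code_given_active, "blocks_by_age_group$p_code_given_active")
      .check_prob(b$p_code_background, "blocks_by_age_group$p_code_background")
      if (b$p_code_given_active <= b$p_code_background) {
        stop_config("blocks_by_age_group", "requires p_code_given_active > p_code_background")
      }
    }
  }
  for (bc in cfg$background_codes) {
    normalize_code(bc$code)
    .check_prob(bc$p, "background_codes$p")
  }
  structure(cfg, class = "generator_config")
}

#' The packaged baseline generator configuration
#'
#' Reads the calibrated baseline configuration shipped with the package
#' (`extdata/baseline_config.yaml`): 13,695 admissions over 2013-01-01 to
#' 2023-11-30 with the cohort's demographics (57.72% female; integer age mean
#' 59.6, SD 14.8, quartiles 51/62/70, skewness -0.57), the observed yearly
#' admission shares, per-sex seasonal multipliers and age-group comorbidity
#' blocks mirroring the published community structure.
#'
#' @param path Optional path to an alternative YAML configuration file.
#' @return A validated `generator_config`.
#' @export
baseline_config <- function(path = system.file("extdata", "baseline_config.yaml",
                                               package = "asthmanet")) {
  raw <- yaml::read_yaml(path)
  raw$year_weights <- unlist(raw$year_weights)
  raw$month_weights_by_sex <- lapply(raw$month_weights_by_sex, unlist)
  validate_generator_config(raw)
}

# draw from the truncated Gaussian mixture with per-draw bounds [lo, hi]
.sample_mixture <- function(n, mixture, lo, hi) {
  w <- vapply(mixture, function(co) co$weight, numeric(1))
  mu <- vapply(mixture, function(co) co$mean, numeric(1))
  sd <- vapply(mixture, function(co) co$sd, numeric(1))
  out <- rep(NA_real_, n)
  todo <- seq_len(n)
  for (it in seq_len(1000L)) {
    if (!length(todo)) break
    comp <- sample.int(length(w), length(todo), replace = TRUE, prob = w)
    x <- stats::rnorm(length(todo), mu[comp], sd[comp])
    ok <- x >= lo[todo] & x <= hi[todo]
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  if (length(todo)) out[todo] <- pmin(pmax(mu[1L], lo[todo]), hi[todo])
  out
}

#' Generate a synthetic admission cohort
#'
#' Draws `n_admissions` admission records with the statistical structure the
#' downstream analysis assumes: demographics from the configured sex
#' probability and truncated age mixture, admission dates from the yearly
#' weights and per-sex monthly multipliers (the final, incomplete calendar
#' year covers January-November only), lognormal lengths of stay, and
#' diagnosis code lists built as `{J45}` plus planted per-age-group
#' comorbidity-block codes plus background codes. Patients may contribute
#' several admissions (`repeat_admission_rate`); a patient's chronic block
#' assignment is drawn once, so repeat admissions re-inject the same chronic
#' codes.
#'
#' Identical configurations (including `seed`) give byte-identical cohorts;
#' each sampling concern draws from its own named substream of the root seed.
#'
#' @param config A validated [generator_config()].
#' @return A data frame of admission records with columns `patient_id`,
#'   `birth_date`, `sex`, `admission_date`, `los_days`, `in_county`,
#'   `consent` and the list-column `codes`.
#' @export
generate_cohort <- function(config) {
  config <- validate_generator_config(config)
  n <- as.integer(config$n_admissions)
  empty <- data.frame(patient_id = character(0), birth_date = as.Date(character(0)),
                      sex = character(0), admission_date = as.Date(character(0)),
                      los_days = numeric(0), in_county = logical(0),
                      consent = logical(0), stringsAsFactors = FALSE)
  empty$codes <- list()
  if (n == 0L) return(empty)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  root <- config$seed

  # --- patients: number of admissions each -------------------------------
  set.seed(.substream_seed(root, "patient_counts"))
  extra <- if (config$repeat_admission_rate > 0) stats::rpois(n, config$repeat_admission_rate) else integer(n)
  counts <- 1L + extra
  np <- which(cumsum(counts) >= n)[1L]
  counts <- counts[seq_len(np)]
  counts[np] <- counts[np] - (sum(counts) - n)

  set.seed(.substream_seed(root, "sex"))
  sex_p <- ifelse(stats::runif(np) < config$p_female, "F", "M")

  pat <- rep.int(seq_len(np), counts)
  sex <- sex_p[pat]

  # --- admission dates ---------------------------------------------------
  set.seed(.substream_seed(root, "dates"))
  years <- as.integer(names(config$year_weights))
  yr <- years[sample.int(length(years), n, replace = TRUE, prob = config$year_weights)]
  last_year <- as.integer(format(.study_window()[2L], "%Y"))
  last_month <- as.integer(format(.study_window()[2L], "%m"))
  mo <- integer(n)
  for (sx in c("F", "M")) {
    mw <- config$month_weights_by_sex[[sx]]
    for (partial in c(FALSE, TRUE)) {
      idx <- which(sex == sx & (yr == last_year) == partial)
      if (!length(idx)) next
      mset <- if (partial) seq_len(last_month) else 1:12
      mo[idx] <- mset[sample.int(length(mset), length(idx), replace = TRUE, prob = mw[mset])]
    }
  }
  day <- 1L + as.integer(floor(stats::runif(n) * .days_in_month(yr, mo)))
  adm <- as.Date(sprintf("%d-%02d-%02d", yr, mo, day))

  # --- ages and birth dates ---------------------------------------------
  # anchor each patient's age draw at the mean of their admission dates so
  # repeat admissions perturb the per-admission age marginal symmetrically
  set.seed(.substream_seed(root, "age"))
  adm_num <- as.numeric(adm)
  fpat <- factor(pat, levels = seq_len(np))
  anchor <- as.numeric(tapply(adm_num, fpat, mean))
  earliest <- as.numeric(tapply(adm_num, fpat, min))
  latest <- as.numeric(tapply(adm_num, fpat, max))
  lo <- 18 + (anchor - earliest) / 365.2425 + 0.01
  hi <- 100 - (latest - anchor) / 365.2425
  age_c <- .sample_mixture(np, config$age_mixture, lo, hi)
  birth <- as.Date(round(anchor - age_c * 365.2425), origin = "1970-01-01")
  # guard the integer-age adult bound against day-rounding at the boundary
  first_date <- as.Date(earliest, origin = "1970-01-01")
  md <- format(first_date, "%m-%d")
  md[md == "02-29"] <- "02-28"
  lim <- as.Date(sprintf("%d-%s", as.integer(format(first_date, "%Y")) - 18L, md))
  birth <- pmin(birth, lim - 1L)

  # --- length of stay ----------------------------------------------------
  set.seed(.substream_seed(root, "los"))
  los <- stats::rlnorm(n, config$los_lognormal$mu, config$los_lognormal$sigma)

  # --- diagnosis codes ---------------------------------------------------
  first_age <- compute_age(birth, first_date)
  pat_group <- assign_age_group(pmax(first_age, 18L))
  idx_acc <- list()
  code_acc <- list()
  k <- 0L
  set.seed(.substream_seed(root, "blocks"))
  for (g in names(config$blocks_by_age_group)) {
    pats_g <- which(pat_group == g)
    if (!length(pats_g)) next
    adm_g <- which(pat_group[pat] == g)
    for (b in config$blocks_by_age_group[[g]]) {
      fired <- stats::runif(length(pats_g)) < b$p_active
      fired_pat <- logical(np)
      fired_pat[pats_g[fired]] <- TRUE
      p_adm <- ifelse(fired_pat[pat[adm_g]], b$p_code_given_active, b$p_code_background)
      for (cc in normalize_code(unlist(b$codes))) {
        inc <- adm_g[stats::runif(length(adm_g)) < p_adm]
        if (length(inc)) {
          k <- k + 1L
          idx_acc[[k]] <- inc
          code_acc[[k]] <- rep.int(cc, length(inc))
        }
      }
    }
  }
  set.seed(.substream_seed(root, "background"))
  for (bc in config$background_codes) {
    inc <- which(stats::runif(n) < bc$p)
    if (length(inc)) {
      k <- k + 1L
      idx_acc[[k]] <- inc
      code_acc[[k]] <- rep.int(normalize_code(bc$code), length(inc))
    }
  }
  if (k > 0L) {
    extra_codes <- split(unlist(code_acc), factor(unlist(idx_acc), levels = seq_len(n)))
    codes <- lapply(extra_codes, function(cc) c("J45", sort(unique(cc))))
    names(codes) <- NULL
  } else {
    codes <- rep(list("J45"), n)
  }

  out <- data.frame(
    patient_id = sprintf("P%06d", pat),
    birth_date = birth[pat],
    sex = sex,
    admission_date = adm,
    los_days = los,
    in_county = TRUE,
    consent = TRUE,
    stringsAsFactors = FALSE
  )
  out$codes <- codes
  out
}
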