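.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(path)
}

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
  })
  message(sprintf("[asthmanet] stage %-10s done in %.2fs", name, proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full admission-analysis pipeline
#'
#' Orchestrates every stage on one admission cohort and writes a reproducible
#' report bundle: the synthetic cohort (or an admission CSV you supply), the
#' inclusion filter and baseline summary, yearly trend and gender tests, the
#' per-sex seasonal decomposition, and per age group the comorbidity graph
#' (GraphML + GEXF + node CSV), community partition, centrality table,
#' network summary and category influence report, plus a manifest echoing the
#' configuration. The same configuration and seed always produce an identical
#' bundle; all logging goes to `stderr`.
#'
#' @param outdir Output directory (created if needed).
#' @param input Path to an admission CSV, or `NULL` to simulate.
#' @param generator A [generator_config()] used when `input` is `NULL`
#'   (default: [baseline_config()]).
#' @param seed Integer seed; overrides the generator's seed and seeds
#'   community detection.
#' @param scheme An [age_group_scheme()].
#' @param categories Category map for influence reports.
#' @param resolution Community-detection resolution.
#' @param bc_weighted Use weighted-distance betweenness?
#' @param bc_normalization `"max"` or `"combinatorial"`.
#' @param shift_years Two calendar years for the gender-shift test.
#' @param write_cohort_csv Also write the analysed admissions as CSV?
#' @return Invisibly, a list with all in-memory results (`records`,
#'   `summary`, `trend`, `tests`, `decomposition`, `networks`).
#' @export
run_pipeline <- function(outdir,
                         input = NULL,
                         generator = baseline_config(),
                         seed = NULL,
                         scheme = age_group_scheme(),
                         categories = default_category_map(),
                         resolution = 1,
                         bc_weighted = FALSE,
                         bc_normalization = "max",
                         shift_years = c(2020L, 2021L),
                         write_cohort_csv = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  records <- .stage("cohort", {
    if (is.null(input)) {
      if (!is.null(seed)) generator$seed <- seed
      generate_cohort(generator)
    } else {
      if (!file.exists(input)) stop(sprintf("admission file not found: %s", input))
      read_admissions(input)
    }
  })
  if (isTRUE(write_cohort_csv)) write_admissions(records, file.path(outdir, "admissions.csv"))

  filt <- .stage("filter", filter_cohort(records))
  cohort <- filt$records
  summ <- .stage("summarize", cohort_summary(cohort, scheme))
  summ_json <- unclass(summ)
  summ_json$pct_by_age_group <- as.list(summ_json$pct_by_age_group)
  summ_json$pct_by_year <- as.list(summ_json$pct_by_year)
  .write_json(c(summ_json, list(exclusions = as.list(filt$exclusions))),
              file.path(outdir, "cohort_summary.json"))
  utils::write.csv(as.data.frame(summ), file.path(outdir, "cohort_summary.csv"),
                   row.names = FALSE)

  trends <- .stage("trends", {
    year <- format(cohort$admission_date, "%Y")
    yearly <- table(year)
    trend <- yearly_trend(stats::setNames(as.numeric(yearly), names(yearly)))
    chi2 <- gender_chi2(sum(cohort$sex == "F"), sum(cohort$sex == "M"))
    ser_f <- monthly_series(cohort, "F")
    ser_m <- monthly_series(cohort, "M")
    shift <- gender_shift_test(ser_f, ser_m, shift_years[1L], shift_years[2L])
    list(trend = trend, chi2 = chi2, shift = shift, ser_f = ser_f, ser_m = ser_m,
         yearly = yearly)
  })
  .write_json(list(yearly_counts = as.list(trends$yearly),
                   trend = unclass(trends$trend),
                   gender_chi2 = unclass(trends$chi2)[c("statistic", "p_value", "test_name")],
                   gender_shift = unclass(trends$shift)[c("statistic", "p_value", "test_name")]),
              file.path(outdir, "trends.json"))

  series_all <- monthly_series(cohort, "all")
  utils::write.csv(rbind(as.data.frame(series_all),
                         as.data.frame(trends$ser_f),
                         as.data.frame(trends$ser_m)),
                   file.path(outdir, "monthly_series.csv"), row.names = FALSE)

  decomp <- .stage("decompose", {
    lapply(list(F = trends$ser_f, M = trends$ser_m), function(s) {
      suppressWarnings(additive_decompose(s))
    })
  })
  for (sx in names(decomp)) {
    d <- decomp[[sx]]
    .write_json(list(sex = sx, seasonal_effects = as.list(d$seasonal_effects),
                     seasonal_pct = as.list(d$seasonal_pct)),
                file.path(outdir, sprintf("decomposition_%s.json", sx)))
  }

  networks <- .stage("network", {
    lapply(stats::setNames(scheme$labels, scheme$labels), function(g_lab) {
      graph <- aggregate_network(cohort, g_lab, scheme)
      centr <- betweenness_centrality(graph, weighted = bc_weighted,
                                      normalization = bc_normalization)
      part <- detect_communities(graph, resolution = resolution,
                                 seed = if (is.null(seed)) 1L else seed)
      infl <- relative_influence(centr, categories)
      list(graph = graph, centrality = centr, partition = part, influence = infl,
           summary = network_summary(graph, part, centr))
    })
  })
  .stage("influence", {
    for (g_lab in names(networks)) {
      nw <- networks[[g_lab]]
      safe <- gsub("[^0-9A-Za-z]+", "_", g_lab)
      export_network(nw$graph, nw$partition, nw$centrality, categories,
                     graphml = file.path(outdir, sprintf("network_%s.graphml", safe)),
                     gexf = file.path(outdir, sprintf("network_%s.gexf", safe)),
                     nodes_csv = file.path(outdir, sprintf("nodes_%s.csv", safe)))
      .write_json(list(age_group = g_lab, summary = nw$summary,
                       influence_pct = as.list(nw$influence$per_category),
                       anchor_norm_bc = nw$influence$anchor_bc),
                  file.path(outdir, sprintf("influence_%s.json", safe)))
      utils::write.csv(as.data.frame(nw$influence),
                       file.path(outdir, sprintf("influence_%s.csv", safe)),
                       row.names = FALSE)
    }
    invisible(NULL)
  })

  manifest <- list(
    package = "asthmanet",
    version = as.character(utils::packageVersion("asthmanet")),
    seed = if (is.null(seed)) generator$seed else seed,
    input = if (is.null(input)) "simulated" else basename(input),
    generator = if (is.null(input)) unclass(generator) else NULL,
    options = list(resolution = resolution, bc_weighted = bc_weighted,
                   bc_normalization = bc_normalization,
                   shift_years = as.integer(shift_years),
                   age_groups = scheme$labels),
    exclusions = as.list(filt$exclusions)
  )
  .write_json(manifest, file.path(outdir, "manifest.json"))

  invisible(list(records = records, cohort = cohort, exclusions = filt$exclusions,
                 summary = summ, trend = trends$trend, chi2 = trends$chi2,
                 shift = trends$shift, decomposition = decomp, networks = networks))
}
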