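#' Relative influence of diagnosis categories, anchored on the asthma code
#'
#' The category-level statistic of the comorbidity analysis: for each
#' clinician-defined category, the sum of the normalized betweenness values of
#' its member codes, divided by the normalized betweenness of the asthma
#' (`J45`) node, expressed in percent. The anchor category always scores
#' exactly 100; category members absent from the graph contribute 0; values
#' above 100 are possible for categories that collectively out-broker asthma.
#' The statistic is scale-free: rescaling all raw centralities leaves it
#' unchanged.
#'
#' @param centrality A `centrality_table` (see [betweenness_centrality()]).
#' @param categories Named list of code vectors (see
#'   [default_category_map()]).
#' @param anchor Anchor code, default `"J45"`; must be present with positive
#'   normalized betweenness (otherwise the graph does not represent an asthma
#'   cohort and an error of class `asthmanet_anchor_error` is raised).
#' @return Object of class `influence_report`: `per_category` (named percent
#'   vector, sorted decreasing), `anchor_bc`, `per_node` (named list:
#'   category -> named member centralities, absent members 0).
#' @export
relative_influence <- function(centrality, categories = default_category_map(),
                               anchor = "J45") {
  stopifnot(inherits(centrality, "centrality_table"))
  bc <- stats::setNames(centrality$norm_bc, centrality$code)
  if (!anchor %in% names(bc) || bc[[anchor]] <= 0) {
    stop_asthmanet(
      sprintf("anchor code %s is absent or has zero betweenness: not an asthma-cohort graph", anchor),
      "asthmanet_anchor_error")
  }
  per_node <- lapply(categories, function(cc) {
    v <- stats::setNames(rep(0, length(cc)), cc)
    hit <- intersect(cc, names(bc))
    v[hit] <- bc[hit]
    v
  })
  per_category <- vapply(per_node, function(v) 100 * sum(v) / bc[[anchor]], numeric(1))
  structure(list(per_category = sort(per_category, decreasing = TRUE),
                 anchor_bc = unname(bc[[anchor]]),
                 per_node = per_node),
            class = "influence_report")
}

#' @export
print.influence_report <- function(x, digits = 2, ...) {
  cat(sprintf("Category relative influence (anchor J45, norm BC %.3f):\n", x$anchor_bc))
  print(round(x$per_category, digits))
  invisible(x)
}

#' Flatten an influence report
#' @param x An `influence_report`.
#' @return Data frame with `category` and `relative_influence_pct` columns.
#' @export
as.data.frame.influence_report <- function(x, ...) {
  data.frame(category = names(x$per_category),
             relative_influence_pct = unname(x$per_category),
             stringsAsFactors = FALSE)
}

#' Influence ratio of two codes
#'
#' Generic node-level comparison, e.g. acute (`J96.0`) versus chronic
#' (`J96.1`) respiratory failure across age groups. A code absent from the
#' graph has influence 0 (so the ratio is 0 when the numerator is absent); a
#' zero or absent denominator is a degenerate-ratio error.
#'
#' @param centrality A `centrality_table`.
#' @param code_a,code_b Canonical codes (numerator, denominator).
#' @return `norm_bc(code_a) / norm_bc(code_b)`.
#' @export
influence_ratio <- function(centrality, code_a, code_b) {
  stopifnot(inherits(centrality, "centrality_table"))
  bc <- stats::setNames(centrality$norm_bc, centrality$code)
  den <- if (code_b %in% names(bc)) bc[[code_b]] else 0
  if (den <= 0) {
    stop_asthmanet(sprintf("denominator code %s absent or with zero betweenness", code_b),
                   "asthmanet_degenerate_ratio_error")
  }
  num <- if (code_a %in% names(bc)) bc[[code_a]] else 0
  unname(num / den)
}
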