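#' All comorbidity pairs of one admission
#'
#' One hospitalization's discharge diagnoses form a clique: every unordered
#' pair of distinct canonical codes co-occurs. Codes are canonicalized (so all
#' J45 subcodes merge to `J45`) and deduplicated first.
#'
#' @param codes Character vector of (raw or canonical) ICD-10 codes.
#' @return Two-column character matrix of unordered pairs (each row sorted);
#'   zero rows for fewer than two distinct codes.
#' @export
admission_clique <- function(codes) {
  cc <- sort(unique(normalize_code(codes)))
  if (length(cc) < 2L) {
    return(matrix(character(0), ncol = 2L, dimnames = list(NULL, c("a", "b"))))
  }
  pairs <- t(utils::combn(cc, 2L))
  dimnames(pairs) <- list(NULL, c("a", "b"))
  pairs
}

#' Aggregate admission cliques into an age-group co-occurrence graph
#'
#' Builds the weighted undirected comorbidity graph of one age group: nodes
#' are the canonical codes appearing on the group's admissions, and the weight
#' of edge \{a, b\} is the number of admissions whose code set contains both
#' `a` and `b`. Every admission counts as a separate event, so repeat
#' admissions of the same patient contribute repeatedly.
#'
#' @param records Admission records (filtered; codes may still be raw).
#' @param age_group Label of the group to aggregate, or `NULL` for all
#'   admissions.
#' @param scheme An [age_group_scheme()].
#' @return Object of class `code_graph`: list with the `igraph` `graph`
#'   (vertices in sorted code order, edge attribute `weight`), `age_group` and
#'   `n_admissions`.
#' @export
aggregate_network <- function(records, age_group = NULL, scheme = age_group_scheme()) {
  records <- as_admission_records(records)
  if (!is.null(age_group)) {
    age <- compute_age(records$birth_date, records$admission_date)
    records <- records[as.character(assign_age_group(age, scheme)) %in% age_group, , drop = FALSE]
  }
  code_sets <- lapply(records$codes, function(cc) unique(normalize_code(cc)))
  nodes <- sort(unique(unlist(code_sets)))
  pair_list <- lapply(code_sets, function(cc) {
    cc <- sort(cc)
    if (length(cc) < 2L) return(NULL)
    t(utils::combn(cc, 2L))
  })
  pairs <- do.call(rbind, pair_list)
  if (is.null(pairs) || nrow(pairs) == 0L) {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    if (length(nodes)) g <- igraph::add_vertices(g, length(nodes), name = nodes)
  } else {
    key <- paste(pairs[, 1L], pairs[, 2L], sep = "\r")
    tab <- table(key)
    ab <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
    edges <- data.frame(a = ab[, 1L], b = ab[, 2L], weight = as.integer(tab),
                        stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(name = nodes))
  }
  structure(list(graph = g,
                 age_group = if (is.null(age_group)) "all" else age_group,
                 n_admissions = nrow(records)),
            class = "code_graph")
}

#' Build a `code_graph` from an explicit edge list
#'
#' Mainly for tests and small worked examples.
#'
#' @param edges Data frame with columns `a`, `b` and optionally `weight`
#'   (default 1).
#' @param nodes Optional character vector of additional (isolated) nodes.
#' @param age_group Label to attach.
#' @return A `code_graph`.
#' @export
code_graph <- function(edges, nodes = NULL, age_group = "all") {
  if (is.null(edges$weight)) edges$weight <- 1L
  all_nodes <- sort(unique(c(edges$a, edges$b, nodes)))
  g <- igraph::graph_from_data_frame(edges[, c("a", "b", "weight")], directed = FALSE,
                                     vertices = data.frame(name = all_nodes))
  structure(list(graph = g, age_group = age_group, n_admissions = NA_integer_),
            class = "code_graph")
}

#' @export
print.code_graph <- function(x, ...) {
  cat(sprintf("Comorbidity co-occurrence graph [%s]: %d codes, %d edges, %s admissions\n",
              x$age_group, igraph::vcount(x$graph), igraph::ecount(x$graph),
              ifelse(is.na(x$n_admissions), "?", x$n_admissions)))
  invisible(x)
}

#' Betweenness centrality of a comorbidity graph
#'
#' Exact (Brandes) betweenness over shortest paths in the undirected graph,
#' with each unordered source-target pair counted once and disconnected pairs
#' contributing nothing. By default the shortest-path topology is unweighted
#' (co-occurrence counts are kept for community detection only);
#' `weighted = TRUE` switches to weighted distances `1/weight` for
#' sensitivity analysis. Raw values are rescaled to \[0, 1\] so that networks
#' of different age groups are comparable: by default division by the maximum
#' observed value (`normalization = "max"`; an all-zero table stays zero),
#' alternatively by the combinatorial bound `(n-1)(n-2)/2`.
#'
#' @param graph A `code_graph`.
#' @param weighted Use `1/weight` shortest-path distances?
#' @param normalization `"max"` (default) or `"combinatorial"`.
#' @return Object of class `centrality_table`: data frame with columns
#'   `code`, `raw_bc`, `norm_bc`.
#' @export
betweenness_centrality <- function(graph, weighted = FALSE,
                                   normalization = c("max", "combinatorial")) {
  stopifnot(inherits(graph, "code_graph"))
  normalization <- match.arg(normalization)
  g <- graph$graph
  n <- igraph::vcount(g)
  if (n == 0L) {
    out <- data.frame(code = character(0), raw_bc = numeric(0), norm_bc = numeric(0))
    return(structure(out, class = c("centrality_table", "data.frame")))
  }
  wts <- if (weighted && igraph::ecount(g) > 0) 1 / igraph::E(g)$weight else NA
  raw <- igraph::betweenness(g, directed = FALSE, weights = wts)
  denom <- switch(normalization,
                  max = max(raw),
                  combinatorial = if (n > 2L) (n - 1) * (n - 2) / 2 else 0)
  norm <- if (denom > 0) raw / denom else rep(0, n)
  out <- data.frame(code = igraph::V(g)$name, raw_bc = unname(raw),
                    norm_bc = unname(norm), stringsAsFactors = FALSE)
  structure(out, class = c("centrality_table", "data.frame"))
}

#' Louvain communities of a comorbidity graph
#'
#' Multi-level (Louvain) greedy optimization of weighted modularity, with
#' edge weights the co-occurrence counts. Vertices enter in sorted code order
#' and the RNG is seeded, so the partition is deterministic for a given graph,
#' resolution and seed. Community ids are re-labelled by descending community
#' size (rank 1 = the main community, corresponding to the "purple" cluster of
#' the figure convention, rank 2 the secondary, ...), ties broken by smallest
#' member code.
#'
#' @param graph A `code_graph` (non-empty).
#' @param resolution Modularity resolution (> 0, default 1).
#' @param seed Integer seed for the sweep.
#' @return Object of class `community_partition`: `assignment` (named integer
#'   vector of size-ranked community ids), `modularity`, `sizes` (named by
#'   rank).
#' @export
detect_communities <- function(graph, resolution = 1, seed = 1L) {
  stopifnot(inherits(graph, "code_graph"))
  if (!is.numeric(resolution) || resolution <= 0) {
    stop_validation("resolution must be > 0")
  }
  g <- graph$graph
  if (igraph::vcount(g) == 0L) stop_validation("cannot partition an empty graph")
  ord <- order(igraph::V(g)$name)
  g <- igraph::permute(g, order(ord))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  wts <- if (igraph::ecount(g) > 0) igraph::E(g)$weight else NULL
  cl <- igraph::cluster_louvain(g, weights = wts, resolution = resolution)
  memb <- igraph::membership(cl)
  sizes <- table(memb)
  min_code <- vapply(names(sizes), function(id) min(names(memb)[memb == id]), character(1))
  rank_order <- names(sizes)[order(-as.integer(sizes), min_code)]
  relabel <- stats::setNames(seq_along(rank_order), rank_order)
  assignment <- stats::setNames(as.integer(relabel[as.character(memb)]), names(memb))
  mod <- igraph::modularity(g, memb, weights = wts, resolution = resolution)
  structure(list(assignment = assignment, modularity = mod,
                 sizes = stats::setNames(as.integer(sort(table(assignment), decreasing = TRUE)),
                                         sort(unique(assignment)))),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("Community partition: %d communities, modularity %.4f\n",
              length(x$sizes), x$modularity))
  cat("  sizes (by rank):", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Structural summary of one age-group network
#'
#' @param graph A `code_graph`.
#' @param partition Optional `community_partition` of the graph.
#' @param centrality Optional `centrality_table` of the graph.
#' @return List: node/edge counts, density, community count and top-3 sizes,
#'   modularity, and the community id (size rank) housing the asthma code.
#' @export
network_summary <- function(graph, partition = NULL, centrality = NULL) {
  stopifnot(inherits(graph, "code_graph"))
  g <- graph$graph
  n <- igraph::vcount(g)
  out <- list(age_group = graph$age_group,
              n_admissions = graph$n_admissions,
              nodes = n, edges = igraph::ecount(g),
              density = if (n > 1L) igraph::edge_density(g) else 0,
              n_communities = 0L, top_community_sizes = integer(0),
              modularity = NA_real_, j45_community = NA_integer_)
  if (!is.null(partition)) {
    out$n_communities <- length(partition$sizes)
    out$top_community_sizes <- utils::head(unname(partition$sizes), 3L)
    out$modularity <- partition$modularity
    if ("J45" %in% names(partition$assignment)) {
      out$j45_community <- unname(partition$assignment[["J45"]])
    }
  }
  if (!is.null(centrality) && "J45" %in% centrality$code) {
    out$j45_norm_bc <- centrality$norm_bc[centrality$code == "J45"]
  }
  out
}

#' Export a comorbidity graph with its analysis attributes
#'
#' Writes the graph as GraphML and/or GEXF with the edge attribute `weight`
#' and node attributes `community`, `bc_raw`, `bc_norm`, plus a CSV node
#' table (`code, community, bc_raw, bc_norm, category`).
#'
#' @param graph A `code_graph`.
#' @param partition,centrality Optional analysis results to attach.
#' @param categories Optional category map (see [default_category_map()]) for
#'   the node table.
#' @param graphml,gexf,nodes_csv Output paths (`NULL` to skip).
#' @return Invisibly, the named list of files written.
#' @export
export_network <- function(graph, partition = NULL, centrality = NULL,
                           categories = NULL, graphml = NULL, gexf = NULL,
                           nodes_csv = NULL) {
  stopifnot(inherits(graph, "code_graph"))
  g <- graph$graph
  codes <- igraph::V(g)$name
  comm <- if (!is.null(partition)) unname(partition$assignment[codes]) else rep(NA_integer_, length(codes))
  bc_raw <- bc_norm <- rep(NA_real_, length(codes))
  if (!is.null(centrality)) {
    m <- match(codes, centrality$code)
    bc_raw <- centrality$raw_bc[m]; bc_norm <- centrality$norm_bc[m]
  }
  igraph::V(g)$community <- comm
  igraph::V(g)$bc_raw <- bc_raw
  igraph::V(g)$bc_norm <- bc_norm
  written <- list()
  if (!is.null(graphml)) {
    igraph::write_graph(g, graphml, format = "graphml")
    written$graphml <- graphml
  }
  if (!is.null(gexf)) {
    .write_gexf(g, gexf)
    written$gexf <- gexf
  }
  if (!is.null(nodes_csv)) {
    cat_of <- rep(NA_character_, length(codes))
    if (!is.null(categories)) {
      for (lab in names(categories)) {
        cat_of[codes %in% categories[[lab]] & is.na(cat_of)] <- lab
      }
    }
    utils::write.csv(data.frame(code = codes, community = comm, bc_raw = bc_raw,
                                bc_norm = bc_norm, category = cat_of,
                                stringsAsFactors = FALSE),
                     nodes_csv, row.names = FALSE)
    written$nodes_csv <- nodes_csv
  }
  invisible(written)
}

# minimal GEXF 1.3 writer: weighted undirected edges + the three node attributes
.write_gexf <- function(g, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  codes <- esc(igraph::V(g)$name)
  att <- function(v) ifelse(is.na(v), "", format(v, digits = 12, trim = TRUE, scientific = FALSE))
  node_lines <- sprintf(
    paste0('      <node id="%s" label="%s">\n        <attvalues>',
           '<attvalue for="community" value="%s"/>',
           '<attvalue for="bc_raw" value="%s"/>',
           '<attvalue for="bc_norm" value="%s"/>',
           '</attvalues>\n      </node>'),
    codes, codes, att(igraph::V(g)$community), att(igraph::V(g)$bc_raw),
    att(igraph::V(g)$bc_norm))
  el <- igraph::as_edgelist(g, names = TRUE)
  w <- if (igraph::ecount(g) > 0) igraph::E(g)$weight else numeric(0)
  edge_lines <- if (nrow(el)) {
    sprintf('      <edge id="%d" source="%s" target="%s" weight="%s"/>',
            seq_len(nrow(el)), esc(el[, 1L]), esc(el[, 2L]), att(w))
  } else character(0)
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://gexf.net/1.3" version="1.3">',
    '  <graph defaultedgetype="undirected">',
    '    <attributes class="node">',
    '      <attribute id="community" title="community" type="integer"/>',
    '      <attribute id="bc_raw" title="bc_raw" type="double"/>',
    '      <attribute id="bc_norm" title="bc_norm" type="double"/>',
    '    </attributes>',
    '    <nodes>', node_lines, '    </nodes>',
    '    <edges>', edge_lines, '    </edges>',
    '  </graph>', '</gexf>'), con = path)
  invisible(path)
}
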