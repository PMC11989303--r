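test_that("admission_clique forms all pairs over distinct canonical codes", {
  tri <- admission_clique(c("J45", "I10", "E66.0"))
  expect_equal(nrow(tri), 3L)
  expect_equal(nrow(admission_clique("J45")), 0L)
  # J45 subcodes merge before pairing
  merged <- admission_clique(c("J45", "J45.0", "I10"))
  expect_equal(nrow(merged), 1L)
  expect_equal(unname(merged[1, ]), c("I10", "J45"))
  # duplicates never create self-pairs
  dup <- admission_clique(c("I10", "i10", "J45"))
  expect_true(all(dup[, 1] != dup[, 2]))
})

test_that("aggregate_network weights equal per-admission co-occurrence counts", {
  recs <- make_records(list(c("J45", "I10", "E66.0"), c("J45", "I10")))
  g <- aggregate_network(recs)
  w <- function(a, b) {
    e <- igraph::get_edge_ids(g$graph, c(a, b))
    if (e == 0) 0L else igraph::E(g$graph)$weight[e]
  }
  expect_equal(w("J45", "I10"), 2L)
  expect_equal(w("J45", "E66.0"), 1L)
  expect_equal(w("I10", "E66.0"), 1L)
  expect_equal(g$n_admissions, 2L)

  # empty input gives an empty, still-valid graph
  eg <- aggregate_network(make_records(list()))
  expect_equal(igraph::vcount(eg$graph), 0L)

  # a repeat admission counts as a separate event: weights double
  rep2 <- make_records(list(c("J45", "I10"), c("J45", "I10")), id = c("P1", "P1"))
  g2 <- aggregate_network(rep2)
  expect_equal(igraph::E(g2$graph)$weight, 2L)

  # an admission with a single code contributes an isolated node
  iso <- aggregate_network(make_records(list(c("J45", "I10"), "E66.0")))
  expect_true("E66.0" %in% igraph::V(iso$graph)$name)
  expect_equal(igraph::degree(iso$graph)["E66.0"][[1]], 0)
})

test_that("aggregate_network edge weights match a double-loop oracle on random records", {
  set.seed(505)
  pool <- c("J45", "I10", "E66.0", "N39.0", "J96.0", "D53.9", "Z72.0", "K21.9")
  for (rep in 1:10) {
    sets <- lapply(1:25, function(i) sample(pool, sample(1:5, 1)))
    g <- aggregate_network(make_records(sets))
    el <- igraph::as_edgelist(g$graph)
    wts <- igraph::E(g$graph)$weight
    for (k in seq_len(nrow(el))) {
      cnt <- sum(vapply(sets, function(s) all(el[k, ] %in% s), logical(1)))
      expect_equal(wts[k], cnt)
    }
    # and no co-occurring pair is missing
    npairs <- sum(vapply(sets, function(s) choose(length(unique(s)), 2), numeric(1)))
    expect_equal(sum(wts), npairs)
  }
})

test_that("aggregate_network splits by age group", {
  recs <- make_records(list(c("J45", "I10"), c("J45", "E66.0")),
                       birth = c("1990-01-01", "1950-01-01"), adm = "2018-06-01")
  young <- aggregate_network(recs, "18-49")
  old <- aggregate_network(recs, "60-69")
  expect_setequal(igraph::V(young$graph)$name, c("I10", "J45"))
  expect_setequal(igraph::V(old$graph)$name, c("E66.0", "J45"))
})

test_that("betweenness matches hand-worked small graphs", {
  path3 <- code_graph(data.frame(a = c("A", "B"), b = c("B", "C")))
  bc <- betweenness_centrality(path3)
  expect_equal(bc$raw_bc[match(c("A", "B", "C"), bc$code)], c(0, 1, 0))
  expect_equal(bc$norm_bc[match(c("A", "B", "C"), bc$code)], c(0, 1, 0))

  star <- code_graph(data.frame(a = "C", b = c("L1", "L2", "L3")))
  bs <- betweenness_centrality(star)
  expect_equal(bs$norm_bc[bs$code == "C"], 1)
  expect_equal(sum(bs$norm_bc), 1)

  cyc <- code_graph(data.frame(a = c("A", "B", "C", "D"), b = c("B", "C", "D", "A")))
  by <- betweenness_centrality(cyc)
  expect_equal(by$raw_bc, rep(0.5, 4))
  expect_equal(by$norm_bc, rep(1, 4))

  p4 <- code_graph(data.frame(a = c("A", "B", "C"), b = c("B", "C", "D")))
  b4 <- betweenness_centrality(p4)
  expect_equal(b4$raw_bc[match(c("B", "C"), b4$code)], c(2, 2))
  expect_equal(influence_ratio(b4, "B", "C"), 1)

  empty <- aggregate_network(make_records(list()))
  expect_equal(nrow(betweenness_centrality(empty)), 0L)
})

test_that("betweenness equals exhaustive path enumeration on 100 random graphs", {
  set.seed(606)
  for (i in 1:100) {
    n <- sample(4:8, 1)
    adj <- random_adj(n, p = runif(1, 0.25, 0.6)) # disconnected cases included
    g <- graph_from_adj(adj)
    got <- betweenness_centrality(g)
    want <- brute_betweenness(adj)
    expect_equal(setNames(got$raw_bc, got$code)[names(want)], want, tolerance = 1e-9)
    if (max(want) > 0) expect_equal(max(got$norm_bc), 1)
  }
})

test_that("normalized betweenness is invariant under relabeling (isomorphism)", {
  set.seed(707)
  adj <- random_adj(7, 0.45)
  g1 <- graph_from_adj(adj)
  perm <- sample(7)
  adj2 <- adj[perm, perm]
  rownames(adj2) <- colnames(adj2) <- paste0("X", rownames(adj)[perm])
  g2 <- graph_from_adj(adj2)
  b1 <- betweenness_centrality(g1); b2 <- betweenness_centrality(g2)
  m1 <- setNames(b1$norm_bc, b1$code)
  m2 <- setNames(b2$norm_bc, sub("^X", "", b2$code))
  expect_equal(m2[names(m1)], m1, tolerance = 1e-12)
})

test_that("combinatorial normalization and weighted distances are available", {
  p3 <- code_graph(data.frame(a = c("A", "B"), b = c("B", "C")))
  comb <- betweenness_centrality(p3, normalization = "combinatorial")
  expect_equal(comb$norm_bc[comb$code == "B"], 1) # 1 / ((3-1)(3-2)/2)
  # heavy edges are short: the detour through D wins over the direct light edge
  wg <- code_graph(data.frame(a = c("A", "A", "D"), b = c("B", "D", "B"),
                              weight = c(1, 10, 10)))
  ww <- betweenness_centrality(wg, weighted = TRUE)
  expect_equal(ww$raw_bc[ww$code == "D"], 1)
  uw <- betweenness_centrality(wg, weighted = FALSE)
  expect_equal(uw$raw_bc[uw$code == "D"], 0)
})

test_that("community detection splits a two-clique bridge like exhaustive bipartition", {
  nodes <- c(paste0("A", 1:4), paste0("B", 1:4))
  adj <- matrix(0, 8, 8, dimnames = list(nodes, nodes))
  for (i in 1:4) for (j in 1:4) if (i != j) {
    adj[i, j] <- 1; adj[i + 4, j + 4] <- 1
  }
  adj["A1", "B1"] <- adj["B1", "A1"] <- 1
  g <- graph_from_adj(adj)
  part <- detect_communities(g, seed = 1L)
  # oracle: best weighted modularity over all 2^8 colorings
  best_q <- -Inf; best_split <- NULL
  for (mask in 0:255) {
    memb <- as.integer(intToBits(mask))[1:8]
    q <- brute_modularity(adj, memb)
    if (q > best_q) { best_q <- q; best_split <- memb }
  }
  expect_equal(sort(unname(part$sizes)), c(4L, 4L))
  sig <- function(membership, names) {
    sort(vapply(split(names, membership), function(v) paste(sort(v), collapse = ","),
                character(1)))
  }
  expect_equal(unname(sig(part$assignment, names(part$assignment))),
               unname(sig(best_split, nodes)))
  expect_equal(part$modularity, best_q, tolerance = 1e-9)

  # a single clique stays one community
  k5 <- igraph::as_adjacency_matrix(igraph::make_full_graph(5), sparse = FALSE)
  rownames(k5) <- colnames(k5) <- paste0("K", 1:5)
  expect_equal(length(detect_communities(graph_from_adj(k5))$sizes), 1L)
  expect_error(detect_communities(g, resolution = 0), class = "asthmanet_validation_error")
})

test_that("community partition beats singletons and is deterministic", {
  set.seed(808)
  adj <- random_adj(8, 0.5)
  g <- graph_from_adj(adj)
  p1 <- detect_communities(g, seed = 9L)
  p2 <- detect_communities(g, seed = 9L)
  expect_identical(p1, p2)
  singletons <- brute_modularity(adj, seq_len(8))
  expect_gte(p1$modularity, singletons)
})

test_that("relative_influence implements the anchored category ratio", {
  ct <- structure(data.frame(code = c("J45", "I10", "I25.9", "E66.0"),
                             raw_bc = c(10, 4, 1, 0),
                             norm_bc = c(1.0, 0.4, 0.1, 0)),
                  class = c("centrality_table", "data.frame"))
  cats <- list(asthma = "J45", cardio = c("I10", "I25.9"),
               obesity = c("E66.0", "E78.5"))
  rep <- relative_influence(ct, cats)
  expect_equal(unname(rep$per_category["asthma"]), 100)
  expect_equal(unname(rep$per_category["cardio"]), 50)
  expect_equal(unname(rep$per_category["obesity"]), 0) # absent members contribute 0
  expect_equal(unname(rep$per_node$cardio), c(0.4, 0.1))

  # influence can exceed 100 when a category out-brokers the anchor
  ct2 <- ct; ct2$norm_bc <- c(0.5, 1, 0.9, 0)
  rep2 <- relative_influence(ct2, cats)
  expect_gt(rep2$per_category[["cardio"]], 100)

  # anchor absent or zero is an error
  ct3 <- ct; ct3$norm_bc[1] <- 0
  expect_error(relative_influence(ct3, cats), class = "asthmanet_anchor_error")
  expect_error(relative_influence(ct[-1, ], cats), class = "asthmanet_anchor_error")
})

test_that("relative_influence is scale-free in the raw centralities", {
  admissions <- list(c("J45", "I10", "E66.0"), c("J45", "I10"), c("J45", "N39.0"),
                     c("I10", "N39.0", "J45"), c("J45", "E66.0", "K21.9"))
  g <- aggregate_network(make_records(admissions))
  bc <- betweenness_centrality(g)
  cats <- list(asthma = "J45", hypertension = "I10",
               other = c("E66.0", "N39.0", "K21.9"))
  base <- relative_influence(bc, cats)
  for (k in c(0.01, 3, 1000)) {
    scaled <- bc
    scaled$raw_bc <- bc$raw_bc * k
    scaled$norm_bc <- if (max(scaled$raw_bc) > 0) scaled$raw_bc / max(scaled$raw_bc) else scaled$raw_bc
    expect_equal(relative_influence(scaled, cats)$per_category, base$per_category,
                 tolerance = 1e-12)
  }
})

test_that("influence_ratio handles absent numerators and degenerate denominators", {
  p4 <- code_graph(data.frame(a = c("A", "B", "C"), b = c("B", "C", "D")))
  bc <- betweenness_centrality(p4)
  expect_equal(influence_ratio(bc, "Z", "B"), 0)
  expect_error(influence_ratio(bc, "B", "A"),
               class = "asthmanet_degenerate_ratio_error")
  expect_error(influence_ratio(bc, "B", "Z"),
               class = "asthmanet_degenerate_ratio_error")
})

test_that("network_summary reports counts, density and the asthma community", {
  eg <- aggregate_network(make_records(list()))
  es <- network_summary(eg)
  expect_equal(es$nodes, 0L); expect_equal(es$edges, 0L); expect_equal(es$density, 0)

  tri <- aggregate_network(make_records(list(c("J45", "I10", "E66.0"))))
  part <- detect_communities(tri)
  ts <- network_summary(tri, part)
  expect_equal(ts$nodes, 3L); expect_equal(ts$edges, 3L); expect_equal(ts$density, 1)
  expect_equal(ts$n_communities, 1L)
  expect_equal(ts$j45_community, 1L)

  # two 4-cliques bridged, J45 planted in the larger labelled set
  edges <- expand.grid(a = c("J45", "I10", "I25.9"), b = c("J45", "I10", "I25.9"),
                       stringsAsFactors = FALSE)
  edges <- edges[edges$a < edges$b, ]
  edges <- rbind(edges,
                 data.frame(a = c("N39.0", "N39.0", "N40"), b = c("N40", "R31", "R31")),
                 data.frame(a = "J45", b = "N39.0"))
  g <- code_graph(edges)
  p <- detect_communities(g)
  s <- network_summary(g, p, betweenness_centrality(g))
  expect_equal(sort(s$top_community_sizes), c(3L, 3L))
  expect_equal(s$j45_community, unname(p$assignment[["J45"]]))
  expect_true(is.numeric(s$j45_norm_bc))
})

test_that("graph exports carry weights, communities and centralities", {
  recs <- make_records(list(c("J45", "I10", "E66.0"), c("J45", "I10")))
  g <- aggregate_network(recs)
  bc <- betweenness_centrality(g)
  part <- detect_communities(g)
  dir <- withr::local_tempdir()
  files <- export_network(g, part, bc, default_category_map(),
                          graphml = file.path(dir, "g.graphml"),
                          gexf = file.path(dir, "g.gexf"),
                          nodes_csv = file.path(dir, "nodes.csv"))
  g_back <- igraph::read_graph(file.path(dir, "g.graphml"), format = "graphml")
  expect_setequal(igraph::V(g_back)$name, c("J45", "I10", "E66.0"))
  expect_equal(sort(igraph::E(g_back)$weight), c(1, 1, 2))
  expect_true(all(igraph::V(g_back)$community %in% part$assignment))
  gexf <- readLines(file.path(dir, "g.gexf"))
  expect_true(any(grepl("defaultedgetype=\"undirected\"", gexf)))
  expect_true(any(grepl("weight=\"2\"", gexf)))
  nodes <- read.csv(file.path(dir, "nodes.csv"))
  expect_equal(nodes$category[nodes$code == "J45"], "asthma")
  expect_equal(nodes$category[nodes$code == "E66.0"], "obesity")
})

test_that("the packaged category map is disjoint and anchored", {
  cm <- default_category_map()
  expect_true("asthma" %in% names(cm))
  expect_identical(cm$asthma, "J45")
  all_codes <- unname(unlist(cm))
  expect_equal(anyDuplicated(all_codes), 0L)
  expect_identical(all_codes, unname(normalize_code(all_codes)))
})
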