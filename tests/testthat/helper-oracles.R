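# Independent brute-force oracles and small fixture builders used across tests.

# --- admission-record builder -------------------------------------------
make_records <- function(codes, sex = "F", birth = "1960-06-15", adm = "2018-03-10",
                         los = 3, in_county = TRUE, consent = TRUE, id = NULL) {
  n <- length(codes)
  df <- data.frame(
    patient_id = if (is.null(id)) sprintf("P%03d", seq_len(n)) else id,
    birth_date = as.Date(rep_len(birth, n)),
    sex = rep_len(sex, n),
    admission_date = as.Date(rep_len(adm, n)),
    los_days = rep_len(los, n),
    in_county = rep_len(in_county, n),
    consent = rep_len(consent, n),
    stringsAsFactors = FALSE
  )
  df$codes <- codes
  df
}

# --- betweenness oracle: exhaustive shortest-path enumeration -----------
# adj: symmetric logical/0-1 matrix with named dimnames
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  bc <- setNames(rep(0, n), rownames(adj))
  if (n < 3L) return(bc)
  all_paths <- function(s, t) {
    # enumerate all simple paths s..t by DFS
    paths <- list()
    walk <- function(v, seen) {
      if (v == t) { paths[[length(paths) + 1L]] <<- seen; return(invisible()) }
      for (w in which(adj[v, ] > 0)) if (!w %in% seen) walk(w, c(seen, w))
    }
    walk(s, s)
    paths
  }
  for (s in 1:(n - 1L)) for (t in (s + 1L):n) {
    paths <- all_paths(s, t)
    if (!length(paths)) next
    lens <- vapply(paths, length, integer(1))
    sp <- paths[lens == min(lens)]
    for (p in sp) {
      inner <- setdiff(p, c(s, t))
      if (length(inner)) bc[inner] <- bc[inner] + 1 / length(sp)
    }
  }
  bc
}

graph_from_adj <- function(adj, weight = 1) {
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  edges <- data.frame(a = rownames(adj)[idx[, 1]], b = rownames(adj)[idx[, 2]],
                      weight = rep_len(weight, nrow(idx)), stringsAsFactors = FALSE)
  code_graph(edges, nodes = rownames(adj))
}

random_adj <- function(n, p = 0.4) {
  nm <- sprintf("N%02d", seq_len(n))
  adj <- matrix(0L, n, n, dimnames = list(nm, nm))
  up <- which(upper.tri(adj))
  adj[up] <- as.integer(runif(length(up)) < p)
  adj + t(adj)
}

# --- Mann-Whitney U oracle: O(n^2) pair counting ------------------------
brute_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# --- weighted modularity oracle (independent formula) -------------------
brute_modularity <- function(adj, membership) {
  m2 <- sum(adj) # 2m for a symmetric matrix
  deg <- rowSums(adj)
  q <- 0
  for (i in seq_len(nrow(adj))) for (j in seq_len(ncol(adj))) {
    if (membership[i] == membership[j]) q <- q + adj[i, j] - deg[i] * deg[j] / m2
  }
  unname(q / m2)
}

# --- adjusted Rand index (mclust) ---------------------------------------
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# strong-signal generator config with planted blocks in one age group
strong_block_config <- function(n = 1500, seed = 1L,
                                p_active = 0.3, p_given = 0.7, p_bg = 0.01) {
  blocks <- lapply(1:3, function(k) {
    list(label = paste0("block", k),
         codes = sprintf("%s%02d.%d", LETTERS[k + 3], 10 + 1:7, k),
         p_active = p_active, p_code_given_active = p_given,
         p_code_background = p_bg)
  })
  generator_config(
    n_admissions = n, p_female = 0.5,
    age_mixture = list(list(weight = 1, mean = 60, sd = 4)),
    year_weights = setNames(rep(1 / 10, 10), 2013:2022),
    repeat_admission_rate = 0,
    blocks_by_age_group = list("50-59" = blocks, "60-69" = blocks),
    seed = seed
  )
}

planted_block_labels <- function(config) {
  blocks <- config$blocks_by_age_group[[1]]
  lab <- unlist(lapply(seq_along(blocks), function(k) {
    setNames(rep(k, length(blocks[[k]]$codes)), normalize_code(blocks[[k]]$codes))
  }))
  lab
}
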