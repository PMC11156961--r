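# Independent oracles and fixture builders used across the suite.

# Build a small association table from vectors (defaults give valid rows).
# Fixture p-values are often set freely for filter tests, so the
# p-vs-z consistency warning (tested on its own elsewhere) is suppressed.
toy_assoc <- function(variant_id, beta, se, pvalue = NULL, eaf = 0.3,
                      chrom = "1", pos = NULL, ea = "A", oa = "G",
                      n = 10000) {
  m <- length(variant_id)
  pvalue <- pvalue %||% pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  suppressWarnings(as_assoc_table(data.frame(
    variant_id = variant_id, chrom = chrom,
    pos = pos %||% seq(1e6, 1e6 + m - 1),
    effect_allele = rep(ea, length.out = m),
    other_allele = rep(oa, length.out = m),
    eaf = rep(eaf, length.out = m), beta = beta, se = se,
    pvalue = pvalue, n = n, stringsAsFactors = FALSE
  )))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Upper-tail hypergeometric by direct summation of binomial coefficients —
# independent of stats::phyper.
oracle_hyper_tail <- function(k, N, K, n) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Brute-force BH step-up: find the largest j with p_(j) <= j*alpha/m by
# scanning thresholds, then report adjusted values by direct definition
# adj_i = min over j >= rank(i) of m * p_(j) / j.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (r in seq_len(m)) {
    adj[r] <- min(1, min(m * ps[r:m] / (r:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Literal voterank reference: plain lists and loops, no matrix algebra.
oracle_voterank <- function(edges, nodes, max_nodes = length(nodes)) {
  nbrs <- setNames(lapply(nodes, function(v) character(0)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    nbrs[[a]] <- union(nbrs[[a]], b)
    nbrs[[b]] <- union(nbrs[[b]], a)
  }
  k_mean <- mean(lengths(nbrs))
  decay <- if (k_mean > 0) 1 / k_mean else 0
  ability <- setNames(rep(1, length(nodes)), nodes)
  alive <- setNames(rep(TRUE, length(nodes)), nodes)
  elected <- character(0)
  while (length(elected) < max_nodes) {
    best <- NA; best_score <- -Inf
    for (v in sort(nodes)) {
      if (!alive[[v]]) next
      s <- sum(ability[nbrs[[v]]])
      if (s > best_score) { best <- v; best_score <- s }
    }
    if (is.na(best) || best_score <= 0) break
    elected <- c(elected, best)
    alive[[best]] <- FALSE
    ability[[best]] <- 0
    for (u in nbrs[[best]]) ability[[u]] <- max(0, ability[[u]] - decay)
  }
  elected
}

# Exhaustive maximal-clique enumeration over all vertex subsets (n <= 12).
oracle_cliques <- function(adj) {
  nodes <- rownames(adj)
  n <- length(nodes)
  is_clique <- function(idx) {
    if (length(idx) < 2) return(length(idx) == 1)
    all(adj[idx, idx][upper.tri(adj[idx, idx])] == 1)
  }
  cliques <- list()
  for (size in n:2) {
    for (cmb in utils::combn(n, size, simplify = FALSE)) {
      if (!is_clique(cmb)) next
      maximal <- TRUE
      for (v in setdiff(seq_len(n), cmb)) {
        if (all(adj[v, cmb] == 1)) { maximal <- FALSE; break }
      }
      if (maximal) cliques[[length(cliques) + 1L]] <- sort(nodes[cmb])
    }
  }
  key <- vapply(cliques, paste, "", collapse = "|")
  cliques[order(-lengths(cliques), key)]
}

# Greedy independent-set-by-p clumping oracle: inclusion test formulation
# (include the next-best p variant iff r2 < r2_max against all included).
oracle_clump <- function(ids, p, z, r2, r2_max) {
  ord <- order(p, -z, ids)
  chosen <- integer(0)
  for (i in ord) {
    if (all(r2[i, chosen] < r2_max)) chosen <- c(chosen, i)
  }
  ids[chosen]
}

# Random simple graph on `n` named nodes with edge probability p.
random_graph <- function(n, p, seed) {
  set.seed(seed)
  nodes <- LETTERS[seq_len(n)]
  adj <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
  }
  adj
}

graph_from_adj <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

adj_edges <- function(adj) {
  idx <- which(adj == 1 & upper.tri(adj), arr.ind = TRUE)
  cbind(rownames(adj)[idx[, 1]], colnames(adj)[idx[, 2]])
}
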