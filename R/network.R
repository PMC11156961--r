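#' Build a simple undirected PPI graph
#'
#' @param edges two-column matrix/data.frame of interacting symbols, or an
#'   igraph object (returned simplified).
#' @return undirected simple [igraph::graph] with normalized symbol names.
#' @export
ppi_graph <- function(edges) {
  if (inherits(edges, "igraph")) {
    g <- igraph::as_undirected(edges, mode = "collapse")
  } else {
    el <- as.matrix(edges[, 1:2, drop = FALSE])
    if (ncol(el) == 1L) el <- t(el)
    el[, 1] <- norm_symbol(el[, 1])
    el[, 2] <- norm_symbol(el[, 2])
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
  }
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Extract the first-order subnetwork around seed proteins
#'
#' Returns the subgraph induced on the seeds present in the PPI plus
#' (at `order = 1`) their direct interactors: every PPI edge between included
#' nodes is retained, including edges among neighbors. Seeds are flagged in
#' the vertex attribute `seed`; seeds absent from the PPI are dropped with a
#' warning and isolated seeds are retained as singletons.
#'
#' @param ppi [igraph::graph] from [ppi_graph()] or [read_edge_list()].
#' @param seeds character vector of seed symbols.
#' @param order 0 = seeds only; 1 = seeds plus first-order neighbors.
#' @return induced subgraph with logical vertex attribute `seed`.
#' @export
extract_seed_subnetwork <- function(ppi, seeds, order = 1L) {
  if (!length(seeds)) stopf("seeds must be non-empty")
  seeds <- unique(norm_symbol(seeds))
  present <- seeds[seeds %in% igraph::V(ppi)$name]
  missing <- setdiff(seeds, present)
  if (!length(present)) {
    stopf("no seed found in the PPI; missing: %s", paste(missing, collapse = ", "))
  }
  if (length(missing)) {
    warnf("seed(s) absent from the PPI: %s", paste(missing, collapse = ", "))
  }
  nodes <- present
  if (order >= 1L) {
    nb <- unique(unlist(lapply(igraph::adjacent_vertices(ppi, present),
                               igraph::as_ids)))
    nodes <- union(present, nb)
  }
  sub <- igraph::induced_subgraph(ppi, nodes)
  igraph::V(sub)$seed <- igraph::V(sub)$name %in% present
  sub
}

#' Node degrees
#'
#' @param net igraph object.
#' @return named integer vector of raw degrees, sorted by decreasing degree
#'   with ties broken lexicographically.
#' @export
degree_centrality <- function(net) {
  d <- igraph::degree(net)
  if (!length(d)) return(setNames(integer(0), character(0)))
  d[order(-d, names(d))]
}

#' Voterank influential-node ranking
#'
#' Iterative election: every node starts with voting ability 1; a node's
#' score is the sum of its neighbors' abilities. The maximum-score node is
#' elected (ties broken lexicographically), its ability drops to 0 and it is
#' excluded from future elections, and each of its neighbors loses 1/<k> of
#' ability (floored at 0), where <k> is the mean degree of the input graph.
#' The election stops when the best available score is <= 0 or `max_nodes`
#' have been elected.
#'
#' @param net igraph object.
#' @param max_nodes optional cap on the number of elected nodes.
#' @return character vector of elected node names, in election order.
#' @export
voterank <- function(net, max_nodes = NULL) {
  nodes <- igraph::V(net)$name %||% as.character(seq_len(igraph::vcount(net)))
  n <- length(nodes)
  if (!n) return(character(0))
  adj <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  dimnames(adj) <- list(nodes, nodes)
  mean_deg <- mean(igraph::degree(net))
  decay <- if (mean_deg > 0) 1 / mean_deg else 0
  ability <- setNames(rep(1, n), nodes)
  elected <- character(0)
  electable <- setNames(rep(TRUE, n), nodes)
  max_nodes <- max_nodes %||% n
  ord <- order(nodes)   # lexicographic tie-break
  while (length(elected) < max_nodes) {
    scores <- as.vector(adj %*% ability)
    names(scores) <- nodes
    scores[!electable] <- -Inf
    best <- nodes[ord][which.max(scores[ord])]
    if (scores[best] <= 0) break
    elected <- c(elected, best)
    electable[best] <- FALSE
    ability[best] <- 0
    nb <- nodes[adj[best, ] > 0]
    ability[nb] <- pmax(0, ability[nb] - decay)
  }
  elected
}

#' Maximal cliques
#'
#' All maximal cliques (Bron-Kerbosch with pivoting, via igraph), returned in
#' a canonical order for determinism: members sorted within each clique,
#' cliques ordered by decreasing size then lexicographically.
#'
#' @param net igraph object.
#' @param min_size smallest clique size to report (default 2).
#' @return list of character vectors.
#' @export
maximal_cliques <- function(net, min_size = 2L) {
  cl <- igraph::max_cliques(net, min = min_size)
  cl <- lapply(cl, function(v) sort(igraph::V(net)$name[v]))
  if (!length(cl)) return(list())
  key <- vapply(cl, paste, "", collapse = "|")
  cl[order(-lengths(cl), key)]
}

#' Walktrap community detection
#'
#' Pons-Latapy random-walk community detection (igraph implementation) with
#' `t`-step walks; the merge sequence is cut at maximum Newman-Girvan
#' modularity. Connected components are clustered independently and module
#' ids renumbered contiguously from 1, largest module first.
#'
#' @param net igraph object.
#' @param t random-walk length (default 4).
#' @return list (`module_partition` class): `membership` (named integer
#'   vector), `n_modules`, `modularity`.
#' @export
walktrap_modules <- function(net, t = 4L) {
  nodes <- igraph::V(net)$name
  comp <- igraph::components(net)
  membership <- setNames(integer(length(nodes)), nodes)
  next_id <- 0L
  for (ci in seq_len(comp$no)) {
    vs <- nodes[comp$membership == ci]
    sub <- igraph::induced_subgraph(net, vs)
    if (igraph::vcount(sub) == 1L || igraph::ecount(sub) == 0L) {
      membership[vs] <- next_id + 1L
      next_id <- next_id + 1L
    } else {
      wt <- igraph::cluster_walktrap(sub, steps = t)
      m <- igraph::membership(wt)
      membership[vs] <- next_id + as.integer(m)
      next_id <- next_id + max(as.integer(m))
    }
  }
  # renumber: contiguous ids from 1, largest module first, ties by member name
  sizes <- table(membership)
  first_member <- vapply(names(sizes), function(id) {
    min(names(membership)[membership == as.integer(id)])
  }, character(1))
  new_order <- names(sizes)[order(-as.vector(sizes), first_member)]
  remap <- setNames(seq_along(new_order), new_order)
  membership <- setNames(as.integer(remap[as.character(membership)]), nodes)
  q <- igraph::modularity(net, membership)
  structure(list(membership = membership,
                 n_modules = max(membership),
                 modularity = q),
            class = "module_partition")
}

#' Annotate network modules by over-representation
#'
#' For each module, runs [ora_batch()] over the supplied gene sets and
#' reports the minimum-p set (ties broken by set name).
#'
#' @param partition `module_partition` from [walktrap_modules()].
#' @param sets named list of gene sets.
#' @param background explicit universe.
#' @return data.frame with one row per module: `module`, `size`, plus the
#'   top [hypergeom_enrich()] row.
#' @export
annotate_modules <- function(partition, sets, background) {
  mods <- sort(unique(partition$membership))
  rows <- lapply(mods, function(m) {
    members <- names(partition$membership)[partition$membership == m]
    res <- suppressWarnings(ora_batch(members, sets, background))
    top <- res[1, , drop = FALSE]
    cbind(data.frame(module = m, size = length(members)), top)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
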