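test_that("seed subnetwork extraction returns the induced first-order graph", {
  # star: center S, leaves L1..L4
  star <- ppi_graph(cbind(rep("S", 4), paste0("L", 1:4)))
  sub <- extract_seed_subnetwork(star, "S")
  expect_equal(igraph::vcount(sub), 5)
  expect_equal(igraph::ecount(sub), 4)
  expect_equal(sum(igraph::V(sub)$seed), 1)

  # isolated seed is kept as a singleton
  g <- igraph::add_vertices(star, 1, name = "ALONE")
  sub2 <- extract_seed_subnetwork(g, c("ALONE"))
  expect_equal(igraph::V(sub2)$name, "ALONE")
  expect_equal(igraph::ecount(sub2), 0)

  # all seeds missing -> error naming them
  expect_error(extract_seed_subnetwork(star, c("NOPE")), "NOPE")
  # some seeds missing -> warning
  expect_warning(extract_seed_subnetwork(star, c("S", "NOPE")), "NOPE")
})

test_that("two seeds sharing a neighbor yield one induced copy with neighbor edges", {
  # hand-constructed 5-node case: seeds S1, S2 share neighbor N; M is a
  # neighbor of S1 only; the N-M edge exists in the ppi; X is second order
  edges <- rbind(c("S1", "N"), c("S2", "N"), c("S1", "M"), c("N", "M"),
                 c("M", "X"))
  ppi <- ppi_graph(edges)
  sub <- extract_seed_subnetwork(ppi, c("S1", "S2"))
  expect_setequal(igraph::V(sub)$name, c("S1", "S2", "N", "M"))
  # induced: the N-M edge between two included neighbors is retained; X
  # (second order) is not reached
  expect_equal(igraph::ecount(sub), 4)
  expect_true(igraph::are_adjacent(sub, "N", "M"))

  # induced-subgraph property on a random graph: every ppi edge between
  # included nodes appears
  adj <- random_graph(9, 0.35, seed = 4)
  g <- graph_from_adj(adj)
  s <- extract_seed_subnetwork(g, c("A", "B"))
  nodes <- igraph::V(s)$name
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i < j && adj[nodes[i], nodes[j]] == 1) {
      expect_true(igraph::are_adjacent(s, nodes[i], nodes[j]))
    }
  }
})

test_that("degree_centrality returns raw degrees with deterministic ordering", {
  path <- ppi_graph(cbind(c("A", "B"), c("B", "C")))
  d <- degree_centrality(path)
  expect_equal(d, c(B = 2, A = 1, C = 1))
  expect_length(degree_centrality(igraph::make_empty_graph(0, directed = FALSE)), 0)
  k4 <- graph_from_adj(matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4])) - diag(4))
  expect_true(all(degree_centrality(k4) == 3))
})

test_that("voterank elects hubs first and honors the hand-traced path ordering", {
  star <- ppi_graph(cbind(rep("C0", 4), paste0("L", 1:4)))
  expect_equal(voterank(star)[1], "C0")

  # path A-B-C-D-E: trace gives B then D, then all scores hit 0
  path5 <- ppi_graph(cbind(c("A", "B", "C", "D"), c("B", "C", "D", "E")))
  expect_equal(voterank(path5), c("B", "D"))

  # edgeless graph: no elections
  lonely <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(lonely)$name <- c("A", "B", "C")
  expect_equal(voterank(lonely), character(0))

  # max_nodes cap
  expect_equal(voterank(path5, max_nodes = 1), "B")
})

test_that("voterank matches the literal reference implementation on random graphs", {
  for (seed in 1:30) {
    n <- sample(4:8, 1)
    adj <- random_graph(n, 0.4, seed = seed + 100)
    g <- graph_from_adj(adj)
    got <- voterank(g)
    want <- oracle_voterank(adj_edges(adj), rownames(adj))
    expect_equal(got, want)
    expect_false(any(duplicated(got)))
  }
})

test_that("maximal cliques match enumeration oracles", {
  tri <- ppi_graph(cbind(c("A", "B", "C"), c("B", "C", "A")))
  expect_equal(maximal_cliques(tri), list(c("A", "B", "C")))

  # K4 minus one edge -> two triangles
  adj <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4])) - diag(4)
  adj["A", "B"] <- adj["B", "A"] <- 0
  cl <- maximal_cliques(graph_from_adj(adj))
  expect_equal(cl, list(c("A", "C", "D"), c("B", "C", "D")))

  edge <- ppi_graph(cbind("A", "B"))
  expect_equal(maximal_cliques(edge), list(c("A", "B")))

  for (seed in 1:15) {
    n <- sample(5:8, 1)
    adj <- random_graph(n, 0.5, seed = seed + 300)
    got <- maximal_cliques(graph_from_adj(adj))
    want <- oracle_cliques(adj)
    want <- want[lengths(want) >= 2]
    expect_equal(got, want)
  }
})

test_that("walktrap recovers planted structure and handles degenerate graphs", {
  # two K5 cliques joined by a single edge -> exactly the two cliques
  nodes <- c(paste0("A", 1:5), paste0("B", 1:5))
  adj <- matrix(0L, 10, 10, dimnames = list(nodes, nodes))
  adj[1:5, 1:5] <- 1L; adj[6:10, 6:10] <- 1L
  diag(adj) <- 0L
  adj["A1", "B1"] <- adj["B1", "A1"] <- 1L
  part <- walktrap_modules(graph_from_adj(adj))
  expect_equal(part$n_modules, 2)
  expect_equal(length(unique(part$membership[paste0("A", 1:5)])), 1)
  expect_equal(length(unique(part$membership[paste0("B", 1:5)])), 1)
  expect_gt(part$modularity, 0.3)

  # complete graph -> one module
  k5 <- graph_from_adj(matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5])) - diag(5))
  expect_equal(walktrap_modules(k5)$n_modules, 1)

  # two disconnected triangles -> two modules
  tri2 <- ppi_graph(rbind(c("A", "B"), c("B", "C"), c("C", "A"),
                          c("X", "Y"), c("Y", "Z"), c("Z", "X")))
  p2 <- walktrap_modules(tri2)
  expect_equal(p2$n_modules, 2)
  # partition properties: every node assigned once, ids contiguous from 1
  expect_equal(sort(unique(p2$membership)), 1:2)
  expect_equal(length(p2$membership), 6)
})

test_that("walktrap modularity beats the trivial partition on planted graphs", {
  sim <- sim_ppi(planted_comms = list(sizes = c(20, 20, 20), p_in = 0.35,
                                      p_out = 0.02), seed = 8)
  part <- walktrap_modules(sim$graph)
  trivial <- igraph::modularity(sim$graph,
                                rep(1, igraph::vcount(sim$graph)))
  expect_gt(part$modularity, trivial)
  expect_equal(sum(table(part$membership)), igraph::vcount(sim$graph))
})

test_that("annotate_modules reports the best-matching set per module", {
  tri2 <- ppi_graph(rbind(c("A", "B"), c("B", "C"), c("C", "A"),
                          c("X", "Y"), c("Y", "Z"), c("Z", "X")))
  part <- walktrap_modules(tri2)
  bg <- c("A", "B", "C", "X", "Y", "Z", paste0("PAD", 1:24))
  sets <- list(first = c("A", "B", "C"), second = c("X", "Y", "Z"),
               none = paste0("PAD", 1:10))
  ann <- annotate_modules(part, sets, bg)
  expect_equal(nrow(ann), 2)
  hit_sets <- ann$set_name[order(ann$module)]
  expect_setequal(hit_sets, c("first", "second"))
  # module disjoint from all sets -> p = 1 everywhere
  lonely_part <- structure(list(membership = c(P1 = 1L, P2 = 1L)),
                           class = "module_partition")
  ann2 <- annotate_modules(lonely_part, sets,
                           c("P1", "P2", unlist(sets)))
  expect_equal(ann2$pvalue, 1)
})
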