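test_that("cpc_from_range applies the inclusive distance rule", {
  co <- cbind(c(0, 500, 1300), 0)
  rownames(co) <- c("c1", "c2", "c3")
  g <- cpc_from_range(co, 745, "comp_autocorr")
  el <- igraph::as_edgelist(g)
  expect_equal(nrow(el), 1)
  expect_setequal(as.vector(el), c("c1", "c2"))
  expect_equal(igraph::ecount(cpc_from_range(co, 0, "comp_autocorr")), 0)
  gc <- cpc_from_range(co, 1300, "comp_autocorr")
  expect_equal(graph_density(gc), 1)
  # boundary inclusive: exactly 500 keeps the edge
  expect_equal(igraph::ecount(cpc_from_range(co, 500, "comp_autocorr")), 1)
  expect_equal(igraph::ecount(cpc_from_range(co, NA, "comp_autocorr")), 0)
})

test_that("cpc_from_rules is a conjunction over favored regions", {
  caves <- toy_caves()
  pt <- build_pair_table(caves)
  # empty rule list: complete graph
  g0 <- cpc_from_rules(pt, list(), "comp_breakpoint")
  expect_equal(graph_density(g0), 1)
  # |delta scarp| <= 3.5 with pair at exactly 3.5 keeps the edge
  pt2 <- pt
  pt2$scarp_height_m <- c(3.5, 10, 8)
  g1 <- cpc_from_rules(pt2, list(list(predictor = "scarp_height_m",
                                      threshold = 3.5)), "comp_breakpoint")
  expect_equal(igraph::ecount(g1), 1)
  # conjunction: a pair violating one rule is excluded
  rules <- list(list(predictor = "scarp_height_m", threshold = 8),
                list(predictor = "granulometry", threshold = 1))
  g2 <- cpc_from_rules(pt, rules, "phy_breakpoint")
  # pairs: AB (d=2, steps 0 -> edge), AC (10, 1 -> no), BC (8, 1 -> edge)
  expect_equal(igraph::ecount(g2), 2)
  # categorical favored-set rule
  g3 <- cpc_from_rules(pt, list(list(predictor = "hydric_features",
                                     favored = "perennial|perennial")),
                       "comp_breakpoint")
  el <- igraph::as_edgelist(g3)
  expect_equal(nrow(el), 1)
  expect_setequal(as.vector(el), c("B", "C"))
  expect_error(cpc_from_rules(pt, list(list(predictor = "nope", threshold = 1))),
               "missing from pair table")
})

test_that("combine_and_weight validates and weights edges", {
  ids <- c("A", "B", "C", "D")
  gs <- list(
    comp_autocorr = mk_cpc(ids, list(c("A", "B"), c("A", "C"), c("C", "D")),
                           "comp_autocorr"),
    comp_breakpoint = mk_cpc(ids, list(c("A", "B"), c("B", "C")),
                             "comp_breakpoint"),
    phy_autocorr = mk_cpc(ids, list(c("A", "B"), c("A", "C")), "phy_autocorr"),
    phy_breakpoint = mk_cpc(ids, list(c("A", "B")), "phy_breakpoint"))
  w <- combine_and_weight(gs)
  get_w <- function(a, b) {
    eid <- igraph::get_edge_ids(w, c(a, b))
    if (eid == 0) NA_integer_ else igraph::E(w)$weight[eid]
  }
  expect_equal(get_w("A", "B"), 4L)   # in all four graphs
  expect_equal(get_w("A", "C"), 2L)   # comp_autocorr + phy_autocorr
  expect_true(is.na(get_w("C", "D"))) # composition-only: dropped
  expect_true(is.na(get_w("B", "C"))) # composition-only: dropped
  expect_true(all(igraph::E(w)$weight %in% 2:4))
  # provenance booleans count up to the weight
  flags <- cbind(igraph::E(w)$comp_autocorr, igraph::E(w)$comp_breakpoint,
                 igraph::E(w)$phy_autocorr, igraph::E(w)$phy_breakpoint)
  expect_equal(rowSums(flags), igraph::E(w)$weight)
  # node-set mismatch errors
  gs$phy_breakpoint <- mk_cpc(c("A", "B", "C"), list(), "phy_breakpoint")
  expect_error(combine_and_weight(gs), "node-set mismatch")
})

test_that("combine_and_weight invariants hold on fuzzed inputs", {
  set.seed(33)
  ids <- paste0("n", 1:8)
  for (rep in 1:20) {
    gs <- lapply(c("comp_autocorr", "comp_breakpoint",
                   "phy_autocorr", "phy_breakpoint"), function(pv) {
      pairs <- combn(ids, 2)
      keep <- runif(ncol(pairs)) < 0.3
      mk_cpc(ids, split(pairs[, keep, drop = FALSE],
                        col(pairs[, keep, drop = FALSE])), pv)
    })
    names(gs) <- c("comp_autocorr", "comp_breakpoint",
                   "phy_autocorr", "phy_breakpoint")
    w <- combine_and_weight(gs)
    expect_true(igraph::is_simple(w))
    if (igraph::ecount(w) > 0) {
      expect_true(all(igraph::E(w)$weight %in% 2:4))
      expect_true(all((igraph::E(w)$comp_autocorr | igraph::E(w)$comp_breakpoint) &
                      (igraph::E(w)$phy_autocorr | igraph::E(w)$phy_breakpoint)))
    }
  }
})

test_that("troglobite-free edges are dropped, others retained", {
  ids <- c("A", "B", "C")
  g <- mk_cpc(ids, list(c("A", "B"), c("B", "C"), c("A", "C")), "comp_autocorr")
  counts <- c(A = 0, B = 0, C = 3)
  g2 <- drop_troglobite_free_edges(g, counts)
  expect_equal(igraph::ecount(g2), 2)               # A-B removed
  expect_equal(igraph::get_edge_ids(g2, c("A", "B")), 0)
  expect_gt(igraph::get_edge_ids(g2, c("B", "C")), 0) # (0,3) retained
  expect_equal(igraph::vcount(g2), 3)               # nodes never removed
  expect_equal(igraph::V(g2)$troglobites, c(0L, 0L, 3L))
  # all positive counts: unchanged
  g3 <- drop_troglobite_free_edges(g, c(A = 1, B = 1, C = 1))
  expect_equal(igraph::ecount(g3), 3)
  expect_error(drop_troglobite_free_edges(g, c(A = 1)), "missing")
})

test_that("density counts edges over all possible pairs", {
  expect_equal(graph_density(igraph::make_full_graph(5)), 1)
  expect_equal(graph_density(igraph::make_empty_graph(5, directed = FALSE)), 0)
  g <- two_triangle_graph()
  expect_equal(graph_density(g), 7 / 15)
  # matches igraph's own density
  expect_equal(graph_density(g), igraph::edge_density(g))
})

test_that("Girvan-Newman clustering on the two-triangle bridge graph", {
  g <- two_triangle_graph()
  cl <- edge_betweenness_clusters(g)
  expect_equal(cl$n_clusters, 2)
  expect_equal(cl$modularity, 2 * (3 / 7 - (7 / 14)^2), tolerance = 1e-10)
  memb <- cl$membership
  expect_equal(memb[["a"]], memb[["b"]])
  expect_equal(memb[["d"]], memb[["e"]])
  expect_false(memb[["a"]] == memb[["d"]])
  # complete graph: single cluster, Q = 0
  k5 <- igraph::make_full_graph(5)
  cl5 <- edge_betweenness_clusters(k5)
  expect_equal(cl5$n_clusters, 1)
  expect_equal(cl5$modularity, 0)
  expect_error(edge_betweenness_clusters(igraph::make_empty_graph(3, directed = FALSE)),
               "empty")
})

test_that("chosen partition beats the brute-force nested-family maximum nowhere", {
  # on small graphs, no partition in the dendrogram's nested family has
  # higher modularity than the one returned
  set.seed(44)
  for (rep in 1:5) {
    g <- igraph::sample_gnp(8, 0.45)
    if (igraph::ecount(g) == 0) next
    igraph::V(g)$name <- paste0("v", 1:8)
    cl <- edge_betweenness_clusters(g)
    cm <- cl$communities
    qs <- vapply(seq_len(nrow(cm$merges) + 1) - 1, function(k) {
      memb <- igraph::cut_at(cm, steps = k)
      igraph::modularity(g, memb)
    }, 0)
    expect_gte(cl$modularity + 1e-12, max(qs))
  }
})

test_that("planted two-block graphs are recovered", {
  ok <- 0
  for (s in 1:25) {
    set.seed(500 + s)
    block <- rep(1:2, each = 15)
    p <- ifelse(outer(block, block, "=="), 0.8, 0.05)
    adj <- matrix(runif(900) < p, 30, 30) & upper.tri(p)
    g <- igraph::graph_from_adjacency_matrix(adj | t(adj), mode = "undirected")
    igraph::V(g)$name <- paste0("v", 1:30)
    cl <- edge_betweenness_clusters(g)
    if (adjusted_rand_index(cl$membership, block) == 1) ok <- ok + 1
  }
  expect_gte(ok / 25, 0.9)
})

test_that("betweenness: closed forms on stars and paths", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:4))
  b <- node_betweenness(star)
  expect_equal(unname(b$scores["hub"]), choose(4, 2))
  expect_equal(unname(b$scores[paste0("leaf", 1:4)]), rep(0, 4))
  expect_equal(b$bridges$cave, "hub")
  path <- igraph::make_graph(~ a - b, b - c)
  bp <- node_betweenness(path)
  expect_equal(unname(bp$scores[c("a", "b", "c")]), c(0, 1, 0))
  two <- igraph::make_graph(~ a - b, c - d)
  expect_equal(unname(node_betweenness(two)$scores), rep(0, 4))
  expect_equal(nrow(node_betweenness(star, top_k = 2)$bridges), 2)
})
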