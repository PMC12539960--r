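test_that("transfer enumeration matches the brute-force filter on small graphs", {
  expect_equal(nrow(enumerate_transfers(gen_named("cycle", 4))), 0)
  s4 <- gen_named("star", 4)
  mv <- enumerate_transfers(s4)
  # each of the 3 leaf pivots can rewire its hub edge to either other leaf
  expect_equal(nrow(mv), 6)
  expect_true(all(mv$deg_from == 3 & mv$deg_to == 1))
  # exhaustive cross-check on all connected graphs with up to 5 nodes
  for (n in 3:5) {
    for (g in enumerate_connected_graphs(n)) {
      k <- igraph::degree(g)
      adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
      naive <- 0L
      for (p in seq_len(n)) for (u in seq_len(n)) for (v in seq_len(n)) {
        if (p != u && p != v && u != v && adj[p, u] && !adj[p, v] &&
            k[u] >= k[v] + 2) naive <- naive + 1L
      }
      expect_equal(nrow(enumerate_transfers(g)), naive)
    }
  }
})

test_that("applying a transfer conserves degree and changes HS as predicted", {
  s4 <- gen_named("star", 4)
  mv <- enumerate_transfers(s4)[1, ]
  g2 <- apply_transfer(s4, mv)
  expect_equal(sort(degree_sequence(g2)), c(1, 1, 2, 2))
  expect_equal(het_hs(s4), 0.75)
  expect_equal(het_hs(g2), 0.25)
  expect_error(apply_transfer(g2, mv), "invalid move")
  # conservation under fuzzed applications
  for (seed in 1:25) {
    g <- gen_er(12, 4, seed = seed)
    mv <- enumerate_transfers(g)
    if (nrow(mv) == 0) next
    pick <- mv[1 + (seed %% nrow(mv)), ]
    g2 <- apply_transfer(g, pick)
    expect_equal(sum(degree_sequence(g2)), sum(degree_sequence(g)))
    expect_equal(igraph::ecount(g2), igraph::ecount(g))
    expect_false(igraph::any_multiple(g2))
  }
})

test_that("the mean-crossing witness leaves the absolute-deviation measure flat", {
  g <- het_witness_graphs()$hn_mean_crossing
  expect_equal(sort(degree_sequence(g)), c(1, 1, 2, 2, 2, 4))
  expect_equal(mean(degree_sequence(g)), 2)
  mv <- enumerate_transfers(g)
  hub <- which(degree_sequence(g) == 4)
  cand <- mv[mv$from == hub & mv$deg_to == 2, ]
  expect_gt(nrow(cand), 0)
  g2 <- apply_transfer(g, cand[1, ])
  expect_equal(het_hn(g), 4)
  expect_equal(het_hn(g2), 4)   # unchanged: a transfer-principle breach
})

test_that("degree-shift addition behaves per theory", {
  s4 <- gen_named("star", 4)
  res <- apply_addition(s4, 2, "degree_shift")
  expect_equal(sort(res$degrees), c(3, 3, 3, 5))
  expect_equal(het_hs(res$graph, degrees = res$degrees), het_hs(s4))
  # HPED strictly decreases: numerator terms unchanged, mean degree grows
  expect_lt(het_hped(res$graph, degrees = res$degrees), het_hped(s4))
  expect_equal(het_ha(res$graph, degrees = res$degrees), het_ha(s4))
})

test_that("overlay addition yields a true graph with shifted degrees", {
  c6 <- gen_named("cycle", 6)
  res <- apply_addition(c6, 2, "overlay")
  expect_equal(degree_sequence(res$graph), rep(4, 6))
  expect_equal(het_hcs(res$graph), 0, tolerance = 1e-9)
  expect_false(igraph::any_multiple(res$graph))
  # original edges are contained in the augmented graph
  el <- igraph::as_edgelist(c6, names = FALSE)
  for (r in seq_len(nrow(el))) {
    expect_true(igraph::get_edge_ids(res$graph, el[r, ]) > 0)
  }
  expect_error(apply_addition(gen_named("complete", 4), 1, "overlay"),
               "infeasible")
})

test_that("replication scales counts but preserves the distribution", {
  d4 <- make_d4()
  r2 <- het_replicate(d4, 2)
  expect_equal(igraph::vcount(r2), 8)
  expect_equal(igraph::ecount(r2), 8)
  expect_equal(igraph::components(r2)$no, 2)
  expect_equal(dist_p <- degree_dist(r2)$counts / 8,
               degree_dist(d4)$counts / 4)
  expect_equal(het_hs(r2), het_hs(d4))
  expect_equal(het_ha(r2), 2 * het_ha(d4))     # adjacent: linear scaling
  expect_equal(het_hap(r2), 4 * het_hap(d4))   # pairwise: quadratic scaling
})

test_that("distribution replication uses minimal integer pre-scaling", {
  d <- degree_dist(c(1, 2))
  r <- replicate_distribution(d, 3, 2)
  expect_equal(unname(r$counts), c(3L, 3L))
  expect_equal(r$n, 6)
  r2 <- replicate_distribution(degree_dist(c(1, 1, 2)), 2)
  expect_equal(unname(r2$counts), c(4L, 2L))
  # shape invariance
  expect_equal(unname(r$counts) / r$n, unname(d$counts) / d$n)
})
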