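test_that("global dispersion presets match hand computations", {
  s4 <- gen_named("star", 4)
  c4 <- gen_named("cycle", 4)
  d4 <- make_d4()
  expect_equal(het_hhg(s4), 6)
  expect_equal(het_hf(s4), 1)
  expect_equal(het_hf(gen_named("star", 7)), 1)
  expect_equal(het_hhg(c4), 0)
  expect_equal(het_hs(c4), 0)
  expect_equal(het_hn(c4), 0)
  expect_equal(het_hs(d4), 0.5)
  expect_equal(het_hn(d4), 2)
  expect_equal(het_hhg(d4), 4)
  expect_equal(het_hf(d4), 2 / 3)
  expect_error(het_hf(gen_named("complete", 2)), "n < 3")
})

test_that("generic class evaluators reproduce the presets", {
  d4 <- make_d4()
  spec_hs <- het_spec("HS", "global_dispersion",
                      c_fun = function(n, m, degs) 1 / n,
                      g = function(x) x^2, h = mean)
  expect_equal(eval_global_dispersion(d4, spec_hs), het_hs(d4))
  spec_hhg <- het_spec("HHG", "global_dispersion",
                       g = function(x) -x, h = max)
  expect_equal(eval_global_dispersion(d4, spec_hhg), het_hhg(d4))
  spec_ha <- het_spec("HA", "adjacent_dispersion", g = abs)
  expect_equal(eval_adjacent_dispersion(d4, spec_ha), het_ha(d4))
  spec_hap <- het_spec("HAp", "pairwise_dispersion", g = abs)
  expect_equal(eval_pairwise_dispersion(d4, spec_hap), het_hap(d4))
  expect_error(het_spec("bad", "global_dispersion", g = function(x) x + 1),
               "g\\(0\\) = 0")
})

test_that("variance identities hold: Eq. forms and the phi-version", {
  for (seed in 1:20) {
    g <- gen_er(30, 5, seed = seed)
    k <- degree_sequence(g)
    expect_equal(het_hs(g), mean(k^2) - mean(k)^2, tolerance = 1e-9)
    expect_equal(het_hs_phi(g, function(x) x^2), het_hs(g), tolerance = 1e-9)
  }
})

test_that("HB reconstruction reproduces the documented extremes", {
  expect_warning(v <- het_hb(gen_named("complete", 4)), "forced")
  expect_equal(v, 0)
  expect_equal(het_hb(gen_named("star", 4)), 1)
  expect_equal(het_hb(gen_named("cycle", 5)), 0)
  # brute-force validation: the numerator's floor term equals the smallest
  # attainable kmax over graphical sequences at that (n, m)
  for (n in 4:7) {
    for (m in c(n - 1, n, n + 2)) {
      if (m > n * (n - 1) / 2) next
      expect_equal(hetnet:::min_attainable_kmax(n, m), ceiling(2 * m / n),
                   info = sprintf("n=%d m=%d", n, m))
    }
  }
  # and HB stays within [0, 1] on arbitrary graphs
  for (seed in 1:30) {
    g <- gen_er(12, 4, seed = seed)
    if (igraph::ecount(g) == 0) next
    v <- suppressWarnings(het_hb(g))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("normalized variance uses the exhaustive (n, m) maximum", {
  expect_equal(het_hs_norm(gen_named("cycle", 4)), 0)
  # all graphs with n = 4, m = 3: max variance is the star's 0.75
  expect_equal(as.numeric(max_hs_value(4, 3)), 0.75)
  expect_equal(het_hs_norm(gen_named("star", 4)), 1)
  d4 <- make_d4()
  expect_equal(het_hs_norm(d4), 0.5 / as.numeric(max_hs_value(4, 4)))
  for (seed in 1:15) {
    g <- gen_er(9, 4, seed = seed)
    v <- suppressWarnings(het_hs_norm(g))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("adjacent measures match hand values and reject isolated nodes", {
  s4 <- gen_named("star", 4)
  d4 <- make_d4()
  expect_equal(het_ha(s4), 6)
  expect_equal(het_ha(gen_named("cycle", 4)), 0)
  expect_equal(het_he(s4), 4 - 2 * sqrt(3), tolerance = 1e-9)
  expect_equal(het_he(d4), 4 - 2 * bf_randic(d4), tolerance = 1e-9)
  g <- igraph::add_vertices(s4, 1)
  igraph::V(g)$name <- as.character(1:5)
  expect_error(het_he(g), "isolated")
  expect_error(het_hep(g), "isolated")
})

test_that("normalized Estrada measure is 1 on stars and 0 on regular graphs", {
  for (n in c(4, 10, 25, 50)) {
    expect_equal(het_he_norm(gen_named("star", n)), 1, tolerance = 1e-9)
  }
  expect_equal(het_he_norm(gen_named("cycle", 8)), 0)
  expect_equal(het_he_norm(make_d4()), (4 - 2 * bf_randic(make_d4())) /
                 (4 - 2 * sqrt(3)), tolerance = 1e-9)
  expect_error(het_he_norm(gen_named("complete", 2)), "n <= 2")
})

test_that("pairwise measures match brute force on fixtures", {
  d4 <- make_d4()
  s4 <- gen_named("star", 4)
  expect_equal(het_hap(d4), 6)
  expect_equal(het_hap(s4), 6)
  expect_equal(het_hap(gen_named("cycle", 4)), 0)
  expect_equal(het_hep(gen_named("cycle", 4)), 0)
  expect_equal(het_hep(d4), bf_hep(d4), tolerance = 1e-9)
})

test_that("expected-difference measures follow the stated conventions", {
  s4 <- gen_named("star", 4)
  d4 <- make_d4()
  expect_equal(het_haed(s4), 6)
  expect_equal(het_haed(d4), 1.5)
  expect_equal(het_haed(gen_named("cycle", 6)), 0)
  expect_equal(het_hhw(s4), 0.25)
  expect_equal(het_hl(d4), 0.625)
  expect_equal(het_hped(d4), het_hl(d4))
  expect_equal(het_hhw(gen_named("regular", 8, r = 3)), 0)
  expect_equal(het_hl(gen_named("regular", 8, r = 3)), 0)
  expect_error(het_haed(igraph::make_empty_graph(3, directed = FALSE)))
})

test_that("spectral defect matches closed forms and requires connectivity", {
  expect_equal(het_hcs(gen_named("cycle", 4)), 0, tolerance = 1e-9)
  expect_equal(het_hcs(gen_named("star", 4)), sqrt(3) - 1.5, tolerance = 1e-9)
  expect_equal(het_hcs(make_d4()), bf_hcs(make_d4()), tolerance = 1e-9)
  t2 <- gen_named("cycle", 3)
  igraph::V(t2)$name <- as.character(4:6)
  two <- igraph::disjoint_union(gen_named("cycle", 3), t2)
  expect_error(het_hcs(two), "connected")
})

test_that("degree diversity and its normalization match hand values", {
  expect_equal(het_hj(gen_named("cycle", 4)), 0)
  d4 <- make_d4()
  expect_equal(het_hj(d4), 0.34375)
  expect_equal(het_hj(d4), 1 - 3 / 4 + 6 / 64)     # complete heterogeneity at n = 4
  expect_equal(het_hj_norm(d4), 1)
  s4 <- gen_named("star", 4)
  expect_equal(het_hj(s4), 0.15625)
  expect_equal(het_hj_norm(s4), 0.15625 / (1 - 3 / 4 + 6 / 64))
  # printed asymptotic denominator exceeds 1 at small n, exact stays in [0, 1]
  expect_gt(het_hj_norm(d4, exact_denominator = FALSE), 1)
  for (n in 4:7) {
    expect_equal(het_hj_norm(gen_diverse(n)), 1, tolerance = 1e-12)
  }
})

test_that("the dispatcher covers the battery and rejects unknown names", {
  c6 <- gen_named("cycle", 6)
  res <- het(c6)
  expect_equal(nrow(res), 12)
  expect_true(all(abs(res$value) <= 1e-9))
  expect_equal(het_evaluate(c6, "HS"), 0)
  expect_error(het_evaluate(c6, "nope"), "available")
  reg <- het_registry()
  expect_setequal(reg$measure, het_measures())
  expect_equal(nrow(reg), 12)
})

test_that("every battery measure is zero on regular graphs", {
  regs <- list(gen_named("cycle", 5), gen_named("cycle", 8),
               gen_named("regular", 8, r = 3), gen_named("regular", 10, r = 4),
               gen_named("complete", 6))
  for (g in regs) {
    vals <- het(g)$value
    expect_true(all(abs(vals) <= 1e-9))
  }
})

test_that("Randic identity links HE to R_{-1/2} on random graphs", {
  for (seed in 1:40) {
    g <- random_no_isolated(25, 0.25, seed)
    n <- igraph::vcount(g)
    expect_equal(het_he(g), n - 2 * randic_index(g), tolerance = 1e-9)
  }
})

test_that("HF is HHG scaled by (n-1)(n-2) identically", {
  for (seed in 1:25) {
    g <- gen_er(15, 4, seed = seed)
    expect_equal(het_hf(g),
                 het_hhg(g) / ((igraph::vcount(g) - 1) * (igraph::vcount(g) - 2)),
                 tolerance = 1e-12)
  }
})

test_that("bounded measures stay in [0, 1] on random graphs", {
  for (seed in 1:40) {
    g <- random_no_isolated(20, 0.3, seed)
    expect_gte(het_hhw(g), 0); expect_lte(het_hhw(g), 1)
    v <- suppressWarnings(het_hb(g))
    expect_gte(v, 0); expect_lte(v, 1)
    if (igraph::vcount(g) >= 4) {
      expect_gte(het_hj_norm(g), 0); expect_lte(het_hj_norm(g), 1)
    }
    if (igraph::vcount(g) >= 3) {
      hv <- het_he_norm(g)
      expect_gte(hv, -1e-12); expect_lte(hv, 1 + 1e-12)
    }
  }
})
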