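# A reduced battery keeps these unit tests fast; the full default battery
# runs in the acceptance suite.
small_battery <- function() {
  battery <- list()
  for (n in 1:5) {
    gs <- enumerate_connected_graphs(n)
    names(gs) <- sprintf("c%d_%02d", n, seq_along(gs))
    battery <- c(battery, gs)
  }
  c(battery, het_witness_graphs())
}

test_that("variance and pairwise-Albertson pass transfer; witnesses condemn the rest", {
  battery <- small_battery()
  expect_true(check_transfer("HS", battery)$pass)
  expect_true(check_transfer("HAp", battery)$pass)
  for (m in c("HN", "HF", "HHG", "HA", "HE", "HAED", "HPED", "HJ", "HCS")) {
    v <- check_transfer(m, battery)
    expect_false(v$pass, info = m)
    expect_false(is.null(v$witness), info = m)
  }
})

test_that("HS transfer compliance matches the closed-form decrement", {
  # sum k^2 changes by -2 (k_u - k_v - 1) <= -2 for an admissible move
  for (seed in 1:10) {
    g <- gen_er(10, 4, seed = seed)
    mv <- enumerate_transfers(g)
    if (nrow(mv) == 0) next
    k <- degree_sequence(g)
    n <- length(k)
    for (r in seq_len(min(nrow(mv), 10))) {
      g2 <- apply_transfer(g, mv[r, ])
      delta <- sum(degree_sequence(g2)^2) - sum(k^2)
      expect_equal(delta, -2 * (mv$deg_from[r] - mv$deg_to[r] - 1))
      expect_lte(delta, -2)
      expect_lt(het_hs(g2), het_hs(g))
    }
  }
})

test_that("transfer witnesses replay to the recorded values", {
  battery <- small_battery()
  for (m in c("HN", "HA", "HPED", "HJ")) {
    v <- check_transfer(m, battery)
    w <- v$witness
    before <- het_evaluate(w$graph, m)
    after <- het_evaluate(apply_transfer(w$graph, w$move), m)
    expect_equal(before, w$before, tolerance = 1e-12, info = m)
    expect_equal(after, w$after, tolerance = 1e-12, info = m)
    expect_gte(after, before - 1e-9)
  }
})

test_that("addition verdicts split along the documented semantics", {
  battery <- small_battery()
  for (m in c("HN", "HS", "HF", "HHG", "HA", "HE", "HAp", "HEp", "HPED",
              "HJ")) {
    expect_true(check_addition(m, battery)$pass, info = m)
  }
  for (m in c("HAED", "HCS")) {
    v <- check_addition(m, battery)
    expect_false(v$pass, info = m)
    expect_false(is.null(v$witness), info = m)
  }
  # HE strictly decreases under a degree shift on a non-regular graph:
  # inverse square roots contract differences
  s4 <- gen_named("star", 4)
  res <- apply_addition(s4, 1, "degree_shift")
  expect_lt(het_he(res$graph, degrees = res$degrees), het_he(s4))
})

test_that("replication verdicts isolate the distribution-shape measures", {
  battery <- small_battery()
  expect_true(check_replication("HS", battery)$pass)
  expect_true(check_replication("HJ", battery)$pass)
  for (m in c("HN", "HF", "HHG", "HA", "HE", "HAp", "HEp", "HAED", "HPED")) {
    v <- check_replication(m, battery)
    expect_false(v$pass, info = m)
  }
  v <- check_replication("HCS", battery)
  expect_false(v$pass)
  expect_match(v$witness$error, "connected")   # fails by inapplicability
})

test_that("enlarging the battery never flips fail to pass", {
  small <- small_battery()
  tiny <- small[1:20]
  for (m in c("HS", "HN", "HA", "HAp")) {
    v_tiny <- check_transfer(m, tiny)
    v_small <- check_transfer(m, small)
    if (!v_tiny$pass) expect_false(v_small$pass, info = m)
  }
})

test_that("the compliance matrix on the default battery reproduces the published pattern", {
  cm <- compliance_matrix()
  expected <- rbind(
    HN   = c(FALSE, TRUE,  FALSE),
    HS   = c(TRUE,  TRUE,  TRUE),
    HF   = c(FALSE, TRUE,  FALSE),
    HHG  = c(FALSE, TRUE,  FALSE),
    HA   = c(FALSE, TRUE,  FALSE),
    HE   = c(FALSE, TRUE,  FALSE),
    HAp  = c(TRUE,  TRUE,  FALSE),
    HEp  = c(FALSE, TRUE,  FALSE),
    HAED = c(FALSE, FALSE, FALSE),
    HPED = c(FALSE, TRUE,  FALSE),
    HJ   = c(FALSE, TRUE,  TRUE),
    HCS  = c(FALSE, FALSE, FALSE))
  colnames(expected) <- c("transfer", "addition", "replication")
  expect_identical(cm$table, expected)
  expect_equal(cm$summary$pass_all, 1)
  expect_equal(cm$summary$addition_passes, 10)
  expect_equal(cm$summary$transfer_passes, 2)
  expect_equal(cm$summary$replication_passes, 2)
  expect_equal(cm$summary$pass_none, 2)
  df <- as.data.frame(cm)
  expect_equal(nrow(df), 36)
})
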