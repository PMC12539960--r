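# Independent brute-force reference implementations of every measure,
# written directly from the defining formulas with naive loops, plus small
# fixture graphs.  These stay deliberately separate from the package's
# optimized evaluators.

edges_of <- function(g) igraph::as_edgelist(g, names = FALSE)

# the 4-node diverse graph: edges {12, 23, 34, 24}, degrees (1, 3, 2, 2)
make_d4 <- function() {
  check_graph(igraph::make_graph(c(1, 2, 2, 3, 3, 4, 2, 4), directed = FALSE))
}

bf_hhg <- function(g) {
  k <- unname(igraph::degree(g))
  sum(max(k) - k)
}

bf_hf <- function(g) {
  n <- igraph::vcount(g)
  bf_hhg(g) / ((n - 1) * (n - 2))
}

bf_hs <- function(g) {
  k <- unname(igraph::degree(g))
  acc <- 0
  for (ki in k) acc <- acc + (ki - mean(k))^2
  acc / length(k)
}

bf_hn <- function(g) {
  k <- unname(igraph::degree(g))
  sum(abs(k - mean(k)))
}

bf_ha <- function(g) {
  k <- unname(igraph::degree(g))
  e <- edges_of(g)
  acc <- 0
  for (r in seq_len(nrow(e))) acc <- acc + abs(k[e[r, 1]] - k[e[r, 2]])
  acc
}

bf_he <- function(g) {
  k <- unname(igraph::degree(g))
  e <- edges_of(g)
  acc <- 0
  for (r in seq_len(nrow(e))) {
    acc <- acc + (1 / sqrt(k[e[r, 1]]) - 1 / sqrt(k[e[r, 2]]))^2
  }
  acc
}

bf_randic <- function(g) {
  k <- unname(igraph::degree(g))
  e <- edges_of(g)
  acc <- 0
  for (r in seq_len(nrow(e))) acc <- acc + 1 / sqrt(k[e[r, 1]] * k[e[r, 2]])
  acc
}

bf_hap <- function(g) {
  k <- unname(igraph::degree(g))
  n <- length(k)
  acc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) acc <- acc + abs(k[i] - k[j])
  acc
}

bf_hep <- function(g) {
  k <- unname(igraph::degree(g))
  n <- length(k)
  acc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) acc <- acc + (1 / sqrt(k[i]) - 1 / sqrt(k[j]))^2
  }
  acc
}

bf_haed <- function(g) {
  k <- unname(igraph::degree(g))
  e <- edges_of(g)
  m <- nrow(e)
  pair <- function(r) sort(c(k[e[r, 1]], k[e[r, 2]]))
  acc <- 0
  for (r in seq_len(m)) {
    pr <- pair(r)
    freq <- sum(vapply(seq_len(m), function(q) all(pair(q) == pr), TRUE)) / m
    acc <- acc + abs(pr[1] - pr[2]) * freq
  }
  acc
}

bf_hhw <- function(g) {
  k <- if (igraph::is_igraph(g)) unname(igraph::degree(g)) else g
  n <- length(k)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) acc <- acc + abs(k[i] - k[j])
  0.5 * acc / (mean(k) * n^2)
}

bf_hl <- function(g) {
  k <- unname(igraph::degree(g))
  n <- length(k)
  p <- function(x) sum(k == x) / n
  acc <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) acc <- acc + abs(k[i] - k[j]) * p(k[i]) * p(k[j])
  }
  acc / mean(k)
}

bf_hcs <- function(g) {
  a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  max(eigen(a, symmetric = TRUE, only.values = TRUE)$values) -
    mean(unname(igraph::degree(g)))
}

bf_hj <- function(g) {
  k <- if (igraph::is_igraph(g)) unname(igraph::degree(g)) else g
  n <- length(k)
  acc <- 0
  for (val in unique(k)) acc <- acc + (1 - sum(k == val) / n)^2
  acc / n
}

bf_hb <- function(g) {
  k <- unname(igraph::degree(g))
  n <- length(k)
  m <- igraph::ecount(g)
  lo <- ceiling(2 * m / n)
  hi <- min(n - 1, m)
  if (hi == lo) return(0)
  (max(k) - lo) / (hi - lo)
}

bf_all <- function(g) {
  c(HN = bf_hn(g), HS = bf_hs(g), HF = bf_hf(g), HHG = bf_hhg(g),
    HA = bf_ha(g), HE = bf_he(g), HAp = bf_hap(g), HEp = bf_hep(g),
    HAED = bf_haed(g), HPED = bf_hl(g), HJ = bf_hj(g), HCS = bf_hcs(g))
}

# random simple graph without isolated nodes, for identity checks
random_no_isolated <- function(n, p, seed) {
  g <- gen_er(n, p * (n - 1), seed = seed)
  k <- unname(igraph::degree(g))
  if (any(k == 0)) {
    g <- igraph::induced_subgraph(g, which(k > 0))
  }
  g
}
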