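# Seeded construction of every graph family used by the evaluation
# machinery: random models for the sweep, named homogeneous/heterogeneous
# families, completely diverse graphs, and degree-sequence realization.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

label_nodes <- function(g) {
  igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  g
}

#' Erdos-Renyi random graph with a target mean degree
#'
#' G(n, p) with p = mean_degree / (n - 1).
#'
#' @param n Number of nodes.
#' @param mean_degree Target mean degree, in `[0, n - 1]`.
#' @param seed Integer seed; identical seeds give identical graphs.
#' @return An igraph object.
#' @export
gen_er <- function(n, mean_degree, seed = NULL) {
  stopifnot(n >= 1, mean_degree >= 0, mean_degree <= n - 1 || n == 1)
  p <- if (n > 1) mean_degree / (n - 1) else 0
  g <- with_seed(seed, igraph::sample_gnp(n, p))
  check_graph(label_nodes(g))
}

#' Power-law random graph by the static fitness model
#'
#' Nodes get fitness proportional to rank^(-1/(gamma - 1)); edges are drawn
#' between nodes with probability proportional to the product of their
#' fitnesses until exactly `target_edges` distinct edges exist.  The
#' resulting degree distribution has a power-law tail with exponent close
#' to `gamma`.
#'
#' @param n Number of nodes.
#' @param gamma Degree exponent, > 2.
#' @param target_edges Exact number of edges (e.g. matched to a paired
#'   Erdos-Renyi draw).
#' @param seed Integer seed.
#' @return An igraph object with exactly `target_edges` edges.
#' @export
gen_powerlaw <- function(n, gamma, target_edges, seed = NULL) {
  stopifnot(n >= 2, gamma > 2, target_edges >= 0)
  if (target_edges > n * (n - 1) / 2) {
    stop("target_edges exceeds the maximum for a simple graph", call. = FALSE)
  }
  fitness <- seq_len(n)^(-1 / (gamma - 1))
  g <- with_seed(seed, igraph::sample_fitness(target_edges, fitness,
                                              loops = FALSE, multiple = FALSE))
  check_graph(label_nodes(g))
}

# Geometric degrees on {1, 2, ...} with the requested mean; parity repaired
# by decrementing the first degree > 1.
sample_geometric_degrees <- function(n, mean_degree, seed = NULL) {
  stopifnot(mean_degree >= 1)
  degs <- with_seed(seed, 1L + stats::rgeom(n, prob = 1 / mean_degree))
  degs <- pmin(degs, n - 1L)
  if (sum(degs) %% 2L == 1L) {
    i <- which(degs > 1L)[1L]
    if (is.na(i)) i <- 1L
    degs[i] <- degs[i] - 1L
  }
  degs
}

#' Exponential-degree random graph (geometric configuration model)
#'
#' Degrees are drawn from the geometric distribution on {1, 2, ...} with the
#' requested mean (the discrete analogue of an exponential degree
#' distribution), repaired to even parity, and realized as a simple graph by
#' degree-sequence matching.
#'
#' @param n Number of nodes.
#' @param mean_degree Target mean degree, >= 1.
#' @param seed Integer seed.
#' @return An igraph object whose degrees follow the sampled sequence.
#' @export
gen_exponential <- function(n, mean_degree, seed = NULL) {
  degs <- sample_geometric_degrees(n, mean_degree, seed)
  if (!igraph::is_graphical(degs)) {
    stop("sampled degree sequence is not graphical after parity repair; ",
         "sum = ", sum(degs), ", max = ", max(degs), call. = FALSE)
  }
  g <- with_seed(seed, igraph::sample_degseq(degs, method = "fast.heur.simple"))
  check_graph(label_nodes(g))
}

#' Named deterministic graph families
#'
#' `star`: node 1 adjacent to all others.  `wheel`: cycle on nodes 2..n plus
#' hub node 1.  `cycle`, `complete`: standard.  `complete_bipartite`: parts
#' of size `parts[1]` and `parts[2]`.  `regular`: circulant with offsets
#' 1..r/2 (plus the antipodal offset n/2 for odd r, even n).
#'
#' @param family One of `"star"`, `"wheel"`, `"cycle"`, `"complete"`,
#'   `"complete_bipartite"`, `"regular"`.
#' @param n Number of nodes.
#' @param r Degree, for `family = "regular"`.
#' @param parts Integer vector of two part sizes, for
#'   `family = "complete_bipartite"` (default splits `n`).
#' @return An igraph object.
#' @examples
#' degree_sequence(gen_named("wheel", 5)) # hub 4, rim 3 3 3 3
#' @export
gen_named <- function(family = c("star", "wheel", "cycle", "complete",
                                 "complete_bipartite", "regular"),
                      n, r = NULL, parts = NULL) {
  family <- match.arg(family)
  g <- switch(family,
    star = {
      stopifnot(n >= 2)
      igraph::make_star(n, mode = "undirected", center = 1)
    },
    wheel = {
      stopifnot(n >= 4)
      rim <- 2:n
      cyc <- cbind(rim, c(rim[-1L], rim[1L]))
      igraph::make_graph(t(rbind(cbind(1L, rim), cyc)), n = n,
                         directed = FALSE)
    },
    cycle = {
      stopifnot(n >= 3)
      igraph::make_ring(n)
    },
    complete = igraph::make_full_graph(n),
    complete_bipartite = {
      if (is.null(parts)) parts <- c(floor(n / 2), ceiling(n / 2))
      stopifnot(length(parts) == 2, sum(parts) == n)
      igraph::make_full_bipartite_graph(parts[1L], parts[2L])
    },
    regular = {
      stopifnot(!is.null(r), r >= 0, r <= n - 1)
      if ((r * n) %% 2 == 1) {
        stop("no r-regular graph exists: r * n must be even", call. = FALSE)
      }
      edges <- NULL
      for (off in seq_len(r %/% 2)) {
        edges <- rbind(edges, cbind(seq_len(n), (seq_len(n) - 1L + off) %% n + 1L))
      }
      if (r %% 2 == 1) { # antipodal matching, n even
        half <- n / 2
        edges <- rbind(edges, cbind(seq_len(half), seq_len(half) + half))
      }
      key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
      edges <- edges[!duplicated(key), , drop = FALSE]
      igraph::make_graph(t(edges), n = n, directed = FALSE)
    })
  check_graph(label_nodes(g))
}

# Canonical completely diverse degree sequence for n in 4..7: the degree
# multiset must take exactly n - 1 distinct values with one value repeated,
# which forces the values {1, ..., n-1}; the duplicated value is the
# smallest choice with even sum that is graphical.
diverse_sequence <- function(n) {
  stopifnot(n >= 4, n <= 7)
  base <- seq_len(n - 1L)
  for (dup in base) {
    s <- sort(c(base, dup))
    if (sum(s) %% 2L == 0L && igraph::is_graphical(s)) return(s)
  }
  stop("no completely diverse sequence found for n = ", n, call. = FALSE)
}

#' Completely diverse graph
#'
#' A completely diverse graph has exactly one repeated degree value; all
#' other degrees are unique.  For n in 4..7 the canonical degree sequence
#' (lexicographically smallest feasible choice, which forces degrees
#' {1, ..., n-1} plus one duplicate) is realized by Havel-Hakimi and
#' repaired to a connected graph if needed.
#'
#' @param n Number of nodes, 4 to 7.
#' @return A connected igraph object with exactly one repeated degree value.
#' @examples
#' sort(degree_sequence(gen_diverse(4))) # 1 2 2 3
#' @export
gen_diverse <- function(n) {
  s <- diverse_sequence(n)
  g <- realize_sequence(s)
  if (!igraph::is_connected(g)) {
    g <- connect_by_swap(g)
  }
  check_graph(g)
}

# Degree-preserving 2-swap until connected (components always merge when an
# edge pair across components is rewired).
connect_by_swap <- function(g) {
  for (guard in 1:100) {
    if (igraph::is_connected(g)) return(g)
    comp <- igraph::components(g)$membership
    el <- igraph::as_edgelist(g, names = FALSE)
    cross <- NULL
    for (i in seq_len(nrow(el))) {
      for (j in seq_len(nrow(el))) {
        if (comp[el[i, 1]] != comp[el[j, 1]]) { cross <- c(i, j); break }
      }
      if (!is.null(cross)) break
    }
    if (is.null(cross)) stop("cannot connect graph by swaps", call. = FALSE)
    a <- el[cross[1], ]; b <- el[cross[2], ]
    g <- igraph::delete_edges(g, igraph::get_edge_ids(
      g, c(a[1], a[2], b[1], b[2])))
    g <- igraph::add_edges(g, c(a[1], b[1], a[2], b[2]))
    g <- igraph::simplify(g)
  }
  g
}

#' Realize a graphical degree sequence (Havel-Hakimi)
#'
#' Deterministic highest-degree-first construction.  Non-graphical
#' sequences raise an error citing the first violated Erdos-Gallai
#' inequality.
#'
#' @param degrees Integer vector of requested degrees.
#' @return An igraph object with exactly the requested degrees (in node
#'   order).
#' @examples
#' sort(degree_sequence(realize_sequence(c(3, 1, 1, 1)))) # the star S4
#' @export
realize_sequence <- function(degrees) {
  degrees <- as.integer(degrees)
  n <- length(degrees)
  stopifnot(n >= 1)
  if (any(degrees < 0L) || any(degrees > n - 1L) || sum(degrees) %% 2L == 1L ||
      !igraph::is_graphical(degrees)) {
    s <- sort(degrees, decreasing = TRUE)
    if (sum(degrees) %% 2L == 1L) {
      stop("degree sequence is not graphical: odd degree sum", call. = FALSE)
    }
    for (k in seq_len(n)) {
      lhs <- sum(s[seq_len(k)])
      rhs <- k * (k - 1L) + sum(pmin(s[-seq_len(k)], k))
      if (lhs > rhs) {
        stop(sprintf(
          "degree sequence is not graphical: Erdos-Gallai inequality fails at k = %d (%d > %d)",
          k, lhs, rhs), call. = FALSE)
      }
    }
    stop("degree sequence is not graphical", call. = FALSE)
  }
  remaining <- degrees
  edges <- NULL
  repeat {
    if (all(remaining == 0L)) break
    u <- order(-remaining, seq_len(n))[1L]
    d <- remaining[u]
    remaining[u] <- 0L
    targets <- order(-remaining, seq_len(n))
    targets <- setdiff(targets, u)[seq_len(d)]
    if (any(remaining[targets] <= 0L)) {
      stop("internal error: Havel-Hakimi failed on a graphical sequence",
           call. = FALSE)
    }
    edges <- rbind(edges, cbind(u, targets))
    remaining[targets] <- remaining[targets] - 1L
  }
  g <- if (is.null(edges)) {
    igraph::make_empty_graph(n, directed = FALSE)
  } else {
    igraph::make_graph(t(edges), n = n, directed = FALSE)
  }
  check_graph(label_nodes(g))
}

#' Sample a discrete power-law degree sequence
#'
#' Degrees are drawn i.i.d. from P(k) proportional to k^(-gamma) on
#' kmin..kmax (a large cutoff standing in for infinite support).  The
#' sequence is returned as sampled, without parity repair, for use by
#' distribution-only measures.
#'
#' @param n Number of draws.
#' @param gamma Degree exponent.
#' @param kmin Smallest degree (default 1).
#' @param kmax Support cutoff (default 1e6).
#' @param seed Integer seed.
#' @return Integer vector of length `n`.
#' @export
sample_powerlaw_degrees <- function(n, gamma, kmin = 1L, kmax = 1e6L,
                                    seed = NULL) {
  stopifnot(gamma > 1, kmin >= 1, kmax > kmin)
  ks <- kmin:kmax
  probs <- ks^(-gamma)
  with_seed(seed, sample(ks, n, replace = TRUE, prob = probs))
}
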