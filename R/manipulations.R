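# The three network manipulations used to probe measure behaviour:
# transfer rewiring, uniform degree addition, and replication.

#' Enumerate all admissible transfer moves
#'
#' A transfer move rewires the edge (pivot, from) to (pivot, to), moving
#' one unit of degree from a higher-degree node to a lower-degree node
#' without reversing their order: the edge (pivot, from) must exist, the
#' edge (pivot, to) must be absent, pivot is distinct from both, and
#' deg(from) >= deg(to) + 2.
#'
#' @param graph An igraph object.
#' @return A data frame with integer vertex-index columns `pivot`, `from`,
#'   `to` and the corresponding degrees, in deterministic index order.
#' @examples
#' nrow(enumerate_transfers(gen_named("cycle", 4))) # 0: all degrees equal
#' nrow(enumerate_transfers(gen_named("star", 4)))  # 6: 3 leaf pivots x 2 targets
#' @export
enumerate_transfers <- function(graph) {
  graph <- check_graph(graph)
  n <- igraph::vcount(graph)
  degs <- igraph::degree(graph)
  adj <- igraph::as_adjacency_matrix(graph, sparse = FALSE) > 0
  out <- list()
  for (u in seq_len(n)) {        # from (loses the edge)
    for (v in seq_len(n)) {      # to (gains the edge)
      if (u == v || degs[u] < degs[v] + 2) next
      pivots <- which(adj[, u] & !adj[, v])
      pivots <- pivots[pivots != v & pivots != u]
      for (p in pivots) {
        out[[length(out) + 1L]] <- c(p, u, v)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(pivot = integer(0), from = integer(0), to = integer(0),
                      deg_from = integer(0), deg_to = integer(0)))
  }
  m <- do.call(rbind, out)
  df <- data.frame(pivot = m[, 1L], from = m[, 2L], to = m[, 3L],
                   deg_from = degs[m[, 2L]], deg_to = degs[m[, 3L]])
  df[order(df$pivot, df$from, df$to), , drop = FALSE]
}

#' Apply a transfer move
#'
#' @param graph An igraph object.
#' @param move A single-row data frame (or named vector/list) with `pivot`,
#'   `from`, `to` vertex indices, as produced by [enumerate_transfers()].
#' @return The rewired graph; total degree is conserved.
#' @export
apply_transfer <- function(graph, move) {
  graph <- check_graph(graph)
  p <- as.integer(move$pivot); u <- as.integer(move$from)
  v <- as.integer(move$to)
  degs <- igraph::degree(graph)
  eid <- igraph::get_edge_ids(graph, c(p, u))
  if (eid == 0) stop("invalid move: edge (pivot, from) does not exist",
                     call. = FALSE)
  if (igraph::get_edge_ids(graph, c(p, v)) != 0) {
    stop("invalid move: edge (pivot, to) already exists", call. = FALSE)
  }
  if (p == v || p == u || u == v || degs[u] < degs[v] + 2) {
    stop("invalid move: transfer admissibility violated", call. = FALSE)
  }
  g <- igraph::delete_edges(graph, eid)
  igraph::add_edges(g, c(p, v))
}

#' Uniform degree addition
#'
#' Increases every node degree by the same amount `c`, under one of two
#' semantics.  `degree_shift` keeps the original edge set and returns a
#' shifted degree map for evaluators that accept explicit degrees (the
#' natural reading for measures built on degree values and fixed-edge
#' differences).  `overlay` constructs a true graph whose edge set contains
#' the original plus an edge-disjoint c-regular overlay, so that every
#' degree is k_i + c.
#'
#' @param graph An igraph object.
#' @param c Positive integer degree increment.
#' @param semantics `"degree_shift"` or `"overlay"`.
#' @param seed Integer seed for the overlay search.
#' @param tries Attempts at finding an edge-disjoint overlay.
#' @return An object of class `addition_result`: a list with `semantics`,
#'   `graph` (original for degree_shift, augmented for overlay) and
#'   `degrees` (the shifted degree vector).
#' @export
apply_addition <- function(graph, c, semantics = c("degree_shift", "overlay"),
                           seed = 1L, tries = 50L) {
  graph <- check_graph(graph)
  semantics <- match.arg(semantics)
  stopifnot(c >= 1)
  degs <- unname(igraph::degree(graph))
  if (semantics == "degree_shift") {
    out <- list(semantics = semantics, graph = graph, degrees = degs + c)
    class(out) <- "addition_result"
    return(out)
  }
  n <- igraph::vcount(graph)
  if (max(degs) + c > n - 1) {
    stop("overlay infeasible: shifted maximum degree exceeds n - 1; ",
         "use degree_shift or a larger graph", call. = FALSE)
  }
  el <- igraph::as_edgelist(graph, names = FALSE)
  have <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  for (t in seq_len(tries)) {
    ov <- with_seed(seed + t - 1L, try(igraph::sample_k_regular(n, c),
                                       silent = TRUE))
    if (inherits(ov, "try-error")) break
    oel <- igraph::as_edgelist(ov, names = FALSE)
    key <- paste(pmin(oel[, 1], oel[, 2]), pmax(oel[, 1], oel[, 2]))
    if (!any(key %in% have)) {
      g2 <- igraph::add_edges(graph, t(oel))
      out <- list(semantics = semantics, graph = g2,
                  degrees = unname(igraph::degree(g2)))
      class(out) <- "addition_result"
      return(out)
    }
  }
  stop("overlay construction failed: no edge-disjoint ", c,
       "-regular overlay found in ", tries, " attempts", call. = FALSE)
}

#' Replicate a graph as x disjoint copies
#'
#' The disjoint union of `x` relabelled copies ("label#copy"): node and
#' edge counts scale by `x` while the degree distribution P(k) is
#' preserved.
#'
#' @param graph An igraph object.
#' @param x Integer replication factor >= 2.
#' @return An igraph object with `x * n` nodes.
#' @export
het_replicate <- function(graph, x) {
  graph <- check_graph(graph)
  stopifnot(x >= 2, x == round(x))
  copies <- lapply(seq_len(x), function(i) {
    g <- graph
    igraph::V(g)$name <- paste0(igraph::V(graph)$name, "#", i)
    g
  })
  do.call(igraph::disjoint_union, copies)
}

#' Replicate a degree distribution by a rational factor
#'
#' Every count n_k is multiplied by `num/den`, pre-scaled by the smallest
#' integer that makes all products integral, so that the distribution shape
#' P(k) is exactly preserved.
#'
#' @param dist A `degree_dist`.
#' @param num,den Integer numerator and denominator of the factor.
#' @return A `degree_dist` with scaled counts.
#' @examples
#' d <- degree_dist(c(1, 2))
#' replicate_distribution(d, 3, 2)$counts # 1 -> 3, 2 -> 3
#' @export
replicate_distribution <- function(dist, num, den = 1L) {
  dist <- degree_dist(dist)
  stopifnot(num >= 1, den >= 1, num == round(num), den == round(den))
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  t <- dist$counts * num
  g <- Reduce(gcd2, c(t, den))
  s <- den / gcd2(den, Reduce(gcd2, t))
  counts <- as.integer(s * t / den)
  out <- list(n = sum(counts),
              counts = stats::setNames(counts, names(dist$counts)))
  class(out) <- "degree_dist"
  out
}

# Reduce a degree distribution to its smallest integer counts (the shape
# P(k) is unchanged); used by the replication checker for distribution-only
# measures.
reduce_distribution <- function(dist) {
  dist <- degree_dist(dist)
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  g <- Reduce(gcd2, dist$counts)
  counts <- as.integer(dist$counts / g)
  out <- list(n = sum(counts),
              counts = stats::setNames(counts, names(dist$counts)))
  class(out) <- "degree_dist"
  out
}
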