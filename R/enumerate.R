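# Exhaustive enumeration utilities: connected graphs up to isomorphism,
# graphical degree sequences with fixed (n, m), and the maximum degree
# variance over graphs with fixed order and size (the HS' denominator).

.het_cache <- new.env(parent = emptyenv())

canonical_key <- function(graph) {
  n <- igraph::vcount(graph)
  perm <- igraph::canonical_permutation(graph)$labeling
  g2 <- igraph::permute(graph, perm)
  el <- igraph::as_edgelist(g2, names = FALSE)
  if (nrow(el) == 0L) return(paste0("n", n, ":"))
  el <- cbind(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
  el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
  paste0("n", n, ":", paste(el[, 1L], el[, 2L], sep = "-", collapse = ","))
}

#' Enumerate all connected graphs on n nodes up to isomorphism
#'
#' Built inductively: every connected graph on n >= 2 nodes has a non-cut
#' vertex, so it arises from a connected graph on n - 1 nodes by attaching a
#' new vertex to a non-empty neighbourhood.  Candidates are deduplicated by
#' a canonical form (BLISS).  Counts for n = 1..7 are 1, 1, 2, 6, 21, 112,
#' 853.  Results are cached per session.
#'
#' @param n Number of nodes (1 <= n <= 8; n = 7 takes a few seconds).
#' @return List of igraph objects, one per isomorphism class.
#' @export
enumerate_connected_graphs <- function(n) {
  stopifnot(n >= 1L, n <= 8L)
  key <- paste0("conn", n)
  if (!is.null(.het_cache[[key]])) return(.het_cache[[key]])
  if (n == 1L) {
    out <- list(check_graph(igraph::make_empty_graph(1, directed = FALSE)))
  } else {
    prev <- enumerate_connected_graphs(n - 1L)
    seen <- new.env(parent = emptyenv())
    out <- list()
    # non-empty subsets of 1..(n-1) as neighbourhoods of the new vertex
    subsets <- lapply(seq_len(2^(n - 1L) - 1L), function(mask) {
      which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 2L))) != 0L)
    })
    for (h in prev) {
      for (s in subsets) {
        g <- igraph::add_vertices(h, 1L)
        g <- igraph::add_edges(g, rbind(rep(n, length(s)), s))
        k <- canonical_key(g)
        if (is.null(seen[[k]])) {
          seen[[k]] <- TRUE
          igraph::V(g)$name <- as.character(seq_len(n))
          out[[length(out) + 1L]] <- g
        }
      }
    }
  }
  .het_cache[[key]] <- out
  out
}

# All non-increasing graphical degree sequences of length n summing to 2m
# with maximum degree <= n - 1.  Returned as a list of integer vectors.
enumerate_graphical_sequences <- function(n, m) {
  total <- 2L * m
  if (total > n * (n - 1L)) return(list())
  res <- list()
  seqs <- vector("list", 64L)
  recurse <- function(remaining, slots, cap, acc) {
    if (slots == 0L) {
      if (remaining == 0L) {
        s <- unlist(acc)
        if (igraph::is_graphical(s)) res[[length(res) + 1L]] <<- s
      }
      return(invisible())
    }
    hi <- min(cap, remaining)
    lo <- ceiling(remaining / slots) # parts are non-increasing
    if (hi < 0L) return(invisible())
    for (v in hi:0) {
      if (v * slots < remaining) break
      recurse(remaining - v, slots - 1L, v, c(acc, list(v)))
    }
    invisible()
  }
  recurse(total, n, n - 1L, list())
  res
}

#' Maximum degree variance over graphs with fixed order and size
#'
#' The denominator of the normalized degree-variance measure: the maximum
#' of HS over all graphs with the same number of nodes and edges.  Because
#' the variance depends only on the degree sequence and every graphical
#' sequence is realizable, the maximum is taken over graphical degree
#' sequences.  Exhaustive for n <= 10; above that a central/peripheral
#' search is used (sequences with `a` nodes of degree n - 1, one
#' intermediate node, and the rest at degree `a`), which reflects the known
#' extremal structure but is flagged approximate.
#'
#' @param n Node count.
#' @param m Edge count.
#' @return Maximum HS value; attribute `exact` says whether the search was
#'   exhaustive.
#' @export
max_hs_value <- function(n, m) {
  stopifnot(n >= 1L, m >= 0L, m <= n * (n - 1L) / 2L)
  key <- sprintf("maxhs:%d:%d", n, m)
  if (!is.null(.het_cache[[key]])) return(.het_cache[[key]])
  variance_of <- function(s) mean((s - mean(s))^2)
  if (n <= 10L) {
    seqs <- enumerate_graphical_sequences(n, m)
    val <- if (length(seqs)) max(vapply(seqs, variance_of, numeric(1))) else 0
    attr(val, "exact") <- TRUE
  } else {
    best <- 0
    total <- 2L * m
    for (a in 0:(n - 1L)) {
      # a central nodes at degree n-1, one node at degree d, rest at degree a
      rest <- n - a - 1L
      d <- total - a * (n - 1L) - rest * a
      if (d < 0L || d > n - 1L) next
      s <- sort(c(rep(n - 1L, a), d, rep(a, rest)), decreasing = TRUE)
      if (max(s) > n - 1L || !igraph::is_graphical(s)) next
      best <- max(best, variance_of(s))
    }
    val <- best
    attr(val, "exact") <- FALSE
  }
  .het_cache[[key]] <- val
  val
}

# Smallest attainable maximum degree over graphs with n nodes and m edges
# (used to validate the density-normalized centralization convention).
min_attainable_kmax <- function(n, m) {
  seqs <- enumerate_graphical_sequences(n, m)
  if (!length(seqs)) return(NA_integer_)
  min(vapply(seqs, max, numeric(1)))
}
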