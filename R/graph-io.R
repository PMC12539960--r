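# Graph representation, validation and file I/O.
#
# Graphs are plain igraph objects: undirected, simple (no loops or multiple
# edges), with opaque string labels stored in the vertex attribute `name`.

#' Validate a graph for use with the heterogeneity framework
#'
#' Checks that `graph` is an undirected simple igraph object with at least
#' one node, and that every vertex carries a `name` label (labels are
#' assigned from the vertex index when missing).
#'
#' @param graph An igraph object.
#' @return The validated (possibly relabelled) graph, invisibly usable.
#' @export
check_graph <- function(graph) {
  if (!igraph::is_igraph(graph)) {
    stop("`graph` must be an igraph object", call. = FALSE)
  }
  if (igraph::is_directed(graph)) {
    stop("directed graphs are not supported", call. = FALSE)
  }
  if (igraph::vcount(graph) < 1L) {
    stop("graph must have at least one node", call. = FALSE)
  }
  if (igraph::any_loop(graph) || igraph::any_multiple(graph)) {
    stop("graph must be simple: no self-loops or duplicate edges",
         call. = FALSE)
  }
  if (!("name" %in% igraph::vertex_attr_names(graph))) {
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  }
  graph
}

#' Load a graph from an edge-list or GML file
#'
#' The edge-list format is plain text with exactly two whitespace-separated
#' node labels per line; lines starting with `#` and blank lines are
#' ignored.  Self-loops and duplicate (unordered) edges are rejected.  GML
#' files are read through igraph and restricted to undirected simple graphs.
#'
#' @param path Path to the file.
#' @param format `"edgelist"` or `"gml"`.
#' @return An igraph object with vertex `name` labels.
#' @examples
#' f <- tempfile()
#' writeLines(c("1 2", "1 3", "1 4"), f)
#' g <- load_graph(f)
#' igraph::ecount(g) # 3: the star on 4 nodes
#' @export
load_graph <- function(path, format = c("edgelist", "gml")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (format == "gml") {
    g <- igraph::read_graph(path, format = "gml")
    if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "each")
    va <- igraph::vertex_attr_names(g)
    if ("label" %in% va) {
      igraph::V(g)$name <- as.character(igraph::V(g)$label)
    } else if ("id" %in% va && !("name" %in% va)) {
      igraph::V(g)$name <- as.character(igraph::V(g)$id)
    }
    return(check_graph(g))
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  nt <- lengths(toks)
  if (any(nt != 2L)) {
    bad <- idx[which(nt != 2L)[1L]]
    stop(sprintf("parse error at line %d: expected two whitespace-separated labels, got %d",
                 bad, nt[which(nt != 2L)[1L]]), call. = FALSE)
  }
  if (length(toks) == 0L) {
    stop("edge list is empty", call. = FALSE)
  }
  ends <- do.call(rbind, toks)
  loops <- ends[, 1L] == ends[, 2L]
  if (any(loops)) {
    stop(sprintf("self-loop at line %d: '%s'", idx[which(loops)[1L]],
                 ends[which(loops)[1L], 1L]), call. = FALSE)
  }
  key <- paste(pmin(ends[, 1L], ends[, 2L]), pmax(ends[, 1L], ends[, 2L]))
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop(sprintf("duplicate edge at line %d: {%s, %s}", idx[d],
                 ends[d, 1L], ends[d, 2L]), call. = FALSE)
  }
  g <- igraph::graph_from_edgelist(ends, directed = FALSE)
  check_graph(g)
}

#' Save a graph to an edge-list or GML file
#'
#' Edge-list output is canonical and byte-stable: each edge is written with
#' its endpoints in sorted order and lines are sorted.  The edge-list format
#' cannot represent isolated nodes; these are dropped with a warning.  GML
#' preserves isolated nodes.
#'
#' @param graph An igraph object.
#' @param path Destination path.
#' @param format `"edgelist"` or `"gml"`.
#' @return Invisibly, `path`.
#' @export
save_graph <- function(graph, path, format = c("edgelist", "gml")) {
  graph <- check_graph(graph)
  format <- match.arg(format)
  if (format == "gml") {
    igraph::write_graph(graph, path, format = "gml")
    return(invisible(path))
  }
  if (any(igraph::degree(graph) == 0L)) {
    warning("edge-list format drops isolated nodes; use GML to preserve them",
            call. = FALSE)
  }
  el <- igraph::as_edgelist(graph, names = TRUE)
  if (nrow(el) > 0L) {
    lines <- sort(paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L])))
  } else {
    lines <- character(0)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Basic graph statistics
#'
#' Node and edge counts, density 2m / (n (n - 1)) (0 for n = 1), mean,
#' maximum and minimum degree, and connectivity.
#'
#' @param graph An igraph object.
#' @return A list with elements `n`, `m`, `density`, `mean_degree`,
#'   `max_degree`, `min_degree`, `connected`.
#' @examples
#' graph_stats(gen_named("star", 4))$density # 0.5
#' @export
graph_stats <- function(graph) {
  graph <- check_graph(graph)
  n <- igraph::vcount(graph)
  m <- igraph::ecount(graph)
  degs <- igraph::degree(graph)
  list(
    n = n,
    m = m,
    density = if (n >= 2L) 2 * m / (n * (n - 1)) else 0,
    mean_degree = 2 * m / n,
    max_degree = max(degs),
    min_degree = min(degs),
    connected = igraph::is_connected(graph)
  )
}

#' Degree sequence of a graph
#'
#' @param graph An igraph object.
#' @return Integer vector of node degrees, in node order.
#' @export
degree_sequence <- function(graph) {
  graph <- check_graph(graph)
  as.integer(igraph::degree(graph))
}

#' Empirical degree distribution
#'
#' Counts of nodes per degree value, together with the node count, giving
#' the empirical distribution P(k) = n_k / n.
#'
#' @param x An igraph object, an integer degree vector, or an existing
#'   `degree_dist`.
#' @return An object of class `degree_dist`: a list with `n` (node count)
#'   and `counts` (named integer vector, names are degree values).
#' @examples
#' d <- degree_dist(gen_named("star", 4))
#' d$counts # 1 -> 3, 3 -> 1
#' @export
degree_dist <- function(x) {
  if (inherits(x, "degree_dist")) return(x)
  degs <- if (igraph::is_igraph(x)) degree_sequence(x) else as.integer(x)
  if (length(degs) < 1L) stop("empty degree sequence", call. = FALSE)
  tab <- table(degs)
  out <- list(n = length(degs),
              counts = stats::setNames(as.integer(tab), names(tab)))
  class(out) <- "degree_dist"
  out
}

#' @export
print.degree_dist <- function(x, ...) {
  cat("degree distribution over", x$n, "nodes\n")
  print(data.frame(degree = as.integer(names(x$counts)),
                   count = unname(x$counts),
                   p = unname(x$counts) / x$n))
  invisible(x)
}

# P(k) vector of a degree_dist
dist_probs <- function(dist) unname(dist$counts) / dist$n
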