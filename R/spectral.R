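# Spectral radius of the adjacency matrix.

#' Spectral radius (largest adjacency eigenvalue)
#'
#' For small graphs (n <= 500) a dense symmetric eigensolver is used.  For
#' larger graphs the value is obtained by power iteration on A + I; the
#' shift makes the dominant eigenvalue of the iterated matrix unique in
#' modulus on connected graphs (bipartite graphs have eigenvalue pairs
#' +/- lambda that would otherwise make the iteration oscillate).  On
#' connected graphs the result satisfies mean degree <= lambda_1 <= max
#' degree.
#'
#' @param graph An igraph object.
#' @param tol Convergence tolerance for the power iteration.
#' @param max_iter Maximum number of iterations before failing.
#' @return The largest eigenvalue of the adjacency matrix.
#' @examples
#' spectral_radius(gen_named("complete", 4)) # 3
#' spectral_radius(gen_named("star", 4))     # sqrt(3)
#' @export
spectral_radius <- function(graph, tol = 1e-10, max_iter = 1e5) {
  graph <- check_graph(graph)
  n <- igraph::vcount(graph)
  if (igraph::ecount(graph) == 0L) return(0)
  if (n <= 500L) {
    a <- igraph::as_adjacency_matrix(graph, sparse = FALSE)
    return(max(eigen(a, symmetric = TRUE, only.values = TRUE)$values))
  }
  a <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  x <- rep(1 / sqrt(n), n)
  lam <- 0
  for (it in seq_len(max_iter)) {
    y <- as.numeric(a %*% x) + x   # (A + I) x
    nrm <- sqrt(sum(y * y))
    y <- y / nrm
    lam_new <- sum(y * (as.numeric(a %*% y) + y))
    if (abs(lam_new - lam) < tol) return(lam_new - 1)
    lam <- lam_new
    x <- y
  }
  stop(sprintf("power iteration did not converge to tol %g in %d iterations",
               tol, max_iter), call. = FALSE)
}
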