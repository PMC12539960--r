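# The heterogeneity measure framework: generic class evaluators, the
# battery of twelve named measures, and normalized variants.
#
# Internally every evaluator works on a light structure with the node
# count, the integer degree vector and (for graph measures) the two-column
# edge index matrix, so that manipulation and compliance code can evaluate
# thousands of perturbed graphs cheaply and so that uniform degree shifts
# can be expressed as an explicit degree override on a fixed edge set.

# ---- internal representation -------------------------------------------

as_hstruct <- function(graph, degrees = NULL) {
  if (inherits(graph, "hstruct")) {
    s <- graph
  } else if (igraph::is_igraph(graph)) {
    graph <- check_graph(graph)
    s <- structure(list(
      n = igraph::vcount(graph),
      m = igraph::ecount(graph),
      degs = as.numeric(igraph::degree(graph)),
      edges = igraph::as_edgelist(graph, names = FALSE),
      graph = graph
    ), class = "hstruct")
  } else if (is.numeric(graph)) {
    s <- structure(list(n = length(graph), m = sum(graph) / 2,
                        degs = as.numeric(graph), edges = NULL, graph = NULL),
                   class = "hstruct")
  } else {
    stop("expected an igraph object or a numeric degree vector", call. = FALSE)
  }
  if (!is.null(degrees)) {
    stopifnot(length(degrees) == s$n)
    s$degs <- as.numeric(degrees)
    s$m <- sum(degrees) / 2
  }
  s
}

need_edges <- function(s, what) {
  if (is.null(s$edges)) {
    stop(what, " needs the edge set, not just a degree sequence",
         call. = FALSE)
  }
}

no_isolated <- function(s, what) {
  if (any(s$degs == 0)) {
    bad <- which(s$degs == 0)[1L]
    lbl <- if (!is.null(s$graph)) igraph::V(s$graph)$name[bad] else bad
    stop(what, " is undefined for isolated nodes (node ", lbl,
         " has degree 0)", call. = FALSE)
  }
}

# ---- measure specifications and generic class evaluators ----------------

#' Construct a measure specification
#'
#' A `het_spec` bundles the ingredients of the generic class formulas: the
#' measure class, the scaling rule `c` (a function of the structure), the
#' convex aggregator `g` (minimum 0 at 0), the degree statistic `h`
#' (global dispersion only), the degree transform `f` (pairwise classes),
#' and applicability requirements.
#'
#' @param name Identifier.
#' @param mclass One of `"global_dispersion"`, `"adjacent_dispersion"`,
#'   `"pairwise_dispersion"`, `"adjacent_expected"`, `"pairwise_expected"`,
#'   `"special"`.
#' @param c_fun Function(n, m, degs) returning the scaling factor.
#' @param g Convex aggregation function with g(0) = 0.
#' @param h Degree statistic (function of the degree vector), for the
#'   global dispersion class.
#' @param f Degree transform, for the pairwise classes.
#' @param requires Character subset of `c("connected", "no_isolated_nodes",
#'   "n_ge_3")`.
#' @return An object of class `het_spec`.
#' @export
het_spec <- function(name, mclass, c_fun = function(n, m, degs) 1,
                     g = abs, h = mean, f = identity,
                     requires = character(0)) {
  stopifnot(mclass %in% c("global_dispersion", "adjacent_dispersion",
                          "pairwise_dispersion", "adjacent_expected",
                          "pairwise_expected", "special"))
  if (abs(g(0)) > 1e-12) {
    stop("aggregator g must have g(0) = 0", call. = FALSE)
  }
  structure(list(name = name, mclass = mclass, c_fun = c_fun, g = g, h = h,
                 f = f, requires = requires), class = "het_spec")
}

#' Evaluate a global dispersion aggregation measure
#'
#' The class formula c * sum_i g(k_i - h(K)): deviations of all degrees
#' from a degree statistic of interest (maximum or mean), aggregated by a
#' convex function and scaled.
#'
#' @param graph An igraph object or numeric degree vector.
#' @param spec A `het_spec` with `mclass = "global_dispersion"`.
#' @param degrees Optional explicit degree vector overriding the graph's.
#' @return Numeric value.
#' @export
eval_global_dispersion <- function(graph, spec, degrees = NULL) {
  stopifnot(inherits(spec, "het_spec"), spec$mclass == "global_dispersion")
  s <- as_hstruct(graph, degrees)
  spec$c_fun(s$n, s$m, s$degs) * sum(spec$g(s$degs - spec$h(s$degs)))
}

#' Evaluate an adjacent pairwise dispersion aggregation measure
#'
#' The class formula c * sum_{edges} g(f(k_i) - f(k_j)): transformed degree
#' differences across connected node pairs only, capturing local
#' topological irregularity.
#'
#' @inheritParams eval_global_dispersion
#' @param spec A `het_spec` with `mclass = "adjacent_dispersion"`.
#' @return Numeric value.
#' @export
eval_adjacent_dispersion <- function(graph, spec, degrees = NULL) {
  stopifnot(inherits(spec, "het_spec"), spec$mclass == "adjacent_dispersion")
  s <- as_hstruct(graph, degrees)
  need_edges(s, spec$name)
  if ("no_isolated_nodes" %in% spec$requires) no_isolated(s, spec$name)
  fk <- spec$f(s$degs)
  val <- sum(spec$g(fk[s$edges[, 1L]] - fk[s$edges[, 2L]]))
  spec$c_fun(s$n, s$m, s$degs) * val
}

#' Evaluate a pairwise dispersion aggregation measure
#'
#' The class formula c * sum_{i < j} g(f(k_i) - f(k_j)) over all unordered
#' node pairs, connected or not: degree variability across the whole
#' network.
#'
#' @inheritParams eval_global_dispersion
#' @param spec A `het_spec` with `mclass = "pairwise_dispersion"`.
#' @return Numeric value.
#' @export
eval_pairwise_dispersion <- function(graph, spec, degrees = NULL) {
  stopifnot(inherits(spec, "het_spec"), spec$mclass == "pairwise_dispersion")
  s <- as_hstruct(graph, degrees)
  if ("no_isolated_nodes" %in% spec$requires) no_isolated(s, spec$name)
  # group by degree value: pairs within a value contribute g(0) = 0
  tab <- table(s$degs)
  vals <- as.numeric(names(tab))
  cnt <- as.numeric(tab)
  fv <- spec$f(vals)
  acc <- 0
  nv <- length(vals)
  if (nv >= 2L) {
    for (i in seq_len(nv - 1L)) {
      j <- (i + 1L):nv
      acc <- acc + sum(cnt[i] * cnt[j] * spec$g(fv[i] - fv[j]))
    }
  }
  spec$c_fun(s$n, s$m, s$degs) * acc
}

#' Evaluate the adjacent expected difference measure (HAED)
#'
#' The expected absolute degree difference across a randomly chosen
#' existing edge, with the unordered degree-pair probability estimated
#' empirically from the edge set:
#' HAED = sum_edges |k_i - k_j| * freq(degree pair of the edge)
#'      = (1/m) * sum_pairs count(k, l)^2 * |k - l|.
#'
#' @inheritParams eval_global_dispersion
#' @return Numeric value.
#' @export
eval_adjacent_expected <- function(graph, degrees = NULL) {
  s <- as_hstruct(graph, degrees)
  need_edges(s, "HAED")
  if (nrow(s$edges) == 0L) stop("HAED is undefined on an empty edge set",
                                call. = FALSE)
  d1 <- s$degs[s$edges[, 1L]]
  d2 <- s$degs[s$edges[, 2L]]
  a <- pmin(d1, d2); b <- pmax(d1, d2)
  key <- paste(a, b)
  cnt <- table(key)
  diffs <- abs(a - b)[match(names(cnt), key)]
  sum(as.numeric(cnt)^2 * diffs) / nrow(s$edges)
}

#' Evaluate a pairwise expected difference measure (HPED family)
#'
#' The expected absolute degree difference between two randomly chosen
#' nodes, summed over ordered node pairs (the diagonal contributes zero):
#' `"HHW"` uses the uniform node convention P = 1/n and c = 1/(2 kbar),
#' yielding the Gini coefficient of the degrees, bounded by `[0, 1]`;
#' `"HL"` attaches degree-frequency weights P(k) = n_k / n to each node
#' term with c = 1/kbar.  `"HPED"` is the battery preset and equals the HL
#' convention.  `"HL_value"` is the value-summation cousin — the plain
#' relative mean absolute difference E|K - L| / kbar over degree *values*
#' weighted by P — which is replication-invariant and orders power-law
#' networks above Erdos-Renyi ones, unlike the node-pair form.
#'
#' @inheritParams eval_global_dispersion
#' @param preset `"HPED"`, `"HHW"`, `"HL"` or `"HL_value"`.
#' @return Numeric value.
#' @export
eval_pairwise_expected <- function(graph,
                                   preset = c("HPED", "HHW", "HL",
                                              "HL_value"),
                                   degrees = NULL) {
  preset <- match.arg(preset)
  s <- as_hstruct(graph, degrees)
  kbar <- mean(s$degs)
  if (kbar == 0) stop(preset, " is undefined when the mean degree is 0",
                      call. = FALSE)
  if (preset == "HHW") {
    k <- sort(s$degs)
    n <- s$n
    # ordered-pair sum of |ki - kj| = 2 * sum_j (2j - 1 - n) k_(j), ascending
    ordered_sum <- 2 * sum((2 * seq_len(n) - 1 - n) * k)
    return(ordered_sum / (2 * kbar * n^2))
  }
  # HL / HPED: group by degree value
  tab <- table(s$degs)
  vals <- as.numeric(names(tab))
  cnt <- as.numeric(tab)
  pw <- if (preset == "HL_value") 1 else 2  # node form weights each value by n_k^2
  acc <- 0
  nv <- length(vals)
  if (nv >= 2L) {
    for (i in seq_len(nv - 1L)) {
      j <- (i + 1L):nv
      acc <- acc + 2 * sum(cnt[i]^pw * cnt[j]^pw * abs(vals[i] - vals[j]))
    }
  }
  acc / (s$n^2 * kbar)
}

# ---- battery presets ----------------------------------------------------

#' Degree-centralization sum (HHG)
#'
#' Sum of differences between the maximum degree and each node degree:
#' `sum_i (kmax - k_i)`.
#'
#' @param graph An igraph object or numeric degree vector.
#' @param degrees Optional explicit degree vector overriding the graph's.
#' @return Numeric value.
#' @examples
#' het_hhg(gen_named("star", 4)) # 6
#' @export
het_hhg <- function(graph, degrees = NULL) {
  s <- as_hstruct(graph, degrees)
  sum(max(s$degs) - s$degs)
}

#' Freeman degree centralization (HF)
#'
#' HHG normalized by its maximum over graphs with n nodes, attained by the
#' star or wheel: `(n - 1)(n - 2)`.  Equals 1 exactly on stars.
#'
#' @inheritParams het_hhg
#' @return Numeric value.
#' @examples
#' het_hf(gen_named("star", 7)) # 1
#' @export
het_hf <- function(graph, degrees = NULL) {
  s <- as_hstruct(graph, degrees)
  if (s$n < 3) stop("HF is undefined for n < 3 (denominator 0)", call. = FALSE)
  het_hhg(s) / ((s$n - 1) * (s$n - 2))
}

#' Density-normalized degree centralization (HB)
#'
#' Excess of the maximum degree over the smallest maximum degree attainable
#' at the graph's density, relative to the largest attainable excess:
#' `(kmax - ceil(2m/n)) / (min(n - 1, m) - ceil(2m/n))`.  When the
#' denominator is zero (null and complete graphs, and other forced-kmax
#' cases) the value is 0 with a warning.
#'
#' @inheritParams het_hhg
#' @return Numeric value in `[0, 1]`.
#' @export
het_hb <- function(graph, degrees = NULL) {
  s <- as_hstruct(graph, degrees)
  if (s$n < 2) stop("HB is undefined for n < 2", call. = FALSE)
  lo <- ceiling(2 * s$m / s$n)
  hi <- min(s$n - 1, s$m)
  if (hi - lo == 0) {
    warning("HB: maximum degree is forced at this density; returning 0",
            call. = FALSE)
    return(0)
  }
  (max(s$degs) - lo) / (hi - lo)
}

#' Degree variance (HS)
#'
#' `1/n * sum_i (k_i - kbar)^2`, the population variance of the degrees.
#'
#' @inheritParams het_hhg
#' @return Numeric value.
#' @examples
#' het_hs(gen_named("star", 4)) # 0.75
#' @export
het_hs <- function(graph, degrees = NULL) {
  s <- as_hstruct(graph, degrees)
  mean((s$degs - mean(s$degs))^2)
}

#' Generalized dispersion about the mean (phi-version of HS)
#'
#' `1/n * sum_i phi(k_i) - phi(kbar)` for a convex non-decreasing `phi`;
#' `phi = square` recovers the degree variance.
#'
#' @inheritParams het_hhg
#' @param phi Convex non-decreasing function on the non-negative integers.
#' @return Numeric value.
#' @export
het_hs_phi <- function(graph, phi = function(x) x^2, degrees = NULL) {
  s <- as_hstruct(graph, degrees)
  mean(phi(s$degs)) - phi(mean(s$degs))
}

#' Normalized degree variance (HS')
#'
#' HS divided by the maximum degree variance over graphs with the same
#' number of nodes and edges (see [max_hs_value()]).  A zero denominator
#' (sizes that force regularity) yields 0 with a warning.
#'
#' @inheritParams het_hhg
#' @return Numeric value in `[0, 1]`.
#' @export
het_hs_norm <- function(graph, degrees = NULL) {
  s <- as_hstruct(graph, degrees)
  mx <- max_hs_value(s$n, as.integer(round(s$m)))
  num <- het_hs(s)
  if (mx == 0) {
    warning("HS': only regular graphs exist at this (n, m); returning 0",
            call. = FALSE)
    return(0)
  }
  num / as.numeric(mx)
}

#' Total absolute deviation from the mean degree (HN)
#'
#' `sum_i |k_i - kbar|`.
#'
#' @inheritParams het_hhg
#' @return Numeric value.
#' @export
het_hn <- function(graph, degrees = NULL) {
  s <- as_hstruct(graph, degrees)
  sum(abs(s$degs - mean(s$degs)))
}

#' Albertson irregularity (HA)
#'
#' Total edge imbalance: `sum_{edges} |k_i - k_j|`.
#'
#' @inheritParams het_hhg
#' @return Numeric value.
#' @export
het_ha <- function(graph, degrees = NULL) {
  s <- as_hstruct(graph, degrees)
  need_edges(s, "HA")
  sum(abs(s$degs[s$edges[, 1L]] - s$degs[s$edges[, 2L]]))
}

#' Estrada heterogeneity (HE)
#'
#' `sum_{edges} (k_i^{-1/2} - k_j^{-1/2})^2`.  On graphs without isolated
#' nodes this equals `n - 2 * R_{-1/2}` where `R_{-1/2}` is the Randic
#' index.  Isolated nodes are rejected (the transform is undefined at
#' degree 0).
#'
#' @inheritParams het_hhg
#' @return Numeric value.
#' @export
het_he <- function(graph, degrees = NULL) {
  s <- as_hstruct(graph, degrees)
  need_edges(s, "HE")
  no_isolated(s, "HE")
  f <- 1 / sqrt(s$degs)
  sum((f[s$edges[, 1L]] - f[s$edges[, 2L]])^2)
}

#' Randic index R_{-1/2}
#'
#' `sum_{edges} (k_i k_j)^{-1/2}`.
#'
#' @inheritParams het_hhg
#' @return Numeric value.
#' @export
randic_index <- function(graph, degrees = NULL) {
  s <- as_hstruct(graph, degrees)
  need_edges(s, "Randic index")
  no_isolated(s, "Randic index")
  sum(1 / sqrt(s$degs[s$edges[, 1L]] * s$degs[s$edges[, 2L]]))
}

#' Normalized Estrada heterogeneity (HE')
#'
#' `(n - 2 R_{-1/2}) / (n - 2 sqrt(n - 1))`: 0 on regular graphs, 1 on
#' stars.
#'
#' @inheritParams het_hhg
#' @return Numeric value.
#' @export
het_he_norm <- function(graph, degrees = NULL) {
  s <- as_hstruct(graph, degrees)
  if (s$n < 3) stop("HE' is undefined for n <= 2", call. = FALSE)
  het_he(s) / (s$n - 2 * sqrt(s$n - 1))
}

#' Pairwise Albertson irregularity (HAp)
#'
#' `sum_{i < j} |k_i - k_j|` over all unordered node pairs, computed in
#' O(n log n) from the sorted degrees.
#'
#' @inheritParams het_hhg
#' @return Numeric value.
#' @export
het_hap <- function(graph, degrees = NULL) {
  s <- as_hstruct(graph, degrees)
  k <- sort(s$degs)
  sum((2 * seq_len(s$n) - 1 - s$n) * k)
}

#' Pairwise Estrada heterogeneity (HEp)
#'
#' `sum_{i < j} (k_i^{-1/2} - k_j^{-1/2})^2` over all unordered node pairs.
#'
#' @inheritParams het_hhg
#' @return Numeric value.
#' @export
het_hep <- function(graph, degrees = NULL) {
  s <- as_hstruct(graph, degrees)
  no_isolated(s, "HEp")
  spec <- het_spec("HEp", "pairwise_dispersion", g = function(x) x^2,
                   f = function(k) 1 / sqrt(k))
  eval_pairwise_dispersion(s, spec)
}

#' Adjacent expected difference (HAED)
#'
#' See [eval_adjacent_expected()].
#'
#' @inheritParams het_hhg
#' @return Numeric value.
#' @export
het_haed <- function(graph, degrees = NULL) {
  eval_adjacent_expected(graph, degrees = degrees)
}

#' Pairwise expected difference, battery preset (HPED)
#'
#' The relative mean absolute degree difference with degree-frequency
#' weights (the HL convention); see [eval_pairwise_expected()].
#'
#' @inheritParams het_hhg
#' @return Numeric value.
#' @export
het_hped <- function(graph, degrees = NULL) {
  eval_pairwise_expected(graph, "HPED", degrees = degrees)
}

#' Gini-type degree inequality (HHW)
#'
#' Half the relative mean absolute degree difference under the uniform
#' node distribution: the Gini coefficient of the degrees, in `[0, 1]`.
#'
#' @inheritParams het_hhg
#' @return Numeric value.
#' @export
het_hhw <- function(graph, degrees = NULL) {
  eval_pairwise_expected(graph, "HHW", degrees = degrees)
}

#' Relative mean absolute degree difference with frequency weights (HL)
#'
#' @inheritParams het_hhg
#' @return Numeric value.
#' @export
het_hl <- function(graph, degrees = NULL) {
  eval_pairwise_expected(graph, "HL", degrees = degrees)
}

#' Spectral irregularity (HCS)
#'
#' The Collatz-Sinogowitz defect: largest adjacency eigenvalue minus mean
#' degree.  Requires a connected graph; zero exactly on regular graphs.
#'
#' @param graph An igraph object (a degree sequence is not sufficient).
#' @param tol Eigensolver tolerance passed to [spectral_radius()].
#' @return Numeric value, non-negative within `tol`.
#' @export
het_hcs <- function(graph, tol = 1e-10) {
  if (inherits(graph, "hstruct")) graph <- graph$graph
  if (is.null(graph) || !igraph::is_igraph(graph)) {
    stop("HCS needs the graph itself, not just a degree sequence",
         call. = FALSE)
  }
  graph <- check_graph(graph)
  if (!igraph::is_connected(graph)) {
    stop("HCS requires a connected graph", call. = FALSE)
  }
  spectral_radius(graph, tol = tol) - mean(igraph::degree(graph))
}

#' Degree diversity (HJ)
#'
#' `(1/n) * sum_{k: P(k) > 0} (1 - P(k))^2`: high when many distinct degree
#' values exist, maximal on completely diverse graphs.  This is the squared
#' quantity of the defining formula.
#'
#' @param x An igraph object, numeric degree vector, or `degree_dist`.
#' @return Numeric value.
#' @export
het_hj <- function(x) {
  d <- if (inherits(x, "degree_dist")) x else {
    if (inherits(x, "hstruct")) degree_dist(x$degs) else degree_dist(x)
  }
  p <- dist_probs(d)
  sum((1 - p)^2) / d$n
}

#' Normalized degree diversity (HJ')
#'
#' HJ divided by its complete-heterogeneity value.  The exact denominator
#' `1 - 3/n + (n + 2)/n^3` (default) guarantees values in `[0, 1]` with 1
#' attained by completely diverse degree distributions; the asymptotic
#' variant uses the printed approximation `1 - 3/n`, which exceeds 1 for
#' small n.
#'
#' @param x An igraph object, numeric degree vector, or `degree_dist`.
#' @param exact_denominator Use the exact complete-heterogeneity value
#'   (default) rather than the asymptotic `1 - 3/n`.
#' @return Numeric value.
#' @export
het_hj_norm <- function(x, exact_denominator = TRUE) {
  d <- if (inherits(x, "degree_dist")) x else {
    if (inherits(x, "hstruct")) degree_dist(x$degs) else degree_dist(x)
  }
  n <- d$n
  if (n < 4) stop("HJ' normalization needs n >= 4", call. = FALSE)
  den <- if (exact_denominator) 1 - 3 / n + (n + 2) / n^3 else 1 - 3 / n
  het_hj(d) / den
}

# ---- registry and dispatcher -------------------------------------------

.measure_registry <- list(
  HN   = list(fun = function(s) het_hn(s),   needs_graph = FALSE,
              requires = character(0), mclass = "global_dispersion",
              addition = "degree_shift"),
  HS   = list(fun = function(s) het_hs(s),   needs_graph = FALSE,
              requires = character(0), mclass = "global_dispersion",
              addition = "degree_shift"),
  HF   = list(fun = function(s) het_hf(s),   needs_graph = FALSE,
              requires = "n_ge_3", mclass = "global_dispersion",
              addition = "degree_shift"),
  HHG  = list(fun = function(s) het_hhg(s),  needs_graph = FALSE,
              requires = character(0), mclass = "global_dispersion",
              addition = "degree_shift"),
  HA   = list(fun = function(s) het_ha(s),   needs_graph = TRUE,
              requires = character(0), mclass = "adjacent_dispersion",
              addition = "degree_shift"),
  HE   = list(fun = function(s) het_he(s),   needs_graph = TRUE,
              requires = "no_isolated_nodes", mclass = "adjacent_dispersion",
              addition = "degree_shift"),
  HAp  = list(fun = function(s) het_hap(s),  needs_graph = FALSE,
              requires = character(0), mclass = "pairwise_dispersion",
              addition = "degree_shift"),
  HEp  = list(fun = function(s) het_hep(s),  needs_graph = FALSE,
              requires = "no_isolated_nodes", mclass = "pairwise_dispersion",
              addition = "degree_shift"),
  HAED = list(fun = function(s) het_haed(s), needs_graph = TRUE,
              requires = "m_ge_1", mclass = "adjacent_expected",
              addition = "realization"),
  HPED = list(fun = function(s) het_hped(s), needs_graph = FALSE,
              requires = "m_ge_1", mclass = "pairwise_expected",
              addition = "degree_shift"),
  HJ   = list(fun = function(s) het_hj(s),   needs_graph = FALSE,
              requires = character(0), mclass = "special",
              addition = "degree_shift"),
  HCS  = list(fun = function(s) het_hcs(s),  needs_graph = TRUE,
              requires = "connected", mclass = "special",
              addition = "realization")
)

#' Names of the twelve battery measures
#'
#' @return Character vector of measure names.
#' @export
het_measures <- function() names(.measure_registry)

#' Measure registry metadata
#'
#' Class, applicability requirements and addition-principle semantics for
#' every battery measure.
#'
#' @return A data frame with one row per measure.
#' @export
het_registry <- function() {
  data.frame(
    measure = names(.measure_registry),
    mclass = vapply(.measure_registry, `[[`, "", "mclass"),
    needs_graph = vapply(.measure_registry, `[[`, TRUE, "needs_graph"),
    requires = vapply(.measure_registry, function(x)
      paste(x$requires, collapse = ","), ""),
    addition_semantics = vapply(.measure_registry, `[[`, "", "addition"),
    row.names = NULL
  )
}

measure_applicable <- function(name, s) {
  reg <- .measure_registry[[name]]
  if ("connected" %in% reg$requires &&
      !(is.null(s$graph) || igraph::is_connected(s$graph))) return(FALSE)
  if ("no_isolated_nodes" %in% reg$requires && any(s$degs == 0)) return(FALSE)
  if ("n_ge_3" %in% reg$requires && s$n < 3) return(FALSE)
  if ("m_ge_1" %in% reg$requires && s$m < 1) return(FALSE)
  TRUE
}

#' Evaluate a battery measure by name
#'
#' Dispatches to the named preset under the battery conventions.  Unknown
#' names raise an error listing the available measures.
#'
#' @param graph An igraph object (or degree vector, for measures that only
#'   need degrees).
#' @param measure Measure name, one of [het_measures()].
#' @param degrees Optional explicit degree vector overriding the graph's.
#' @return Numeric value.
#' @examples
#' het_evaluate(gen_named("cycle", 4), "HS") # 0
#' @export
het_evaluate <- function(graph, measure, degrees = NULL) {
  if (!measure %in% names(.measure_registry)) {
    stop("unknown measure '", measure, "'; available: ",
         paste(names(.measure_registry), collapse = ", "), call. = FALSE)
  }
  s <- as_hstruct(graph, degrees)
  .measure_registry[[measure]]$fun(s)
}

#' Evaluate several measures on one graph
#'
#' @param graph An igraph object.
#' @param measures Character vector of measure names.
#' @param graph_id Optional identifier copied into the result.
#' @return A data frame with columns `graph`, `measure`, `value`,
#'   `warnings` (empty string when none; evaluation errors propagate).
#' @export
het <- function(graph, measures = het_measures(), graph_id = "graph") {
  s <- as_hstruct(graph)
  rows <- lapply(measures, function(nm) {
    warns <- character(0)
    val <- withCallingHandlers(
      het_evaluate(s, nm),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    data.frame(graph = graph_id, measure = nm, value = val,
               warnings = paste(warns, collapse = "; "))
  })
  do.call(rbind, rows)
}
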