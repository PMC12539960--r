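# Principle-compliance engine: decide, with witnesses, whether each
# battery measure satisfies the transfer, addition and replication
# principles, and assemble the compliance matrix.
#
# "Pass" is universally quantified over a finite, frozen battery: it
# certifies that no violation was found, while a fail carries a replayable
# witness.  Transfer demands strict decrease; addition allows no change;
# replication demands exact invariance.

#' Curated witness fixtures for the compliance battery
#'
#' Small graphs, committed as edge lists built in code, on which specific
#' measures violate specific principles.  They complement the exhaustive
#' small-graph enumeration: `hn_mean_crossing` carries the no-change
#' transfer witness for the absolute-deviation measure (degrees
#' 4,2,2,2,1,1 with mean 2), and the `highdeg_neighbourhood` graphs carry
#' transfer violations for edge-difference and expected-difference
#' measures, where the node losing an edge sits in a high-degree
#' neighbourhood.  The `hcs_*` graphs falsify the spectral defect measure
#' under transfer and under realization-based degree addition, so that no
#' verdict depends on the random battery layer.  All are synthetic search
#' products, not published networks.
#'
#' @return Named list of igraph objects.
#' @export
het_witness_graphs <- function() {
  build <- function(edges) {
    check_graph(igraph::graph_from_edgelist(
      matrix(as.character(edges), ncol = 2, byrow = TRUE), directed = FALSE))
  }
  list(
    # degrees 4,2,2,2,1,1 (mean 2): admissible move 4 -> 3 / 2 -> 3 leaves
    # sum |k - kbar| unchanged
    hn_mean_crossing = build(c(1,2, 1,3, 1,4, 1,5, 2,3, 4,6)),
    # dense core with pendant path: rewiring away from the core increases
    # edge-difference measures
    highdeg_neighbourhood_a = build(c(1,2, 1,3, 1,4, 2,3, 2,4, 3,4,
                                      1,5, 5,6, 6,7)),
    # two hubs sharing leaves: expected-difference transfer violations
    highdeg_neighbourhood_b = build(c(1,3, 1,4, 1,5, 1,6, 2,3, 2,4, 2,5,
                                      2,6, 1,7, 7,8)),
    # double star with a bridging leaf: rewiring away from the larger hub
    # raises the spectral radius faster than it is offset, so the spectral
    # defect increases
    hcs_transfer = build(c(1,2, 1,3, 1,4, 1,5, 2,6, 2,7, 3,7)),
    # sparse tree-like graph: a Havel-Hakimi realization of the uniformly
    # shifted degrees concentrates edges among high-degree nodes and
    # raises the spectral defect
    hcs_addition = build(c(1,2, 2,3, 2,4, 4,5, 5,6, 3,7, 1,8, 2,8, 5,8))
  )
}

#' Default compliance battery
#'
#' (i) every connected graph on up to `max_exhaustive` nodes (one
#' representative per isomorphism class), (ii) the curated witness
#' fixtures, (iii) `n_random` seeded Erdos-Renyi draws with 4 to 12 nodes.
#'
#' @param seed Integer seed for the random layer.
#' @param n_random Number of random graphs.
#' @param max_exhaustive Largest order enumerated exhaustively.
#' @return Named list of igraph objects.
#' @export
default_battery <- function(seed = 42L, n_random = 200L,
                            max_exhaustive = 6L) {
  battery <- list()
  for (n in seq_len(max_exhaustive)) {
    gs <- enumerate_connected_graphs(n)
    names(gs) <- sprintf("conn%d_%03d", n, seq_along(gs))
    battery <- c(battery, gs)
  }
  battery <- c(battery, het_witness_graphs())
  rg <- with_seed(seed, {
    lapply(seq_len(n_random), function(i) {
      n <- sample(4:12, 1L)
      p <- stats::runif(1, 0.2, 0.8)
      label_nodes(igraph::sample_gnp(n, p))
    })
  })
  names(rg) <- sprintf("rand_%03d", seq_len(n_random))
  c(battery, rg)
}

new_verdict <- function(measure, principle, pass, witness = NULL,
                        n_graphs = 0L, n_cases = 0L, skipped = character(0)) {
  structure(list(measure = measure, principle = principle, pass = pass,
                 witness = witness, n_graphs = n_graphs, n_cases = n_cases,
                 skipped = skipped),
            class = "compliance_verdict")
}

#' @export
print.compliance_verdict <- function(x, ...) {
  cat(sprintf("%s / %s: %s (%d graphs, %d cases examined)\n", x$measure,
              x$principle, if (x$pass) "pass" else "FAIL", x$n_graphs,
              x$n_cases))
  if (!is.null(x$witness)) {
    cat(sprintf("  witness on '%s': before = %.9g, after = %.9g\n",
                x$witness$graph_id, x$witness$before, x$witness$after))
  }
  invisible(x)
}

transfer_after_struct <- function(s, p, u, v, need_graph = FALSE) {
  degs2 <- s$degs
  degs2[u] <- degs2[u] - 1
  degs2[v] <- degs2[v] + 1
  e <- s$edges
  hit <- which((e[, 1L] == p & e[, 2L] == u) | (e[, 1L] == u & e[, 2L] == p))[1L]
  e[hit, ] <- c(p, v)
  g2 <- NULL
  if (need_graph) {
    g2 <- igraph::make_graph(t(e), n = s$n, directed = FALSE)
    g2 <- label_nodes(g2)
  }
  structure(list(n = s$n, m = s$m, degs = degs2, edges = e, graph = g2),
            class = "hstruct")
}

#' Check the transfer principle for one measure
#'
#' Pass iff every admissible transfer move on every applicable battery
#' graph strictly decreases the measure (tolerance `tol`); the first
#' violation is recorded as a replayable witness.  Graphs where the measure
#' is inapplicable, and moves whose result violates the measure's
#' requirements (e.g. a spectral measure on a move that disconnects the
#' graph), are skipped and logged.
#'
#' @param measure Measure name.
#' @param battery Named list of igraph objects.
#' @param tol Strictness tolerance.
#' @param stop_at_first Stop scanning after the first violation (default).
#' @return A `compliance_verdict`.
#' @export
check_transfer <- function(measure, battery, tol = 1e-9,
                           stop_at_first = TRUE) {
  if (is.null(names(battery))) names(battery) <- seq_along(battery)
  reg <- .measure_registry[[measure]]
  n_graphs <- 0L; n_cases <- 0L
  skipped <- character(0)
  witness <- NULL
  for (gid in names(battery)) {
    s <- as_hstruct(battery[[gid]])
    if (!measure_applicable(measure, s)) {
      skipped <- c(skipped, gid)
      next
    }
    moves <- enumerate_transfers(s$graph)
    if (nrow(moves) == 0L) next
    n_graphs <- n_graphs + 1L
    before <- reg$fun(s)
    for (r in seq_len(nrow(moves))) {
      p <- moves$pivot[r]; u <- moves$from[r]; v <- moves$to[r]
      s2 <- transfer_after_struct(s, p, u, v,
                                  need_graph = measure == "HCS")
      if (!measure_applicable(measure, s2)) next
      after <- reg$fun(s2)
      n_cases <- n_cases + 1L
      if (after > before - tol) {
        witness <- list(graph_id = gid, graph = s$graph,
                        move = moves[r, , drop = FALSE],
                        before = before, after = after)
        if (stop_at_first) {
          return(new_verdict(measure, "transfer", FALSE, witness, n_graphs,
                             n_cases, skipped))
        }
      }
    }
  }
  new_verdict(measure, "transfer", is.null(witness), witness, n_graphs,
              n_cases, skipped)
}

# Deterministic candidate realizations of the shifted degree sequence
# k + c, for measures whose addition behaviour depends on which topology
# realizes the new degrees.
shifted_realizations <- function(graph, c, seed = 1L) {
  degs <- igraph::degree(graph)
  n <- igraph::vcount(graph)
  target <- degs + c
  out <- list()
  if (max(target) <= n - 1 && igraph::is_graphical(target)) {
    ov <- try(apply_addition(graph, c, "overlay", seed = seed),
              silent = TRUE)
    if (!inherits(ov, "try-error")) out$overlay <- ov$graph
    hh <- try(realize_sequence(target), silent = TRUE)
    if (!inherits(hh, "try-error")) out$havel_hakimi <- hh
    for (i in 1:3) {
      cf <- try(with_seed(seed + 100L + i, igraph::sample_degseq(
        target, method = "fast.heur.simple")), silent = TRUE)
      if (!inherits(cf, "try-error")) {
        out[[paste0("config_", i)]] <- label_nodes(cf)
      }
    }
  }
  out
}

#' Check the addition principle for one measure
#'
#' Uniform degree addition must not increase the measure.  Semantics are
#' per-measure (see [het_registry()]): measures built on degree values and
#' fixed-edge differences are evaluated under a degree shift (original
#' edge set, degrees k + c); measures whose value depends on which
#' topology realizes the shifted degrees (HAED, HCS) are evaluated over a
#' deterministic set of realizations of k + c — the edge-disjoint
#' c-regular overlay when one exists, a Havel-Hakimi realization, and
#' seeded configuration realizations — and fail if any realization
#' increases the value.
#'
#' @param measure Measure name.
#' @param battery Named list of igraph objects.
#' @param c_values Degree increments to test.
#' @param tol Comparison tolerance.
#' @param seed Seed for realization candidates.
#' @param stop_at_first Stop scanning after the first violation.
#' @return A `compliance_verdict`.
#' @export
check_addition <- function(measure, battery, c_values = c(1L, 2L),
                           tol = 1e-9, seed = 1L, stop_at_first = TRUE) {
  if (is.null(names(battery))) names(battery) <- seq_along(battery)
  reg <- .measure_registry[[measure]]
  n_graphs <- 0L; n_cases <- 0L
  skipped <- character(0)
  witness <- NULL
  for (gid in names(battery)) {
    s <- as_hstruct(battery[[gid]])
    if (!measure_applicable(measure, s)) {
      skipped <- c(skipped, gid)
      next
    }
    before <- reg$fun(s)
    used <- FALSE
    for (cc in c_values) {
      if (reg$addition == "degree_shift") {
        s2 <- s
        s2$degs <- s$degs + cc
        s2$m <- sum(s2$degs) / 2
        if (!measure_applicable(measure, s2)) next
        after <- reg$fun(s2)
        n_cases <- n_cases + 1L; used <- TRUE
        if (after > before + tol) {
          witness <- list(graph_id = gid, graph = s$graph,
                          move = list(c = cc, semantics = "degree_shift"),
                          before = before, after = after)
          if (stop_at_first) {
            return(new_verdict(measure, "addition", FALSE, witness,
                               n_graphs + 1L, n_cases, skipped))
          }
        }
      } else {
        cands <- shifted_realizations(s$graph, cc, seed = seed)
        for (nm in names(cands)) {
          s2 <- as_hstruct(cands[[nm]])
          if (!measure_applicable(measure, s2)) next
          after <- reg$fun(s2)
          n_cases <- n_cases + 1L; used <- TRUE
          if (after > before + tol) {
            witness <- list(graph_id = gid, graph = s$graph,
                            move = list(c = cc, semantics = nm),
                            before = before, after = after)
            if (stop_at_first) {
              return(new_verdict(measure, "addition", FALSE, witness,
                                 n_graphs + 1L, n_cases, skipped))
            }
          }
        }
      }
    }
    if (used) n_graphs <- n_graphs + 1L
  }
  new_verdict(measure, "addition", is.null(witness), witness, n_graphs,
              n_cases, skipped)
}

#' Check the replication principle for one measure
#'
#' Replication (disjoint union of x copies) must leave the measure
#' unchanged.  A measure that errors on the replicated (disconnected)
#' input fails with the error as witness.  The distribution-only diversity
#' measure HJ is checked on the degree distribution reduced to its
#' smallest integer counts, the same minimal-integer convention that
#' defines non-integer replication — under which replication is exactly
#' the identity on the distribution.
#'
#' @param measure Measure name.
#' @param battery Named list of igraph objects.
#' @param factors Integer replication factors.
#' @param tol Equality tolerance.
#' @param stop_at_first Stop scanning after the first violation.
#' @return A `compliance_verdict`.
#' @export
check_replication <- function(measure, battery, factors = c(2L, 3L),
                              tol = 1e-9, stop_at_first = TRUE) {
  if (is.null(names(battery))) names(battery) <- seq_along(battery)
  reg <- .measure_registry[[measure]]
  n_graphs <- 0L; n_cases <- 0L
  skipped <- character(0)
  witness <- NULL
  for (gid in names(battery)) {
    s <- as_hstruct(battery[[gid]])
    if (!measure_applicable(measure, s)) {
      skipped <- c(skipped, gid)
      next
    }
    n_graphs <- n_graphs + 1L
    if (measure == "HJ") {
      d0 <- reduce_distribution(degree_dist(s$degs))
      before <- het_hj(d0)
    } else {
      before <- reg$fun(s)
    }
    for (x in factors) {
      n_cases <- n_cases + 1L
      if (measure == "HJ") {
        dx <- reduce_distribution(replicate_distribution(
          degree_dist(s$degs), x))
        after <- het_hj(dx)
      } else {
        rep_g <- het_replicate(s$graph, x)
        after <- try(reg$fun(as_hstruct(rep_g)), silent = TRUE)
        if (inherits(after, "try-error")) {
          witness <- list(graph_id = gid, graph = s$graph,
                          move = list(x = x),
                          before = before,
                          after = NA_real_,
                          error = attr(after, "condition")$message)
          if (stop_at_first) {
            return(new_verdict(measure, "replication", FALSE, witness,
                               n_graphs, n_cases, skipped))
          }
          next
        }
      }
      if (is.null(witness) && abs(after - before) > tol) {
        witness <- list(graph_id = gid, graph = s$graph, move = list(x = x),
                        before = before, after = after)
        if (stop_at_first) {
          return(new_verdict(measure, "replication", FALSE, witness,
                             n_graphs, n_cases, skipped))
        }
      }
    }
  }
  new_verdict(measure, "replication", is.null(witness), witness, n_graphs,
              n_cases, skipped)
}

#' Assemble the compliance matrix
#'
#' Runs the transfer, addition and replication checks for every requested
#' measure over one battery and collects the 36 verdicts with summary
#' tallies.
#'
#' @param measures Measure names (default: the 12-measure battery).
#' @param battery Named list of igraph objects (default:
#'   [default_battery()]).
#' @param tol Tolerance passed to the checkers.
#' @return An object of class `compliance_matrix`: list with `verdicts`
#'   (list of `compliance_verdict`), `table` (measures x principles logical
#'   matrix) and `summary` (tallies: `pass_all`, `pass_none`, per-principle
#'   pass counts).
#' @export
compliance_matrix <- function(measures = het_measures(),
                              battery = default_battery(), tol = 1e-9) {
  verdicts <- list()
  tab <- matrix(NA, nrow = length(measures), ncol = 3,
                dimnames = list(measures,
                                c("transfer", "addition", "replication")))
  for (m in measures) {
    vt <- check_transfer(m, battery, tol = tol)
    va <- check_addition(m, battery, tol = tol)
    vr <- check_replication(m, battery, tol = tol)
    verdicts[[paste0(m, ".transfer")]] <- vt
    verdicts[[paste0(m, ".addition")]] <- va
    verdicts[[paste0(m, ".replication")]] <- vr
    tab[m, ] <- c(vt$pass, va$pass, vr$pass)
  }
  summary <- list(
    pass_all = sum(rowSums(tab) == 3L),
    pass_none = sum(rowSums(tab) == 0L),
    transfer_passes = sum(tab[, "transfer"]),
    addition_passes = sum(tab[, "addition"]),
    replication_passes = sum(tab[, "replication"])
  )
  structure(list(verdicts = verdicts, table = tab, summary = summary),
            class = "compliance_matrix")
}

#' @export
print.compliance_matrix <- function(x, ...) {
  disp <- ifelse(x$table, "✓", "×")
  print(as.data.frame(disp))
  cat(sprintf(
    "\npass all three: %d | transfer: %d | addition: %d | replication: %d | pass none: %d\n",
    x$summary$pass_all, x$summary$transfer_passes,
    x$summary$addition_passes, x$summary$replication_passes,
    x$summary$pass_none))
  invisible(x)
}

#' @export
as.data.frame.compliance_matrix <- function(x, ...) {
  data.frame(measure = rep(rownames(x$table), each = 3L),
             principle = rep(colnames(x$table), times = nrow(x$table)),
             pass = as.vector(t(x$table)), row.names = NULL)
}
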