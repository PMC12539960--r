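---
title: "Measuring degree and graph heterogeneity: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring degree and graph heterogeneity: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetnet)
```

## The problem

"Heterogeneity" of a network is used to mean at least three different
things: inequality in how many connections nodes have (degree
heterogeneity), structural irregularity that also depends on *which* nodes
are connected (topological graph heterogeneity), and the dominance of
central nodes over peripheral ones (centralization).  Measures built for
one notion routinely get applied under another, with confusing results:
a star is maximally heterogeneous to a centralization measure and almost
homogeneous to a degree-diversity measure.

`hetnet` implements a battery of twelve measures drawn from three generic
constructions, together with the machinery used to compare them: seeded
graph generators, three behavioural principles (transfer, addition,
replication) tested by explicit manipulations, and scaled random-graph
experiments.

## The measure classes

All measures work on a finite undirected simple graph with `n` nodes,
`m` edges, degrees `k_i`, mean degree `kbar` and degree distribution
`P(k) = n_k / n`.

**Global dispersion aggregation** — `c * sum_i g(k_i - h(K))` for a
scaling rule `c`, a convex aggregator `g` with `g(0) = 0`, and a degree
statistic `h` (maximum or mean).  Presets: `HHG = sum_i (kmax - k_i)`
(degree centralization), `HF = HHG / ((n-1)(n-2))` (its ratio to the
star/wheel maximum; exactly 1 on stars), `HS = mean((k - kbar)^2)` (degree
variance), `HN = sum_i |k_i - kbar|`.  A density-aware variant `HB`
rescales the maximum degree against the smallest and largest maximum
degree attainable at the graph's density, and `HS'` divides the variance
by its maximum over graphs with the same `(n, m)`.

**Adjacent and pairwise dispersion** — `c * sum g(f(k_i) - f(k_j))` taken
over edges (adjacent: a graph-heterogeneity view) or over all node pairs
(pairwise: a degree-only view).  With `f` the identity and `g = abs` these
are the edge-imbalance measure `HA` and its all-pairs analogue `HAp`; with
`f(k) = k^(-1/2)` and `g` the square they are `HE` and `HEp`.  `HE`
satisfies the Randić-index identity `HE = n - 2 R_{-1/2}` on graphs
without isolated nodes, which yields the normalized `HE'` with value 1 on
stars and 0 on regular graphs.

**Expected difference** — Gini-inspired: the expected absolute degree
difference across a random edge (`HAED`, with the unordered degree-pair
probability estimated from the edge set) or across random node pairs
(`HPED` family).  The uniform-node convention `HHW` is exactly the Gini
coefficient of the degree sequence; the battery preset `HPED` attaches
degree-frequency weights `P(k_i) P(k_j)` to node pairs and scales by
`1/kbar`.

**Special measures** — the spectral defect `HCS = lambda_1 - kbar`
(zero iff regular; requires a connected graph) and the degree-diversity
measure `HJ = (1/n) sum_{P(k)>0} (1 - P(k))^2`, which peaks on
"completely diverse" graphs where only one degree value repeats.

## Conventions that required a decision

The defining formulas leave several conventions open; the package fixes
them as follows and exposes the alternatives.

* **`HB` reconstruction.** The printed normalization for the
  density-aware centralization is typographically corrupt.  We use
  `(kmax - ceil(2m/n)) / (min(n-1, m) - ceil(2m/n))`, i.e. the excess of
  the maximum degree over its smallest attainable value relative to the
  largest attainable excess at that density.  Tests validate by brute
  force that `ceil(2m/n)` is exactly the minimum attainable maximum
  degree over graphical sequences at each small `(n, m)`, and that the
  null/complete extremes evaluate to 0.  The degenerate `0/0` case
  (densities that force the maximum degree) returns 0 with a warning.
* **`HJ` is the squared form.** The diversity measure is defined through
  its square; we return the squared quantity, whose
  complete-heterogeneity value is exactly `1 - 3/n + (n+2)/n^3`.  The
  normalized `HJ'` uses that exact denominator by default — the printed
  asymptotic `1 - 3/n` exceeds 1 for small n (try `het_hj_norm(x,
  exact_denominator = FALSE)` on a 4-node diverse graph) — so that
  `HJ' = 1` is attained precisely by completely diverse distributions.
* **`HPED` summation convention.** Summing `|k_i - k_j| P(k_i) P(k_j)`
  over ordered *node* pairs (the battery convention) makes the measure
  scale quadratically under replication, which is what the compliance
  matrix requires.  The cousin that sums over degree *values* — the plain
  relative mean absolute difference, equal to twice the Gini coefficient —
  is replication-invariant and, unlike the node form, ranks heavy-tailed
  networks above Erdős–Rényi ones in the sweep; it is available as
  `eval_pairwise_expected(g, "HL_value")`.  No single convention
  satisfies both published behaviours; the package pins the node form and
  documents the trade-off.
* **`HJ` under replication.** The raw graph value carries an explicit
  `1/n` factor, so x-fold replication divides it by x even though `P(k)`
  is unchanged.  Since the replication principle itself defines
  non-integer replication through minimal-integer count scaling, the
  compliance engine treats the diversity measure as a functional of the
  degree distribution reduced to its smallest integer counts, under which
  replication is the identity.  Users evaluating `het_hj()` on a
  replicated *graph* will see the `1/n` scaling; the vignette flags this
  so nobody mistakes the compliance verdict for raw-value invariance.
* **Addition semantics are per-measure.** "Increase all degrees by c"
  does not say which edges realize the new degrees.  For measures defined
  on degree values or fixed-edge differences, we shift the degree map on
  the original edge set (`apply_addition(..., "degree_shift")`).  For the
  two measures whose value depends on which topology realizes the shifted
  degrees (`HAED`, `HCS`), a c-regular edge-disjoint overlay alone cannot
  falsify the spectral defect — by Weyl's inequality
  `lambda_1(A + B) <= lambda_1(A) + c` for any c-regular overlay `B`, so
  the defect never increases that way.  The checker therefore quantifies
  over a deterministic set of realizations of the shifted sequence
  (overlay, Havel–Hakimi, seeded configuration draws) and fails a measure
  if *any* realization increases it, which is the reading under which the
  published compliance pattern is reproducible.
* **Transfer strictness.** A transfer (rewiring an edge endpoint from a
  higher-degree to a lower-degree node, order preserved: the donor must
  exceed the recipient by at least 2) must *strictly* decrease a
  compliant measure; a no-change outcome counts as a violation.  This is
  what condemns `HN`: on the committed witness with degrees
  (4,2,2,2,1,1) and mean 2, the move 4→3 / 2→3 leaves the absolute
  deviation unchanged at 4.

## Compliance is falsification, not proof

`compliance_matrix()` quantifies "pass" over a frozen finite battery:
every connected graph on up to 6 nodes (one representative per
isomorphism class — violations are isomorphism-invariant), curated
witness fixtures committed in code, and 200 random graphs with 4–12 nodes
from a frozen seed.  A pass certifies "no violation found on the
battery"; a fail carries a replayable witness (graph, move, before/after
values).  True compliance claims (e.g. for the degree variance under
transfer, where the squared-degree sum drops by exactly
`2 (k_u - k_v - 1) >= 2`) are checked as closed-form properties in the
test suite.  Enlarging the battery can only flip pass → fail, never the
reverse; a property test verifies this monotonicity on nested batteries.

## What the generators emulate

* `gen_er(n, lambda)` draws `G(n, p)` with `p = lambda/(n-1)`.
* `gen_powerlaw(n, gamma, m)` is a static fitness sampler (fitness
  `rank^(-1/(gamma-1))`) drawing exactly `m` edges, so sweep comparisons
  hold the edge count equal to the paired Erdős–Rényi draw by
  construction.
* `gen_exponential(n, mu)` draws geometric degrees on {1, 2, …} with mean
  `mu` — the discrete analogue of an exponential degree distribution —
  repairs parity, and realizes the sequence as a simple graph.  This is
  the family on which the Gini-type measure `HHW` is bounded by 0.5; for
  discrete power laws with exponent between 2 and 2.5, `HHW` sits at or
  above 0.5 (`sample_powerlaw_degrees()` draws such sequences directly,
  with a 10^6 support cutoff standing in for infinite support).
* `gen_diverse(n)` (n = 4..7) picks the canonical completely diverse
  degree sequence — exactly `n-1` distinct values, which forces
  `{1, …, n-1}` plus the smallest graphical duplicate — and realizes it
  connectedly.  The resulting fixtures, e.g. the 7-node, 12-edge graph,
  have densities 0.57–0.67, higher than the paired stars (0.29–0.5);
  star/diverse contrasts therefore mix a size and a density effect, which
  the comparison reports rather than corrects.

These generators produce idealized models: no degree correlations,
communities, clustering beyond what the models imply, or temporal
structure.  A green sweep test establishes orderings among these models
only, not behaviour on empirical networks.

## Numerical choices

* Spectral radius: dense symmetric eigensolver up to n = 500; above that,
  power iteration on `A + I` (the shift breaks the ±lambda oscillation on
  bipartite graphs) with tolerance 1e-10 and an iteration cap, erroring
  rather than returning a stale value.
* Equality and monotonicity comparisons in the compliance engine use a
  1e-9 tolerance; battery graphs are small, so genuine changes are orders
  of magnitude larger.
* `HS'` denominators come from exhaustive enumeration of graphical degree
  sequences at the given `(n, m)` up to n = 10 (equivalent to enumerating
  graphs, since the variance depends only on the degree sequence); above
  that a central/peripheral/intermediate family search is used and
  flagged approximate.
* Pairwise measures group nodes by degree value, making the sweep's
  10^4-node evaluations O(V^2) in the number of distinct values; `HAp`
  and `HHW` use the sorted-degree linear form.
* Measures with the `k^(-1/2)` transform reject isolated nodes.  In the
  sweep, sparse draws are evaluated on the induced subgraph of
  non-isolated nodes (and the spectral defect on the largest component),
  with a note column recording the restriction.

## Scale

The sweep's desk scale (default) uses 10^4 nodes, mean degrees
{2, 10, 50} and 5 replicates; the full design (10^5 nodes, mean degrees
2–50, 100 replicates, 12,250 networks) is available via
`sweep_config(scale = "full")` but is not exercised by the tests.
Rank assertions use replicate means, not single draws.

## Known limitations

* Compliance verdicts are battery-relative; a pass is not a theorem.
* The star/diverse comparison covers orders 4–7 only, and its
  normalization is relative to the eight graphs compared, not to
  theoretical maxima.
* The node-pair `HPED` convention (kept for the compliance pattern)
  orders Erdős–Rényi above power-law networks at moderate densities; use
  `"HL_value"` when the inequality-ordering behaviour is wanted.
* Degree-shift addition results are degree maps, not graphs; measures
  that need a realized topology receive candidate realizations instead,
  and the candidate set, while deterministic, is not exhaustive.
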