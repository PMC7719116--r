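---
title: "Edge curvatures for graphs and directed hypergraphs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge curvatures for graphs and directed hypergraphs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypercurv)
```

## Why edge-based measures

Most local network statistics decorate vertices; hypercurv instead decorates
the *relations*.  For each edge or directed hyperedge it computes three
numbers that describe how the relation sits among its neighbours:

* **Forman–Ricci curvature** `F(e)` — a purely combinatorial count.  For an
  undirected edge, `F(e) = 2 - deg(e)`, where `deg(e)` is the number of
  edges sharing a vertex with `e` (`e` is not its own neighbour).  For a
  directed edge with tail `v` and head `w`, `F(e) = 2 - deg_in(e) -
  deg_out(e)` with inputs counted at `v` (edges whose head is `v`) and
  outputs at `w`.  For a directed hyperedge `e = (e1, e2)`,
  `F(e) = |e1| + |e2| - deg_in(e) - deg_out(e)`, where an incoming
  hyperedge touching several tail vertices of `e` counts once per vertex
  touched (multiplicity counting).  Very negative values flag relations
  whose both sides are highly connected.
* **Degree difference** — `|deg_v(e) - deg_w(e)|` for undirected edges,
  signed `deg_out(e) - deg_in(e)` for directed ones: a local indicator of
  assortativity (positive = productive, negative = receptive).
* **Ollivier–Ricci curvature** `O(e) = 1 - W1(mu_a, mu_b)` — one minus the
  1-Wasserstein distance between two probability measures attached to the
  two sides of the edge.  It refines `F` by seeing *where* the neighbours
  lead: coincidences (directed triangles) raise it, detours lower it.

## The measures being transported

For an undirected edge `e = (v, w)`, each of the `|E_v|` edges at `v`
(including `e`) receives weight `1/|E_v|`; mapping each incident edge to its
far endpoint makes `mu_v` the uniform measure on the neighbours of `v`
(including `w`).  Distances between support vertices are unrestricted
shortest paths in the graph and never exceed 3.

For a directed hyperedge, `hyper_in_measure()` implements an even-splitting
cascade.  The unit mass is split evenly over the `eta_in` tail vertices.  A
*source* — a tail vertex with no incoming hyperedges once the focal
hyperedge is excluded — keeps its share in place.  At any other tail vertex
the share is split evenly over the hyperedges coming in there, and each
hyperedge's portion is split evenly over its tail vertices (the *masses*);
shares landing on the same vertex add up.  `hyper_out_measure()` mirrors
this on the head side (sinks and *holes*).  The directed distance counts
hyperedge traversals (tail vertex to head vertex); between a mass and a hole
of the same hyperedge it is at most 3, because the route through the focal
hyperedge always exists, so the breadth-first search is truncated at depth 3
and a longer pair is treated as a data-integrity error.

Two conventions are worth spelling out, since the definitions leave them
open:

* The focal hyperedge is always excluded from its own input/output lists —
  both in the degree counts and in the measure construction — even when its
  tail and head overlap (catalysts).  A catalyst vertex still contributes to
  both `|e1|` and `|e2|`.
* A hyperedge may have one empty side (a pure import or export process).
  It is accepted structurally, but the measure on the empty side is
  undefined, so its Ollivier curvature is not computed:
  `ollivier()` raises an error and `compute_curvatures()` records `NA`
  with a warning.  Relatedly, if a *neighbouring* hyperedge has an empty
  far side (it can receive no mass), its share stays on the vertex where it
  was generated, preserving normalisation.  Neither case can arise from a
  reaction table, whose rows always have a non-empty side pair.

Directed graphs are handled through their embedding as hypergraphs with
singleton tails and heads (`digraph_to_hypergraph()`); the embedding
reproduces the directed edge-measure formulation exactly (the test suite
checks this against an independent implementation of that formulation), and
the source/sink fallback — mass 1 retained at the tail/head vertex itself —
is recovered automatically because a tail vertex with no other incoming
hyperedge is a source.

## Exact arithmetic and the transport solver

All measure weights are exact rationals (numerator/denominator pairs held in
doubles, reduced by gcd; exact below 2^53, with an overflow guard).  This is
not cosmetic: the defining identities `O = 1 - W1 = m0 - m2 - 2 m3` and the
bounds `-2 <= O <= 1` are asserted *exactly* in the tests, which a floating
cascade of divisions by `eta * k * |tail|` would not support.

`wasserstein1()` scales both marginals to integer units of `1/D`, `D` the
least common multiple of all weight denominators, and solves the
transportation problem by successive shortest augmenting paths
(Bellman–Ford on the bipartite residual network, integer costs 0–3, integer
flows).  Every intermediate is integral, so the returned cost and m-vector
are exact rationals.  For `D > 2^45` the same algorithm runs on double
weights with a `1e-12` zero tolerance and results are floats; reported
table values are rounded to 12 significant digits.  Optimal plans are not
unique — the worked fixture below has two — so only the cost (hence the
curvature) is canonical; the returned m-vector belongs to *one* optimal
plan, and downstream code must not treat it as unique.

The independent check is `brute_force_w1()`: both measures are expanded
into `D` atoms of weight `1/D` and a minimum-cost perfect assignment is
found — by exhaustive permutation search for `D <= 8`, by an `O(n^3)`
Hungarian solver otherwise (itself tested against the permutation search).
A transportation problem with rational marginals attains its optimum on the
`1/D` grid (after scaling, the transportation polytope is integral), so the
assignment optimum equals the LP optimum exactly.  The oracle is guarded at
`D <= 64`; random-instance tests compare the two solvers on every instance
under the guard.

## The worked fixture

`fixture("fig3")` is the package's canonical example: hyperedges
`e = ({src, t2}, {h2, snk})`, `f = ({tm}, {t2})`, `g1 = ({h2}, {tm})`,
`g2 = ({h2}, {tr1, tr2})`.

```{r}
h <- fixture("fig3")
hyper_in_measure(h, "e")
hyper_out_measure(h, "e")
ollivier(h, "e")
```

The masses are `src` (a source, share 1/2 in place) and `tm` (1/2 through
`f`); the holes are `snk` (a sink, 1/2), `tm` (1/4 through `g1`) and
`tr1`, `tr2` (1/8 each through `g2`).  The optimal cost is 5/4, so
`O(e) = -1/4`; the two optimal m-vectors are `(1/4, 1/2, 0, 1/4)` and
`(1/4, 1/4, 1/2, 0)`, and the solver returns one of them.  The
`fig4_triangle` / `fig4_quadrangle` / `fig4_pentagon` fixtures isolate the
three motifs behind the m-decomposition: a coincidence (distance 0, `O = 1`),
a one-step detour (distance 1, `O = 0`) and a two-step detour (distance 2,
`O = -1`), against the no-shortcut floor of `O = -2`
(`fixture("directed_path")`).

## Synthetic generators

`generate_network()` provides Erdős–Rényi graphs and digraphs (independent
edge probability `p`) and random directed hypergraphs (`m` hyperedges, tail
and head sizes uniform on small ranges, memberships sampled without
replacement, tails and heads disjoint unless `allow_catalysts = TRUE` — the
default avoids the hyperloop ambiguity).  The generators emulate the
*local* incidence patterns the measures read (branching, sharing,
coincidences); they do not emulate degree heterogeneity, modularity or the
reversible-reaction structure of real metabolic models, so passing tests
demonstrate correctness of the measures, not distributional claims about
real networks.  The test suite runs the full identity battery (exact
`O = 1 - W1 = m0 - m2 - 2 m3`, bounds, marginal conservation, oracle
agreement) over 200 seeded structures with up to 8 vertices — sizes chosen
so the exhaustive oracle stays applicable and the whole suite runs in under
a minute — and checks the digraph/hypergraph equivalence on every edge of
seeded random digraphs.

## Metabolic reaction tables

`read_reaction_table()` turns a four-column TSV (id, `irrev`/`rev`,
reactants, products) into a directed hypergraph: one hyperedge per
irreversible reaction, and two (`id_f`, `id_r`, sides swapped) per
reversible one, so the hyperedge count is always
`#irreversible + 2 * #reversible`.  Stoichiometric coefficients are dropped
(the hypergraph is set-valued and unweighted; one warning per file) and
species appearing on both sides are kept on both (catalysts).  No currency
metabolites (h, h2o, atp, ...) are filtered: filtering is a modelling
choice best left to the user, and the degree-based measures are precisely
the tools that expose those hubs.  Converting an SBML/BiGG model to this
table format is out of scope; any such model reduces to it by listing, per
reaction, its id, reversibility flag and the two species lists.

## Defaults worth knowing

* `summarize_curvatures()` bins histograms from the integer floor of the
  minimum; default widths 1 (Forman, degree difference — integer-valued
  measures) and 0.05 (Ollivier, which lives in `[-2, 1]`).
* `degree_assortativity()` is the standard Newman excess-degree Pearson
  correlation (via igraph) and errors on regular graphs, where it is
  undefined (zero variance).
* `giant_component()` keeps the largest weakly connected component, the
  usual restriction for globally disconnected interaction networks.
* Batch Ollivier is the expensive step; `compute_curvatures(measures =
  c("forman", "daleth"))` (or the CLI `--measures` flag) skips it.
  Per-edge results are independent, so any execution order gives identical
  output.

## Known limitations

Weighted graphs, augmented Forman curvature with inserted 2-faces,
idleness/lazy-walk variants of Ollivier curvature and vertex-flow
curvatures are out of scope.  Hyperloop curvature (a hyperedge feeding
itself through a catalyst) is sidestepped by the exclusion convention
above.  The double-precision fallback of the solver is only exercised when
measure denominators exceed 2^45, which requires pathologically branched
neighbourhoods; its `1e-12` tolerance is then the accuracy floor.
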