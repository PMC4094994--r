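---
title: "Generating modular random graphs with specified degrees and modularity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating modular random graphs with specified degrees and modularity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modgraph)
```

## The model

Biological networks — protein interaction maps, metabolic networks, food
webs, animal contact networks — are typically both degree-heterogeneous and
community-structured. To ask whether an observed network property is a
*consequence* of community structure, or merely a byproduct of the degree
sequence, one needs random controls: graphs that share the degree sequence
and the strength of community structure of the data and are otherwise as
random as possible. The same graphs double as benchmarks with known ground
truth for community-detection algorithms.

`modgraph` generates undirected, simple, connected graphs with

* a specified size $n$ and degree distribution $p_d$ (zero-truncated
  Poisson, geometric $p(1-p)^{k-1}$, discrete power law
  $k^{-\alpha}/\zeta(\alpha)$, or an explicit degree sequence),
* $K$ modules with specified sizes $s_k$ (equal by default), and
* a planted partition whose Newman modularity
  $$Q = \sum_{k=1}^{K}\left(e_{kk} - a_k^2\right)$$
  matches a target $E[Q]$ within a tolerance $\varepsilon$ (default 0.01),
  where $e_{kk}$ is the fraction of edges inside module $C_k$ and $a_k$ the
  fraction of edge ends attached to $C_k$.

Each node's degree $d(v)$ is split into a within-degree $d_w(v)$ (edges to
its own module) and a between-degree $d_b(v) = d(v) - d_w(v)$. Averaging
the modularity of this construction gives
$$E[Q] = \sum_k \left[\frac{\bar d_w\, s_k}{M}
  - \left(\frac{\bar d\, s_k}{M}\right)^2\right], \qquad M = n\,\bar d,$$
with the equal-size reduction $E[Q] = \bar d_w/\bar d - 1/K$, so a target
modularity translates into a target mean within-degree
$\bar d_w = \bar d\,(E[Q] + \sum_k (s_k/n)^2)$
(`solve_mean_within_degree()`). $M$ is the *total degree sum* $2|E|$; this
is the only reading under which the equal-size reduction and the identity
$Q = \bar d_w/\bar d - \sum_k a_k^2$ hold exactly. The attainable range is
$-\sum_k (s_k/n)^2 \le E[Q] < 1 - \sum_k (s_k/n)^2$; negative
(disassortative) targets are supported down to the point where
$\bar d_w = 0$. The supremum with $K$ modules is $Q_{\max} = 1 - 1/K$
(`q_max()`); for Poisson-like graphs the construction is equivalent to a
planted-partition model with block densities
$p_{in} = \bar d_w/(\bar s - 1)$ and
$p_{out} = (\bar d - \bar d_w)/(\bar s (K-1))$ (`block_densities()`).

## The algorithm

Generation proceeds in four steps.

1. **Module sizes.** $K$ sizes summing to $n$ are fixed (`"equal"`
   spreads the remainder one node per module) and nodes are assigned to
   modules in blocks.
2. **Degrees and within-degrees.** A degree sequence is rejection-sampled
   from $p_d$ until it has no zeros, attains the requested mean within a
   tolerance (default $0.05\,\bar d$), has even sum (Handshake Theorem) and
   passes the Erdős–Gallai graphicality criterion. Within-degrees are then
   drawn from the same family with mean $\bar d_w$ and subjected to the
   realizability conditions described below. A single-module specification
   (the $Q = 0$ null) sets $d_w = d$, $d_b = 0$ directly, which makes the
   planted modularity exactly zero.
3. **Between-edges.** Cross-module edges are wired by a modified
   Havel–Hakimi construction: nodes are sorted by their module's total
   residual between-degree, then by their own residual; the top node is
   connected to random eligible partners (different module, not already a
   neighbor, not both within-isolated) until exhausted. Partners are drawn
   stub-wise (probability proportional to residual). End-game jams are
   repaired by splitting an existing between-edge $(x,y)$ into $(u,x)$ and
   $(w,y)$, which preserves all degrees; failing that the construction
   restarts. The result is randomized by degree-preserving double-edge
   swaps constrained to keep both replacement edges cross-module.
4. **Within-edges.** Each module is wired independently by the standard
   Havel–Hakimi construction and randomized by unconstrained double-edge
   swaps within the module. Global connectivity is then verified and, if
   needed, repaired by cross-component same-class swaps (two between-edges
   in different components, or two within-edges of the same module), which
   change no node's within- or between-degree. Per-module connectivity is
   *not* required by default; `connect_modules = TRUE` additionally applies
   cross-component rewiring inside each module (Taylor's procedure).

The achieved modularity of the planted partition is fixed as soon as the
degree triples are fixed — wiring and swaps preserve per-node within- and
between-degree counts exactly — so the $\varepsilon$ check runs at the
sampling stage and the generator retries with fresh randomness until
$|Q - E[Q]| \le \varepsilon$. Retries are tiered cheapest-first: re-wire,
re-draw within-degrees (up to 10 per degree sequence), then re-draw the
degree sequence and module sizes.

## Realizability and repairs

A within/between split must satisfy a surprisingly long list of conditions:

* **Dominance** ($d(v) \ge d_w(v)$): both sequences are sorted and matched
  largest-with-largest, and the within-degree profile is clipped at the
  degree profile and at the module-size cap $\min_k s_k - 1$. For strong
  community structure ($\bar d_w$ close to $\bar d$) pure rejection on this
  condition has vanishing acceptance for heavy-tailed degrees — a draw
  would have to sit below the degree profile at every one of $n$ ranks —
  so the clip enforces it constructively, in the same spirit as the parity
  repair below.
* **Mean.** The total within-stub count is steered onto the target mean
  exactly, in module-parity-preserving two-stub steps; surplus stubs are
  removed from the module currently carrying the least between-degree, at
  random nodes, which both balances the coarse between totals and spreads
  between-stubs over many carriers. Accepted sequences always satisfy
  $|\overline{d_w} - \bar d_w| \le \varepsilon_{d_w}$ with
  $\varepsilon_{d_w} = \varepsilon\,\bar d$ — for equal sizes this is
  *equivalent* to the modularity tolerance, since
  $Q - E[Q] = (\overline{d_w} - \bar d_w)/\bar d$.
* **Per-module parity and graphicality.** Modules with odd within-sums are
  repaired by a single decrement; Erdős–Gallai violations are repaired by
  moving stubs from the module's largest within-degree to its smallest one
  with room, and, when a module cannot absorb its share at all, by
  exporting stub pairs to another module (shifting between-degree onto the
  over-full module's hubs).
* **Between-side realizability.** The coarse module-level multigraph of
  between-stubs must be realizable (Chungphaisan's criterion; the
  multiplicity cap is left at its vacuous value, since two modules can
  carry up to $s_k s_l$ parallel between-edges no tighter uniform cap is a
  valid necessary condition), and each module's between-degrees must embed
  into the outside nodes' stub capacities (a defect Gale–Ryser condition) —
  without the latter, hub-heavy splits pass the coarse test and then stall
  the wiring.

Degree draws for which no admissible split exists are detected cheaply
before within-sampling: each module's maximal graphical dominated
within-profile bounds how many within-stubs the partition can carry, and no
node's forced between-degree may exceed half the between-stub budget. For
tight configurations (high $Q$ with heavy-tailed degrees) a constructive
fallback starts from those maximal profiles and shaves them onto the
target. Draws are batch-vectorized (256 at a time) with an adaptive
proposal mean that compensates the downward bias of the dominance clip.

The generator solves $\bar d_w$ against the *realized* per-module degree
sums $a_k$ rather than the idealized size fractions: with heavy-tailed
degrees a single hub shifts $\sum_k a_k^2$ enough that the
$\varepsilon = 0.01$ band around the idealized target would be
systematically unreachable. The exported `expected_q()` /
`solve_mean_within_degree()` implement the idealized (size-based)
relations.

## Tunable parameters

| Parameter | Meaning | Default |
|---|---|---|
| `epsilon` | tolerance on achieved planted modularity | 0.01 |
| `epsilon_dw` | tolerance on the realized mean within-degree | `epsilon * d_mean` |
| `degree_mean_tol` | tolerance on a sampled degree sequence's mean | `0.05 * d_mean` |
| `swaps_per_edge` | accepted double-edge swaps per edge of each class | 10 |
| `connect_modules` | require each module's internal subgraph connected | `FALSE` |
| `max_attempts` | per-loop rejection budget (within-degree draws are batched at 5x this and degree redraws at 3x, as both are orders of magnitude cheaper than a wiring attempt) | 1000 |

The swap count follows the common mixing heuristic of ten accepted swaps
per edge; the decorrelation property test (endpoint-degree correlation of
the randomized between-edge set) confirms that this suffices at the scales
the package targets.

## A worked example

```{r example, eval = FALSE}
spec <- graph_spec(
  n = 500, degree = deg_poisson(10),
  target_q = 0.4, modules = 5
)
res <- generate_modular_graph(spec, seed = 1)
glance(res)
graph_metrics(res$graph, partition = res$partition)
autoplot(res)
```

For null analysis of an empirical network, `spec_from_network()` extracts
the degree sequence, observed modularity, and module count from a graph
plus a (detected) partition, assuming equal module sizes at the observed
mean (the first null-model class); `preserve_sizes`/`preserve_within` keep
the observed sizes and within-degree sequence instead (the second class).
`configuration_counterpart()` generates the degree-matched,
modularity-unconstrained control. Partitions recovered by external
detection algorithms can be compared to the planted one with
`partition_jaccard()` and `variation_of_information()`.

## What the synthetic benchmarks do and do not show

The package's test suite generates all of its data. The generator's own
ensembles emulate degree heterogeneity (three families plus explicit
sequences), community sizes, and the full feasible modularity range, and
the structural sweep confirms that degree assortativity, mean local
clustering, and average path length stay flat as modularity is tuned — the
property that makes the graphs usable as controls. They do not emulate
degree–degree correlations, clustering above the random expectation,
overlapping or hierarchical communities, weights, or directionality; on
real networks exhibiting those features the generated ensemble is a null
model, not a fit. Tests passing on these ensembles validate the
construction machinery, not any claim about a particular empirical system.

## Numerical choices and edge cases

* Power-law exponents are solved from the requested mean on the truncated
  support $[1, n-1]$ by root finding; zero-truncated Poisson rates
  likewise. Geometric uses $p = 1/\bar d$.
* The sweep and test problem sizes (ensembles of 10–50 graphs at
  $n = 150$–$1000$) were chosen as the smallest scales at which the
  ensemble statistics are stable; the construction itself has been run at
  $n = 10^4$.
* Ties in Havel–Hakimi orderings are broken uniformly at random; edge
  lists are stored as canonical (min, max) pairs and written in sorted
  order, so identical spec + seed reproduce outputs byte for byte.
* Modularity of an edgeless graph is undefined and raises an error;
  assortativity of a regular graph is NaN with a warning; average path
  length of a disconnected input is computed on the largest component with
  a warning.
* The all-singleton partition pair makes the pair-counting Jaccard ratio
  0/0; it is returned as 1 with a warning. Variation of information uses
  natural logarithm (base configurable).
* For between-edge wiring, the rule that two within-isolated nodes are not
  joined is relaxed when it would leave a node with no partner at all
  (e.g. singleton modules); global connectivity is restored explicitly
  afterwards, which is the rule's purpose.

## Known limitations

* Modules smaller than the mean within-degree cannot carry their share of
  within-edges; such size draws are rejected, and specifications dominated
  by them fail with a structured error naming the condition.
* At high modularity with heavy-tailed degrees the feasible set of
  within/between splits is thin; generation succeeds via the constructive
  fallback but single graphs can take seconds rather than milliseconds,
  and a small fraction of degree draws must be discarded as infeasible.
* Weighted, directed, bipartite, hierarchical, and overlapping-community
  variants are out of scope, as is bundling any community-detection
  algorithm.
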