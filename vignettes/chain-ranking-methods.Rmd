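---
title: "Chain ranking: models, null distributions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chain ranking: models, null distributions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chainrank)
```

## The model

`chainrank` treats signal flow between two protein sets as travel along
*chains*: simple (cycle-free) paths in an undirected interaction network in
which each protein can modify the next. The package enumerates every chain
of at most `k` nodes from a start set to an end set, scores chains by the
evidence attached to their member nodes, and judges chain scores against a
randomized-network null.

The central modelling assumptions are:

* **Undirected, unweighted edges.** PPI evidence is physical binding;
  direction and interaction type are not modelled. Self-loops and duplicate
  edges are removed on input.
* **Bounded relevance.** Biological relevance of a connection decays with
  its length relative to the shortest path, so exhaustive search is cut off
  at `k` nodes. `k` is a scientific choice, not a tuning parameter: set it
  at (or slightly above) the length of the reference pathway you hope to
  recover, typically 7–9 nodes for signalling cascades.
* **Node-level evidence.** All context specificity enters through *element
  scores* on nodes: topology (connectivity), expression (fold change), or
  arbitrary user-supplied tables. Higher always means more relevant; the
  connectivity score is already inverted to fit this convention.

## Chain enumeration

Enumeration is a depth-limited depth-first search, implemented in C++ for
speed, iterated over each start node. End nodes terminate a traversal and
start nodes may not be re-entered, so by default start/end nodes occur only
at chain termini; `allow_endpoint_interior = TRUE` lifts this. This default
mirrors the evaluation convention (start and end proteins are excluded from
scoring against the gold standard) and avoids chains that run *through* a
query protein — if such chains are wanted they are a query with that
protein in neither set. Multiple start/end nodes are handled by iterating
the single-source search rather than by adding super-source nodes, which
would perturb the degrees used by the connectivity score and the null
model.

Chains are emitted in canonical lexicographic order of their node
sequences, and ties in every ranking are broken by that same order, so all
outputs are deterministic. Two chains visiting the same node set in
different orders are distinct chains.

The proximity pre-filter keeps nodes `v` with
`d_start(v) + d_end(v) ≤ k − 1` (BFS edge distances to the nearest
start/end node). Any simple path of ≤ `k` nodes lies entirely inside this
set, so pre-filtering is exact — the test suite asserts equality of the
filtered and unfiltered chain sets on random graphs — while typically
removing a substantial fraction of nodes before the exponential-cost step.

## Scores and combination

The chain score is the mean element score over the chain's `l` nodes,
`S = Σ sᵢ / l`. Normalizing by length removes the bias a plain sum would
give longer chains; with a constant score table every chain scores
identically regardless of length (asserted in the tests).

Three combination strategies are provided:

1. **Weighted sum** `c_k = Σⱼ wⱼ s_kj` of min–max-normalized scores,
   computed at node level *before* chain scoring (the combined quantity is
   a property of the node, and this keeps the combined table usable
   anywhere a score table is).
2. **Filter-then-rerank**: threshold chains by one score (p-value cutoff or
   top fraction), re-rank survivors by another.
3. **Intersection**: keep chains passing all thresholds simultaneously.

Thresholds can be expressed as empirical p-value cutoffs or as top
fractions of a ranking. Both forms are needed in practice: p-value cutoffs
presume the null top-score distribution is informative, which fails for
score tables far from normality (heavily tied counts, extreme skew), where
a top-fraction rule is the honest alternative.

Degenerate score tables (all values equal) normalize to all-1.0 rather
than all-0, so a constant table is neutral in a weighted sum instead of
annihilating the contribution of its weight. Nodes missing from a score
table receive the table minimum before normalization — unknown evidence
ranks lowest — and the count of such nodes is reported.

## The null model and empirical p-values

Significance is assessed against networks randomized by double-edge swaps
(igraph's degree-sequence-preserving rewiring; 10 attempted swaps per edge
by default), with the node→score assignment permuted in each replicate.
The permutation is drawn jointly for all score tables, preserving
within-node correlation between scores. Each replicate `r` contributes only
its *top* chain score `m_r`; the p-value of an observed chain with score
`s` is

`p = (1 + #{r : m_r ≥ s}) / (R + 1)`.

Design choices worth stating:

* **One top score per replicate**, not a pool of all random chains: pooling
  would conflate chain multiplicity with significance (a dense random
  network contributes thousands of mediocre chains) and break the
  family-wise logic of comparing best against best.
* **Pseudo-count** `+1` in numerator and denominator: an empirical null of
  `R` draws cannot support `p = 0`; the smallest attainable p-value is
  `1/(R+1)` (0.01 at the default `R = 100`).
* **Disconnected replicates** (rewired networks with no start–end chain
  within `k`) contribute `m_r = −∞` rather than being redrawn; redrawing
  would bias the null toward connected topologies.
* **Determinism**: replicate `r` derives its RNG stream from the master
  seed and `r`, so any single replicate can be reproduced in isolation and
  results are independent of evaluation order. The caller's RNG state is
  never disturbed.
* No multiple-testing correction is applied across chains: chains overlap
  heavily and are not independent tests; the p-values are a ranking device
  and their calibration is checked for the top chain only.

The calibration property the suite verifies: when node scores are
exchangeable noise, the p-value of the observed top chain is approximately
Uniform(0, 1] over repeated experiments (200 repetitions, KS test at
α = 0.01, with the "observed" network drawn from the same rewiring
ensemble so observed and null statistics are exchangeable).

## Evaluation

Positives `P` are gold-standard nodes present in the network minus
start/end nodes. A selection of chains covers the union of their nodes
(again minus start/end), each node counted once — unique-node counting is
what makes `TP + FP` a partition and precision well-defined.
`Improvement` divides the selection's precision by the mean precision of
`B` uniform random selections (without replacement) of the same size; its
Monte-Carlo standard error is reported. The ROC is node-level — labels
exist only for nodes — with each candidate node scored by the best rank of
any chain containing it, nodes in no chain tied after all covered nodes,
midpoint ranks for ties, and AUC by the trapezoidal rule (equal to the
normalized Mann–Whitney count, cross-checked by brute force in the tests).

Default selection rules follow common practice for this method: a p-value
cutoff of 0.015 or the top 50 chains; combination thresholds of p ≤ 0.05
or the top quartile.

## The synthetic benchmark

`make_fixture()` emulates the evaluation design the method is meant for: a
known pathway embedded in a larger interaction network. It generates an
Erdős–Rényi `G(n, m)` (default) or Barabási–Albert background — the BA
option approximates the heavy-tailed degree distributions of real PPI
networks — plants a fresh simple path of `planted_len` nodes between fresh
start/end nodes, threads `n_decoys` alternative start–end paths through
random background nodes, anchors every planted node in the background with
`attach` random edges, and drops any background node left isolated (real
interaction networks have no unconnected proteins; this also makes the
zero-density fixture exactly the planted path). Gold-standard nodes
(planted path members) draw scores from `Normal(mu_gs, sigma)`, background
nodes from `Normal(mu_bg, sigma)`; a lognormal option mimics skewed
evidence such as study-occurrence counts.

Defaults were fixed once at the magnitude of a tissue-specific use case —
300 background nodes, 850 edges, a planted 8-node path, 8 decoys, 2
attachment edges per planted node, `mu_gs − mu_bg = 3` at `sigma = 1`
("moderate" separation) — and the test suite additionally uses
`mu_gs = 4, sigma = 0.25` as its "strong separation" condition (the
chain-mean gap is then many standard errors wide, so recovery should be
near-certain by construction). Problem sizes in the test suite (200
calibration repetitions at 20 nodes, 100 benchmark seeds at 300 nodes,
brute-force oracles up to 9 nodes) were chosen as the smallest scales at
which the respective properties are meaningfully exercised.

What passing these benchmarks does *not* show: real PPI networks have
correlated, noisy, incomplete evidence scores, node coverage gaps, and
degree–score dependence (hubs are better studied), none of which the
generator emulates beyond the BA degree option. Results on synthetic
fixtures demonstrate correctness of the machinery and sensible behaviour
of the statistics, not expected field performance.

## Known limitations

* Exhaustive search is exponential in `k`; dense networks with `k ≥ 9`
  and high-degree start nodes can be prohibitively slow even after
  proximity filtering. No heuristic or approximate mode is provided.
* Edges are unweighted; interaction-confidence weighting and
  information-propagation ranking are out of scope.
* Empirical p-values inherit the resolution `1/(R+1)` and are
  uninformative for score tables whose null top-score distribution is
  degenerate; use top-`n` selection there.
* Node identifiers are opaque case-sensitive strings; no identifier
  mapping between naming schemes is attempted.
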