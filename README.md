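# chainrank

Context-specific subnetwork extraction from biological interaction networks
by exhaustive enumeration and evidence-based ranking of interaction chains.

## The problem

Genome-scale protein–protein interaction (PPI) networks are too large and
too context-agnostic for direct interpretation: they pool interactions
observed across tissues, diseases and experimental platforms. Given two
sets of proteins of interest — say a receptor and a downstream effector, or
two biomarkers of a disease state — the question is which *chains of
interactions* (simple paths, where each protein can pass a signal to the
next) plausibly connect them in a given biological context, and which
subnetwork those chains form.

`chainrank` answers this in four steps:

1. **Chain search.** All simple paths of at most *k* nodes linking any
   start node to any end node are enumerated by a depth-limited depth-first
   search (exhaustive within the depth limit; the limit is what makes the
   otherwise factorial "all simple paths" problem tractable). A
   proximity pre-filter first restricts the network to nodes `v` with
   `d_start(v) + d_end(v) ≤ k − 1` edges, which provably cannot change the
   result but shrinks the search space.
2. **Scoring.** Every node carries one or more *element scores* —
   topological (e.g. the connectivity score
   `score(v) = (max degree − degree(v)) + 1`, which favours specific over
   hub-like proteins), experimental (e.g. a fold-change score
   `log2(case/control)`), or any user-supplied evidence. A chain of nodes
   `1..l` gets the length-normalized score `S = Σᵢ sᵢ / l`, so longer
   chains are not favoured merely by having more terms. Multiple scores can
   be combined three ways: a weighted sum of min–max-normalized node scores
   (`c_k = Σⱼ wⱼ s_kj`), filter-by-one-score-then-rerank-by-another, or
   the intersection of chains passing several thresholds simultaneously.
3. **Significance.** Each chain's score is compared with the *top* chain
   score obtained in each of `R` randomized networks (degree-preserving
   double-edge swaps, with the node→score assignment shuffled):
   `p = (1 + #{r : m_r ≥ s}) / (R + 1)`.
4. **Selection and assembly.** Chains passing a p-value cutoff (or the top
   *n*) are merged into a subnetwork whose nodes carry an `occurrence`
   attribute — how many selected chains contain each protein.

An evaluation harness measures, against a gold-standard protein list:
precision `TP/(TP+FP)`, recall `TP/P`, *improvement* (precision of the
ranking divided by the mean precision of random chain selections of the
same size) and a node-level ROC/AUC. A synthetic benchmark generator
(`make_fixture()`) plants a known pathway in a random background network so
the whole method can be exercised and validated without any external data.

## Worked example

The canonical two-route toy network (`S–C1`, `C1–E`, `C1–C2`, `C2–E`) has
exactly two chains from S to E within 4 nodes:

```r
library(chainrank)
g <- igraph::graph_from_edgelist(
  cbind(c("S", "C1", "C1", "C2"), c("C1", "E", "C2", "E")),
  directed = FALSE)
scores <- list(evidence = c(S = 1, C1 = 3, C2 = 4, E = 2))
fit <- chainrank(g, "S", "E", k = 4, scores = scores,
                 null_model = null_model_config(replicates = 99, seed = 1))
as.data.frame(fit)
#>       chain length evidence evidence_p
#> 1 S|C1|C2|E      4      2.5          1
#> 2    S|C1|E      3      2.0          1
```

`S|C1|C2|E` averages evidence 2.5 over its 4 nodes and outranks `S|C1|E`
(2.0). Both p-values are 1: in a 4-node toy, degree-preserving
randomization cannot produce networks whose best chain scores worse, so
neither chain is significant — as it should be.

At realistic scale, with a planted 8-node pathway in a ~300-node background
(the magnitude of a tissue-specific PPI subnetwork):

```r
fx <- make_fixture(seed = 42)          # network, scores, gold standard
fit <- chainrank(fx$network, fx$start, fx$end, k = fx$k, scores = fx$scores,
                 null_model = null_model_config(replicates = 99, seed = 43))
summary(fit, n = 3)
#> Top 3 chains by 'relevance':
#>                          chain length relevance relevance_p
#> 1  S|P01|P02|P03|P04|P05|P06|E      8  2.854475        0.01
#> 2 S|P01|P02|P03|P04|P05|b242|E      8  2.618861        0.01
#> 3                S|b072|b091|E      4  2.092190        0.02

evaluate_chains(fit$chains, fx$gold_standard, "relevance",
                top_n = 50, B = 1000, seed = 44)
#> Evaluation of ranking by 'relevance' (top_n = 50)
#>   selected chains: 50, positives in network: 6
#>   precision 0.087, recall 1.000, improvement 3.72 (baseline 0.023 +/- 0.001)
#>   node-level AUC 1.000
```

The planted pathway (`S|P01|…|P06|E`) ranks first among 3695 chains with
the smallest attainable p-value (0.01 at R = 99); the top-50 selection
recovers all 6 gold-standard proteins and is 3.7× more precise than random
chain selection. `subnetwork(fit, top_n = 50)` returns the assembled
igraph subnetwork with per-protein occurrence counts, and
`run_pipeline("run.yaml")` drives the same steps from files on disk
(see `inst/cli/chainrank.R` for a shell entry point).

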