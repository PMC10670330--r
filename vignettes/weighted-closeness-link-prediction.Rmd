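---
title: "Link prediction by weighted local and global closeness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Link prediction by weighted local and global closeness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkclose)
```

## The problem and the model

Given an observed undirected, unweighted simple graph, link prediction asks
which unconnected node pairs are most likely to be edges — missing
interactions in a protein network, unrecorded ties in a social network,
future routes in a transport network. Similarity-based predictors assign
each candidate pair a score and rank: pairs scoring higher are called more
likely.

The indices at the core of this package combine two signals that most
neighbourhood-counting predictors ignore:

* **Closeness.** A node's closeness centrality
  \(C_i = (n-1) / \sum_{j \ne i} d_{ij}\) measures how quickly it reaches the
  rest of the network. For a *pair* we use \(C_{i,j} = C_i + C_j\): two nodes
  that are both near the network's core are better positioned to acquire a
  link than two peripheral nodes of the same degree.
* **Clustering.** The local clustering coefficient \(CC_z\) of a common
  neighbour \(z\) measures triangle density around it; common neighbours
  embedded in dense neighbourhoods are stronger evidence for a future link.

The **local attribute closeness** of a pair sums these over the common
neighbours, penalising promiscuous intermediaries by their degree:

\[ LC_{i,j} = \sum_{z \in \Gamma_i \cap \Gamma_j} \frac{C_{i,j} + CC_z}{k_z}. \]

The **global attribute closeness** scales pair closeness by two whole-network
quantities, the average clustering coefficient \(CC\) and the average
shortest path length \(d\):

\[ GC_{i,j} = C_{i,j} \cdot CC / d. \]

Networks that are globally tight (high \(CC\), short \(d\)) make any
well-positioned pair more plausible. The **LGC** index is the convex
combination \( S = \lambda\,LC + (1-\lambda)\,GC \), and **LGC\*** squares
the local numerator, \( (C_{i,j} + CC_z)^2 / k_z \), which amplifies
already-high proximity values and shrinks low ones, widening the gap between
strong and weak candidates.

### Assumptions

The model assumes the observed topology is a representative (if incomplete)
sample of the true network: scores are computed from structure alone, with no
node attributes, weights or directions. Common-neighbour evidence dominates
the local term, so pairs at distance three or more are separated only by the
global term; on networks where most missing links span long distances, all
common-neighbour indices — LGC included — degrade together.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `lambda_weight` | local/global balance \(\lambda \in [0,1]\) | 0.8 | AUC and precision typically rise as \(\lambda\) grows to about 0.8 and flatten or dip beyond; `lambda_sweep()` reproduces this on any graph |
| `gc_form` | reading of the global term | `"product"` | `"product"` is \(C \cdot CC / d\): tighter clustering raises confidence and stays defined on triangle-free graphs; `"inverse"` (\(C / (d \cdot CC)\)) is provided for comparison and errors when \(CC = 0\) |
| `katz_beta` | Katz path damping | 0.01 | must be below \(1/\rho(A)\); validated at scoring time against the computed spectral radius |
| `lp_epsilon` | 3-walk weight in LP | 0.001 | 0 reduces LP to 2-walk counts |
| `cn2d_beta` | second-order weight in CN2D | 0.1 | 0 reduces CN2D to CN |
| `dense_cap` | max n for dense Katz/LP | 3000 | both need an \(O(n^3)\) dense solve; beyond the cap they error with guidance rather than thrash |

Katz, LP and CN2D weights are conventional values from the link-prediction
literature; no canonical values exist for them, so results for those
baselines should be read as representative rather than definitive.

## Numerical and design choices

* **Disconnected graphs.** Random edge removal routinely disconnects training
  graphs, and the classical closeness formula assumes reachability. We use
  the Wasserman–Faust component scaling — a node reaching \(r\) of the
  \(n-1\) others gets \((r/(n-1)) \cdot (r/\sum d)\) — which coincides exactly
  with the classical form on connected graphs and gives isolated nodes 0.
  Similarly, the average shortest path length is taken over reachable pairs
  only, and local clustering of degree-<2 nodes is defined as 0.
* **The scorer never sees probe edges.** All per-node and network-level
  quantities (degrees, clustering, closeness, \(CC\), \(d\)) are computed on
  the graph passed to `score_index()` — during evaluation, the training
  graph.
* **Negatives for AUC** are the non-edges of the *original* graph (pairs in
  neither the training nor the probe set). AUC is exhaustive — every
  positive–negative comparison, ties counted half — when the comparison count
  is at most 10^6, and otherwise uses 10,000 seed-controlled uniform draws.
* **Ties in the precision ranking** are broken by canonical pair order
  (sorted within pair, pairs sorted lexicographically), making the top-m
  list deterministic even for tie-heavy scorers such as CN on sparse graphs.
  Pairs an index leaves unscored (e.g. no common neighbours) rank with score
  0 rather than being dropped, so every index ranks the same universe.
* **Precision's m** has no canonical value; the default is 100 with
  `m = "probe"` (each trial's holdout size) as a named alternative — the
  sensible choice on small graphs where 100 would exceed the ranking depth.
* **Reproducibility.** `run_experiment()` draws all per-trial seeds up front
  from the master seed, so a run is a pure function of
  (graph, index, parameters, ratio, reps, m, seed), and sweeps reuse the
  same master seed across settings, giving paired comparisons in which
  differences are attributable to the swept parameter alone.

## What the synthetic generators emulate

`generate_graph()` covers the three standard random families —
Erdős–Rényi (no structure: a null case), Barabási–Albert (heavy-tailed
degrees, as in protein and citation networks; each new node attaches
`m_attach` edges preferentially, so the edge count is
`sum(pmin(m_attach, 1:(n-1)))`), and Watts–Strogatz (high clustering with
short paths, the regime where closeness-plus-clustering indices have signal)
— plus deterministic fixtures (complete, path, star, two disjoint triangles)
whose index values are known in closed form.

These generators exercise every code path, but real networks have features
none of them produce: community structure, degree correlations, and
domain-specific motifs. Passing tests on synthetic graphs therefore
demonstrates correctness of the computations and sane discriminative
behaviour, not performance claims transferable to any particular real
dataset. For real benchmarks, read an edge list with `read_edgelist()`;
the karate-club network bundled with igraph is used in
`scripts/acceptance.R` as a small real-world check, where LGC's mean AUC
over 50 random 9:1 splits lands around 0.72–0.76.

## Problem sizes

The test suite and the acceptance script run on graphs of 15–200 nodes with
3–50 repetitions per experiment — large enough that AUC separations are
stable across seeds, small enough that the whole suite runs in a couple of
minutes on one core. The same machinery scales to the few-thousand-node
range; only Katz and LP hit the `dense_cap` guard beyond it.

## Known limitations

* Closeness needs all-pairs shortest paths, so scoring is
  \(O(n \cdot (n + m))\) at best and Katz/LP are \(O(n^3)\): this is a
  small-to-medium-network method, not a web-scale one.
* Undirected, unweighted, simple graphs only; no temporal or attribute
  information.
* The candidate universe is materialised densely (all non-edges), which is
  quadratic in n.
* On triangle-free networks the default global term is 0 everywhere and LGC
  degenerates gracefully to its local term scaled by \(\lambda\); the
  inverse global form refuses such networks instead.
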