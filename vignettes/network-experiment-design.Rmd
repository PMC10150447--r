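---
title: "Designing network experiments under interference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing network experiments under interference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netdesign)
```

## The problem

A/B tests assume each unit's outcome depends only on its own assignment
(SUTVA). On a network this fails: treatment "spills over" along edges, so
the naive difference in means
$\hat\tau = \bar Y_{V_1} - \bar Y_{V_0}$ mixes the *direct treatment
effect* (DTE) with *peer effects*. Peer effects inside an arm (allowable,
APE) are part of what a roll-out would produce; peer effects across arms
(unallowable, UPE) are pure contamination. The two designs in this package
attack the two halves of the problem:

* the **independent-set design** (`design_causeis()`) targets the DTE by
  assigning treatment and control only to a maximal independent set, so no
  experiment node neighbours another and APE and cross-arm UPE are removed
  by construction;
* the **cluster-matching design** (`design_cmatch()`) targets the total
  treatment effect by clustering the weighted graph (stage 1, interference
  minimization) and then matching covariate-similar clusters across arms
  (stage 2, selection-bias minimization).

Both sit in a common frame: a design is a per-node assignment to
`TREATED`, `CONTROL`, or `EXCLUDED` (a *bystander*: in the network but not
in the experiment), and the estimator is always the difference in means
over the two arms.

## The independent-set design

The selection problem is: maximize the number of selected nodes subject to
$s_i + s_j \le 1$ for every edge $(i,j)$ — exactly the maximum independent
set problem. Finding a maximum independent set is NP-hard, so
`greedy_mis()` uses the standard $O(|E|)$ greedy sweep over a random node
permutation, which returns a *maximal* set; a `restarts` argument keeps
the largest set over several permutations when a closer approximation to
the maximum is wanted. Members are split into the two arms uniformly
(sizes within one); everything else becomes a bystander.

Bystanders still transmit influence into both arms. The design's defence
is symmetry: because arms are randomized within the independent set, a
bystander is equally likely to abut treated and control nodes, so the
influence flowing into the two arms cancels in expectation.
`bystander_balance()` measures exactly this — the signed percentage of
edges from bystanders to treated minus to control, with all edges as the
denominator — and its mean over designs is zero.

The cancellation is exact for the *count* of exposed nodes, not for the
resulting outcome shift: spillover activates a fraction of the *inactive*
nodes of each arm, and the inactive fractions differ
($1 - p_t$ vs $1 - p_c$). The residual bias of the difference in means is
therefore of order $-(p_t - p_c)\,Q$, where $Q$ is the probability that an
inactive experiment node is activated through bystander exposure. This
term shrinks with graph size much more slowly than sampling noise and is
the dominant part of the design's error under heavy contagion; the
replication experiments in `tests/` and `scripts/acceptance.R` show it
directly. Turning bystander transmission off
(`excluded_as_control = FALSE`) removes it entirely.

`design_causeis(match = TRUE)` adds covariate matching *inside* the
independent set (exact maximum-weight matching on similarity, pairs split
across arms), which tightens covariate balance in small graphs where pure
randomization is noisy.

## The cluster-matching design

**Stage 1 — weighted clustering.** Every edge carries a spillover
probability $e_{ij}.p$, a proxy for how likely influence is to cross it;
`add_edge_probabilities()` sets it to a constant or to the covariate
similarity of the endpoints. Markov clustering (`cluster_mcl()`) consumes
these weights and picks its own number of clusters; the restreamed
deterministic greedy partitioner (`cluster_reldg()`, `k` given,
deliberately unweighted) is the comparison stage-1 engine. The quantity
stage 1 drives down is the cross-arm spillover mass
$\hat\theta = \sum_{i \in V_0, j \in V_1} e_{ij}.p$, reported by
`cut_statistics()`.

**Stage 2 — matching clusters.** Cluster similarity is built from node
matches:

* *threshold matching* (TNM, `alpha_q` 0–3): all cross-cluster pairs with
  similarity above the chosen quartile of the pairwise-similarity
  distribution (level 0 = no threshold);
* *best matching* (BNM): each node's single most similar node among other
  clusters — conservative, possibly asymmetric.

Pairwise cluster weights summarize the matches: counts (`c`), average
similarity (`s`), or the same after an exact maximum-weight *bipartite*
matching so each node is used once (`mc`, `ms`, `mss`), plus the
match-free negated distance of cluster attribute means (`e`). Candidate
cluster pairs survive a quartile threshold (TCM) or each cluster's single
best partner (GCM), and an exact maximum-weight matching over the
candidate graph picks disjoint cluster pairs maximizing total weight,
each cluster used at most once. Every matched pair is split across arms
by a coin; unmatched clusters are excluded, which is what lets the design
trade population size for balance. The default bundle is
TNM2 + C + TCM2.

The bias story for cluster designs is made concrete by `linear_bias()`:
under a linear outcome model $E[y_i(Z)] = a_i + \sum_j B_{ij} z_j$, the
truth is $\mu = \tfrac1n\sum_{ij} B_{ij}$, cluster randomization recovers
the within-cluster mass $\mu^{cbr}$, node randomization only the diagonal
$\mu^{rand}$, and $\mu/\mu^{cbr} - 1$ is the relative bias — zero exactly
when the clustering captures the interference blocks.

## Baselines and diagnostics

`design_randomized()` (network-blind split), `design_match()`
(maximum-weight matched pairs on covariates, each split by coin), and
`design_cbr()` (reLDG clusters paired into strata of two by nearest
attribute means, then cluster-level coins for CBR or node-level
randomization within strata for CR) complete the comparison set.
Diagnostics: `rmse()` over replicate runs, `covariate_distance()`
(selection bias), `cut_statistics()` (interference exposure),
`degree_comparison()` (KS statistic between arm degree distributions),
and `bystander_balance()`.

## The outcome simulator

`simulate_outcomes()` draws a base activation for every node —
probability 0.4 in treatment, 0.2 in control, so the true effect is 0.2 —
and then adds interference:

* **direct** — every treated neighbour of an inactive control node
  contributes an independent trial with the edge's $e.p$ (so $k$ treated
  neighbours activate with $1-(1-p)^k$). The treated node's *assignment*,
  not its realized outcome, is what spills over, and only control nodes
  receive.
* **contagion** — an independent cascade. When an inactive experiment
  node first has an *activated* neighbour in a different treatment class,
  it draws a single Bernoulli trial with probability
  $1-\prod_e (1-e.p)$ over those neighbours' edges. Newly activated nodes
  extend the frontier; activation never reverts.

Three conventions here were genuinely open and are worth stating:

* *One trial per node.* Unlimited per-round retrials would drive every
  exposed node's activation probability to 1 and destroy the signal; a
  single trial at first exposure (the independent-cascade convention)
  keeps the spillover probability interpretable.
* *Bystander behaviour.* Bystanders draw control-level base activations
  and transmit (an activated bystander can infect both arms — that is the
  design's whole point of concern) but do not themselves receive
  spillover: spillover activation applies to the experiment arms. Both
  halves are toggleable via `excluded_as_control`.
* *Class boundaries.* "Different treatment class" compares the three-way
  arm label, so bystanders count as a distinct class from either arm and
  bystander–bystander edges never carry contagion.

## Synthetic study conditions

`generate_study_graph()` reproduces the simulation conditions used
throughout: Barabási–Albert graphs with $m = 3$ (seeded from a complete
graph on $m$ nodes, making the edge count exactly
$\binom m2 + m(n-m)$) or forest-fire graphs with forward and backward
burning probabilities $p_f = p_b = 0.3$ (geometric burn counts with mean
$p/(1-p)$, undirected output), plus $d = 10$ i.i.d. Uniform$(-1,1)$
attributes per node. Attributes are independent of structure by design,
so these fixtures exercise the estimators but cannot exhibit homophily,
degree–covariate correlation, or clustered covariates; passing tests on
them says nothing about designs' behaviour when covariates and topology
are dependent, which is exactly where real networks are hardest.

Replication experiments use $S = 10$ seeded runs per cell
(`run_experiment()`), with per-stage seeds derived deterministically from
the base seed so different designs face identical graphs. The test and
acceptance workloads use $n$ from 500 up to 50{,}000 nodes for the
selection-bias curves and $n = 10{,}000$ for the contagion error
comparisons.

## Numerical choices

* Similarity is mapped to $[0,1]$: the L2 form normalizes by the
  theoretical maximum distance $\mathrm{range}\cdot\sqrt d$ when attribute
  bounds are known and by the observed maximum otherwise; cosine clamps
  negatives to zero (so 0 keeps meaning "no affinity" for the threshold
  quantiles); Jaccard uses the generalized (Ruzicka) form after shifting
  by the attribute lower bound.
* Maximum-weight matching is the exact blossom algorithm (compiled),
  with weights scaled to integers at $10^{-6}$ resolution. The dense
  implementation is quadratic in memory, so node-level matched designs
  are exact up to 1000 nodes and fall back to greedy matching over each
  node's top-50 similarity candidates beyond that.
* Threshold level 0 means "no threshold" for both node (TNM0) and cluster
  (TCM0) rules; taking it literally as the distribution's minimum would
  exclude ties at the bottom, and for negated-distance cluster weights a
  zero threshold would exclude everything.
* Distance-based (`e`) cluster weights are non-positive, and a plain
  maximum-weight matching over them would select nothing; candidate edges
  are shifted to be strictly positive before matching, which pairs as
  many clusters as possible while preferring small distances.
* MCL runs with inflation 2, expansion 2, self-loops at each node's
  maximum incident weight, pruning at $10^{-5}$, convergence at
  $10^{-8}$; cluster counts are sensitive to the inflation, which is why
  it is exposed. reLDG breaks score ties toward the lowest cluster index
  and enforces capacity $\lceil n/k \rceil$; as a greedy streaming
  heuristic it can lodge in a poor local partition on an unlucky stream
  order, which restreaming usually (not always) repairs.
* The greedy maximal independent set is used rather than an exact
  maximum-set solver, matching the selection actually used in this kind
  of experiment design; `restarts` trades time for size.

## Known limitations

The independent-set design's estimate keeps a residual bias term under
contagion (see above) that the symmetry argument does not remove; it is
the price of letting bystanders transmit. Cluster matching enumerates all
node pairs when building threshold matches, which is comfortable at the
cluster sizes MCL and reLDG produce on desk-scale graphs but quadratic in
general (quantile estimation subsamples at $10^6$ pairs). The stratum
construction for CR/CBR (greedy nearest cluster means, strata of two) is
one reasonable reading of "similar clusters share a stratum" and is
exposed as a hook rather than fixed doctrine. Outcomes are binary;
continuous outcomes, time-stamped diffusion, and threshold contagion are
out of scope.
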