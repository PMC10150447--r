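# netdesign

Experiment design for A/B tests on networks, where treatment effects
spill over between connected units and break the stable-unit-treatment
assumption behind the usual difference-in-means analysis.

When units interact, two estimands matter and they need different
designs:

* **Direct treatment effect (DTE)** — the effect of a unit's own
  treatment, free of peer influence. `netdesign` implements an
  **independent-set design**: treatment and control are assigned only to
  a maximal independent set of the graph (found by the O(|E|) greedy
  sweep), so no two experiment nodes are adjacent and no peer effect can
  cross between or within arms. Remaining nodes are *bystanders* —
  outside the experiment, but randomization makes their influence on the
  two arms cancel in expectation.
* **Total treatment effect (TTE)** — the all-treated vs all-control
  contrast, including allowable peer effects. `netdesign` implements a
  **cluster-matching design**: cluster the graph weighted by per-edge
  spillover probabilities `e.p` (Markov clustering or restreamed greedy
  partitioning), score cluster pairs by how well their nodes match on
  covariates, and solve

  max_A Σ a_ij · w_ij  subject to  Σ_j a_ij ≤ 1, a_ij ∈ {0,1}

  by exact maximum-weight matching; each matched cluster pair is split
  across arms, jointly driving down the cross-arm spillover mass
  θ̂ = Σ_{i∈V0, j∈V1} e_ij.p and the covariate distance
  ‖mean(X_T) − mean(X_C)‖₂ (selection bias).

The package also ships the comparison designs (node-level randomization,
covariate-matched pairs, stratified cluster randomization CR/CBR), the
synthetic graph generators used in the simulation study (Barabási–Albert
m = 3 and forest fire p_f = p_b = 0.3, with 10 Uniform(−1,1) attributes
per node), an interference simulator (one-shot direct spillover and
independent-cascade contagion over base activation probabilities
0.4 / 0.2, true effect 0.2), and the evaluation metrics (RMSE over seeded
runs, covariate distance, cut statistics, bystander balance,
degree-distribution comparison, and linear-model cluster-bias
diagnostics). It is aimed at anyone planning or studying randomized
experiments on social, citation, or interaction networks.

## A worked example

Compare node-level randomization against the independent-set design on a
forest-fire network under contagion, spillover probabilities set from
covariate similarity:

```r
library(netdesign)

suite <- run_suite(list(
  dataset = list(model = "ff", n = 2000, d = 10),
  designs = c("randomized", "causeis"),
  sim     = list(mode = "contagion", ep = "edge_weight"),
  S       = 10, base_seed = 1
))
suite$summary[, c("design", "rmse", "bias", "mean_covariate_distance",
                  "mean_edge_fraction")]
#> # A tibble: 2 × 5
#>   design       rmse    bias mean_covariate_distance mean_edge_fraction
#>   <chr>       <dbl>   <dbl>                   <dbl>              <dbl>
#> 1 randomized 0.116  -0.115                   0.0739              0.504
#> 2 causeis    0.0561 -0.0500                  0.133               0
```

Read: with the true effect at 0.2, blind randomization leaves half of
all edges running between treatment and control
(`mean_edge_fraction 0.504`) and contagion drags its estimate down by
−0.115 on average; the independent-set design has *zero* cross-arm edges
by construction and roughly halves the error, its residual bias coming
only from bystander transmission. The price is selection: its arms are
drawn from the independent set only, so their covariate distance (0.133)
is larger than under full randomization — the matched variant
(`design_causeis(match = TRUE)`) exists to claw that back on small
graphs.

Every stage is also callable on its own and returns a tibble that pipes:

```r
g  <- generate_study_graph("ff", n = 2000, seed = 42) |>
  add_edge_probabilities("similarity")
cl <- cluster_mcl(g)
d  <- design_cmatch(g, clustering = cl, seed = 1)   # TNM2 + C + TCM2 defaults
cut_statistics(g, d)
```

`autoplot()` works on `run_experiment()` / `run_suite()` results, and
`tidy()` / `glance()` follow the broom conventions. A thin command-line
wrapper lives at `inst/cli/netdesign.R`
(`netdesign.R {generate|design|experiment}`).

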