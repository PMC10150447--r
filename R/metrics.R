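# Evaluation metrics: estimation error, covariate balance, cross-arm cut
# statistics, degree-distribution comparison, and the linear-outcome-model
# bias diagnostics for cluster randomization.

#' Root mean squared error of replicated effect estimates
#'
#' @param estimates Numeric vector of per-run estimates.
#' @param truth True effect (scalar, or one value per run).
#' @return `sqrt(mean((estimates - truth)^2))`.
#' @export
rmse <- function(estimates, truth) {
  if (length(estimates) == 0) abort("no estimates supplied")
  sqrt(mean((estimates - truth)^2))
}

#' Covariate distance between arms
#'
#' Euclidean distance between the attribute mean vectors of treated and
#' control nodes — the package's selection-bias measure. `EXCLUDED` nodes
#' are not in the experiment and are omitted.
#'
#' @param design Design tibble.
#' @param X Node attribute matrix (row per node, aligned to node index).
#' @return Non-negative scalar distance.
#' @export
covariate_distance <- function(design, X) {
  assert_design(design)
  t_idx <- arm_nodes(design, "TREATED")
  c_idx <- arm_nodes(design, "CONTROL")
  if (length(t_idx) == 0 || length(c_idx) == 0) abort("both arms must be non-empty")
  mt <- colMeans(X[t_idx, , drop = FALSE])
  mc <- colMeans(X[c_idx, , drop = FALSE])
  sqrt(sum((mt - mc)^2))
}

#' Cross-arm cut statistics
#'
#' How much of the graph crosses the treatment/control boundary: the
#' fraction of edges with one endpoint in each arm, the same fraction
#' weighted by edge spillover probabilities, and the raw cross-arm
#' spillover sum `theta_hat = sum of e.p over TREATED-CONTROL edges` (the
#' quantity the weighted-clustering stage minimizes). Without edge
#' probabilities all edges count with weight 1 (so `theta_hat` is the
#' cross-arm edge count).
#'
#' @param graph Undirected igraph object.
#' @param design Design tibble covering the graph.
#' @return A one-row tibble: `edge_fraction`, `weight_fraction`,
#'   `theta_hat`.
#' @export
cut_statistics <- function(graph, design) {
  assert_graph(graph)
  assert_design(design, graph)
  m <- igraph::ecount(graph)
  if (m == 0) abort("graph has no edges")
  el <- igraph::as_edgelist(graph, names = FALSE)
  arm <- design$arm[order(design$node)]
  p <- igraph::edge_attr(graph, "p")
  if (is.null(p)) p <- rep(1, m)
  a1 <- arm[el[, 1]]
  a2 <- arm[el[, 2]]
  cross <- (a1 == "TREATED" & a2 == "CONTROL") | (a1 == "CONTROL" & a2 == "TREATED")
  tibble(
    edge_fraction = sum(cross) / m,
    weight_fraction = sum(p[cross]) / sum(p),
    theta_hat = sum(p[cross])
  )
}

#' Bias diagnostics under a linear outcome model
#'
#' For a linear outcome model `E[y_i(Z)] = a_i + sum_j B_ij z_j`, the true
#' total treatment effect is `mu = sum(B) / n`; cluster randomization
#' recovers only the within-cluster mass `mu_cbr = sum(B_ij over pairs in
#' the same cluster) / n`, and node randomization only the diagonal
#' `mu_rand = sum(diag(B)) / n`. The relative bias `mu / mu_cbr - 1`
#' measures how much of the interference structure the clustering misses:
#' it is 0 when `B` is block-aligned with the clustering.
#'
#' @param B Square numeric coefficient matrix (`n x n`).
#' @param clustering Clustering tibble covering the `n` nodes.
#' @return A one-row tibble: `mu`, `mu_cbr`, `mu_rand`, `relative_bias`
#'   (`NA` with a warning when `mu_cbr` is 0).
#' @export
linear_bias <- function(B, clustering) {
  B <- as.matrix(B)
  n <- nrow(B)
  if (ncol(B) != n) abort("B must be square")
  if (!all(is.finite(B))) abort("B must be finite")
  assert_clustering(clustering)
  if (nrow(clustering) != n) abort("clustering and B disagree on n")
  lab <- clustering$cluster[order(clustering$node)]
  same <- outer(lab, lab, `==`)
  mu <- sum(B) / n
  mu_cbr <- sum(B[same]) / n
  mu_rand <- sum(diag(B)) / n
  rb <- if (mu_cbr == 0) {
    warn("mu_cbr is zero; relative bias is undefined")
    NA_real_
  } else {
    mu / mu_cbr - 1
  }
  tibble(mu = mu, mu_cbr = mu_cbr, mu_rand = mu_rand, relative_bias = rb)
}

#' Degree-distribution comparison between arms
#'
#' Compares the full-graph degree distributions of the treated and control
#' nodes (bystanders omitted), returning per-arm degree counts and the
#' two-sample Kolmogorov-Smirnov statistic (the largest gap between the two
#' empirical CDFs, computed directly since degrees are heavily tied).
#'
#' @param graph Undirected igraph object.
#' @param design Design tibble covering the graph.
#' @return A list with `degrees` (tibble `arm`, `degree`, `count`) and
#'   `ks_statistic`.
#' @export
degree_comparison <- function(graph, design) {
  assert_graph(graph)
  assert_design(design, graph)
  deg <- igraph::degree(graph)
  dt <- deg[arm_nodes(design, "TREATED")]
  dc <- deg[arm_nodes(design, "CONTROL")]
  if (length(dt) == 0 || length(dc) == 0) abort("both arms must be non-empty")
  grid <- sort(unique(c(dt, dc)))
  ks <- max(abs(stats::ecdf(dt)(grid) - stats::ecdf(dc)(grid)))
  degrees <- bind_rows(
    tibble(arm = "TREATED", degree = dt),
    tibble(arm = "CONTROL", degree = dc)
  ) |>
    count(.data$arm, .data$degree, name = "count")
  list(degrees = degrees, ks_statistic = ks)
}
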