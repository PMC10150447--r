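# Cluster-matching design for total treatment effects. Stage 1 (clustering,
# see cluster_mcl/cluster_reldg) minimizes cross-arm spillover; stage 2
# (here) minimizes selection bias: nodes are matched on covariates across
# clusters, cluster-pair weights summarize those matches, a cluster graph of
# candidate matches is thresholded, and an exact maximum-weight matching
# picks disjoint cluster pairs, each split across treatment and control.

#' Cross-cluster node matching
#'
#' Two rules:
#' * **Threshold matching (`"tnm"`)** — all cross-cluster pairs with
#'   similarity strictly above `alpha` are matched, where `alpha` is the
#'   chosen quartile (`alpha_q` 0-3) of the pairwise similarity
#'   distribution (`alpha_q = 0` means no threshold: every pair matches).
#'   A node may match many nodes; matches are symmetric.
#' * **Best matching (`"bnm"`)** — each node matches only its most similar
#'   node among nodes of *other* clusters; matches may be asymmetric.
#'
#' @param clustering Clustering tibble covering the graph.
#' @param X Node attribute matrix (one row per node).
#' @param rule `"tnm"` or `"bnm"`.
#' @param alpha_q Quartile (0, 1, 2, 3) for the TNM threshold.
#' @param metric Similarity metric, see [pair_similarity()].
#' @param attr_range Attribute bounds for similarity normalization.
#' @param max_quantile_pairs Cap on pairs used to estimate the similarity
#'   quartiles (a seeded uniform sample is taken above it).
#' @param seed Seed for the quantile subsample.
#' @return A `node_match_set`: list with `rule`, `alpha` (TNM only), and
#'   `matches`, a tibble with columns `k`, `l`, `sim` (for TNM, `k < l`;
#'   for BNM, directed `k -> l`).
#' @export
node_matches <- function(clustering, X, rule = c("tnm", "bnm"), alpha_q = 2,
                         metric = "l2", attr_range = c(-1, 1),
                         max_quantile_pairs = 1e6, seed = NULL) {
  rule <- match.arg(rule)
  assert_clustering(clustering)
  n <- nrow(X)
  lab <- clustering$cluster[order(clustering$node)]
  if (length(lab) != n) abort("clustering and attribute matrix disagree on n")
  if (n < 2) abort("need at least two nodes to match")
  pairs <- t(combn(n, 2))
  cross <- lab[pairs[, 1]] != lab[pairs[, 2]]
  if (rule == "tnm") {
    stopifnot(alpha_q %in% 0:3)
    sim_all <- pair_similarity(X, pairs, metric = metric, attr_range = attr_range)
    if (length(sim_all) <= 1 || isTRUE(all.equal(min(sim_all), max(sim_all)))) {
      warn("degenerate similarity distribution: all pairwise similarities are equal")
    }
    alpha <- if (alpha_q == 0) {
      0
    } else {
      qs <- sim_all
      if (length(qs) > max_quantile_pairs) {
        qs <- with_seed_if(seed, sample(qs, max_quantile_pairs))
      }
      unname(quantile(qs, alpha_q / 4))
    }
    keep <- cross & sim_all > alpha
    matches <- tibble(k = pairs[keep, 1], l = pairs[keep, 2], sim = sim_all[keep])
  } else {
    alpha <- NA_real_
    k <- integer(n)
    l <- integer(n)
    s <- numeric(n)
    for (v in seq_len(n)) {
      others <- which(lab != lab[v])
      if (length(others) == 0) {
        l[v] <- NA_integer_
        next
      }
      sims <- pair_similarity(X, cbind(v, others), metric = metric, attr_range = attr_range)
      bi <- which.max(sims)
      k[v] <- v
      l[v] <- others[bi]
      s[v] <- sims[bi]
    }
    ok <- !is.na(l) & k > 0
    matches <- tibble(k = k[ok], l = l[ok], sim = s[ok])
  }
  structure(
    list(rule = rule, alpha = alpha, matches = matches),
    class = "node_match_set"
  )
}

#' Pairwise cluster weights
#'
#' Summarizes the node matches between every pair of clusters into a single
#' similarity weight:
#' * `"c"` — count of matched node pairs;
#' * `"s"` — average similarity of matched pairs (0 when none);
#' * `"mc"`, `"ms"`, `"mss"` — count / average / sum recomputed after an
#'   exact maximum-weight bipartite matching over the threshold-admissible
#'   pairs, so each node is used at most once (TNM matches only);
#' * `"e"` — negated Euclidean distance between the clusters' attribute
#'   mean vectors (no node matches involved; larger is more similar).
#'
#' @param matchset A `node_match_set` from [node_matches()] (ignored for
#'   `"e"`, which may pass `NULL`).
#' @param clustering Clustering tibble.
#' @param X Node attribute matrix (required for `"e"`).
#' @param method One of `"c"`, `"s"`, `"mc"`, `"ms"`, `"mss"`, `"e"`.
#' @return A tibble with one row per unordered cluster pair: `ci`, `cj`
#'   (`ci < cj`) and weight `w`.
#' @export
cluster_weights <- function(matchset, clustering, X = NULL,
                            method = c("c", "s", "mc", "ms", "mss", "e")) {
  method <- match.arg(method)
  assert_clustering(clustering)
  lab <- clustering$cluster[order(clustering$node)]
  g <- max(lab)
  cp <- if (g >= 2) t(combn(g, 2)) else matrix(integer(), ncol = 2)
  out <- tibble(ci = cp[, 1], cj = cp[, 2], w = 0)
  if (method == "e") {
    if (is.null(X)) abort("Euclidean cluster weights need the attribute matrix X")
    means <- rowsum(X, lab) / as.vector(table(lab))
    out$w <- -unname(sqrt(rowSums((means[out$ci, , drop = FALSE] - means[out$cj, , drop = FALSE])^2)))
    return(out)
  }
  if (!inherits(matchset, "node_match_set")) abort("`matchset` must come from node_matches()")
  if (method %in% c("mc", "ms", "mss") && matchset$rule != "tnm") {
    abort("cluster weight methods mc/ms/mss require threshold node matching (BNM is not supported)")
  }
  m <- matchset$matches
  if (nrow(m) == 0) return(out)
  mci <- pmin(lab[m$k], lab[m$l])
  mcj <- pmax(lab[m$k], lab[m$l])
  key <- paste(mci, mcj)
  if (method %in% c("c", "s")) {
    agg <- tibble(key = key, sim = m$sim) |>
      group_by(.data$key) |>
      summarise(cnt = n(), avg = mean(.data$sim), .groups = "drop")
    idx <- match(paste(out$ci, out$cj), agg$key)
    out$w <- switch(method,
      c = ifelse(is.na(idx), 0, agg$cnt[idx]),
      s = ifelse(is.na(idx), 0, agg$avg[idx])
    )
    return(out)
  }
  # mc / ms / mss: per cluster pair, exact bipartite matching restricted to
  # the admissible (threshold-passing) pairs
  for (r in which(paste(out$ci, out$cj) %in% unique(key))) {
    sel <- which(mci == out$ci[r] & mcj == out$cj[r])
    sub <- m[sel, ]
    verts <- unique(c(sub$k, sub$l))
    matched <- max_weight_matching(
      data.frame(i = match(sub$k, verts), j = match(sub$l, verts), w = sub$sim),
      length(verts)
    )
    out$w[r] <- switch(method,
      mc = nrow(matched),
      ms = if (nrow(matched) > 0) mean(matched$w) else 0,
      mss = sum(matched$w)
    )
  }
  out
}

#' Build the candidate cluster graph
#'
#' Decides which cluster pairs are allowed to be matched:
#' * **Threshold rule (`"tcm"`)** — keep pairs with weight strictly above
#'   `beta`, the chosen quartile (`beta_q` 1-3) of the cluster-weight
#'   distribution; `beta_q = 0` keeps every pair.
#' * **Greedy rule (`"gcm"`)** — each cluster keeps only the edge to its
#'   top-weight partner (union over clusters; ties to the lowest index).
#'
#' @param weights Cluster-weight tibble from [cluster_weights()].
#' @param rule `"tcm"` or `"gcm"`.
#' @param beta_q Quartile (0-3) for the TCM threshold.
#' @return A `cluster_graph`: list with `candidates` (tibble `ci`, `cj`,
#'   `w`), the full `weights`, `rule`, and `beta` (TCM only).
#' @export
build_cluster_graph <- function(weights, rule = c("tcm", "gcm"), beta_q = 2) {
  rule <- match.arg(rule)
  stopifnot(all(c("ci", "cj", "w") %in% names(weights)))
  if (rule == "tcm") {
    stopifnot(beta_q %in% 0:3)
    beta <- if (beta_q == 0) -Inf else unname(quantile(weights$w, beta_q / 4))
    cand <- weights[weights$w > beta, , drop = FALSE]
  } else {
    beta <- NA_real_
    gs <- unique(c(weights$ci, weights$cj))
    keep <- logical(nrow(weights))
    for (cl in gs) {
      inc <- which(weights$ci == cl | weights$cj == cl)
      if (length(inc) > 0) keep[inc[which.max(weights$w[inc])]] <- TRUE
    }
    cand <- weights[keep, , drop = FALSE]
  }
  structure(
    list(candidates = as_tibble(cand), weights = as_tibble(weights), rule = rule, beta = beta),
    class = "cluster_graph"
  )
}

#' Match clusters by maximum-weight matching
#'
#' Solves the cluster-matching objective: choose disjoint cluster pairs
#' among the candidate edges maximizing the total weight, each cluster used
#' at most once. Distance-based (non-positive) weights are shifted to be
#' strictly positive first, so the matcher pairs as many clusters as
#' possible while preferring small distances.
#'
#' @param cg A `cluster_graph` from [build_cluster_graph()].
#' @return A tibble of matched cluster pairs (`ci`, `cj`, `w` on the
#'   original weight scale).
#' @export
match_clusters <- function(cg) {
  if (!inherits(cg, "cluster_graph")) abort("`cg` must come from build_cluster_graph()")
  cand <- cg$candidates
  if (nrow(cand) == 0) {
    return(tibble(ci = integer(), cj = integer(), w = numeric()))
  }
  w <- cand$w
  if (any(w <= 0)) {
    w <- w - min(w) + max(1e-3, 1e-3 * (max(w) - min(w)))
  }
  g <- max(c(cand$ci, cand$cj))
  matched <- max_weight_matching(data.frame(i = cand$ci, j = cand$cj, w = w), g)
  if (nrow(matched) == 0) {
    return(tibble(ci = integer(), cj = integer(), w = numeric()))
  }
  orig <- cand$w[match(
    paste(matched$i, matched$j),
    paste(pmin(cand$ci, cand$cj), pmax(cand$ci, cand$cj))
  )]
  tibble(ci = matched$i, cj = matched$j, w = orig)
}

#' Cluster-matching experiment design
#'
#' Runs the full stage-2 pipeline — node matching, cluster weights,
#' candidate cluster graph, exact maximum-weight cluster matching — and for
#' every matched cluster pair sends one cluster (all its nodes) to
#' treatment and the other to control by a seeded coin flip. Clusters left
#' unmatched are `EXCLUDED` from the experiment.
#'
#' The default option bundle is threshold node matching at the median
#' (`alpha_q = 2`), matched-node-count weights, and a median cluster
#' threshold (`beta_q = 2`).
#'
#' @param graph Undirected igraph object with node attributes.
#' @param clustering Clustering tibble (from [cluster_mcl()] or
#'   [cluster_reldg()]); when `NULL` one is computed via `cluster_algo`.
#' @param cluster_algo `"mcl"` or `"reldg"` (used when `clustering` is
#'   `NULL`; reLDG also needs `k`).
#' @param k Cluster count for reLDG.
#' @param node_rule,alpha_q Node matching rule and threshold quartile, see
#'   [node_matches()].
#' @param weight_method Cluster weight method, see [cluster_weights()].
#' @param cluster_rule,beta_q Candidate rule and threshold quartile, see
#'   [build_cluster_graph()].
#' @param metric Similarity metric.
#' @param seed Optional integer seed (drives clustering, quantile sampling,
#'   and the coin flips).
#' @return A design tibble with columns `node`, `name`, `arm`.
#' @export
design_cmatch <- function(graph, clustering = NULL, cluster_algo = c("mcl", "reldg"),
                          k = NULL, node_rule = "tnm", alpha_q = 2,
                          weight_method = "c", cluster_rule = "tcm", beta_q = 2,
                          metric = "l2", seed = NULL) {
  assert_graph(graph)
  cluster_algo <- match.arg(cluster_algo)
  X <- require_attrs(graph, "design_cmatch()")
  rng <- igraph::graph_attr(graph, "attr_range")
  with_seed_if(seed, {
    if (is.null(clustering)) {
      clustering <- switch(cluster_algo,
        mcl = cluster_mcl(graph),
        reldg = {
          if (is.null(k)) abort("reLDG clustering needs `k`")
          cluster_reldg(graph, k)
        }
      )
    }
    assert_clustering(clustering, graph)
    ms <- if (weight_method == "e") {
      NULL
    } else {
      node_matches(clustering, X,
        rule = node_rule, alpha_q = alpha_q,
        metric = metric, attr_range = rng
      )
    }
    wts <- cluster_weights(ms, clustering, X = X, method = weight_method)
    cg <- build_cluster_graph(wts, rule = cluster_rule, beta_q = beta_q)
    pairs <- match_clusters(cg)
    if (nrow(pairs) == 0) abort("no cluster pair survived matching; no experiment constructed")
    lab <- clustering$cluster[order(clustering$node)]
    arm <- rep("EXCLUDED", length(lab))
    for (r in seq_len(nrow(pairs))) {
      fl <- sample(c("TREATED", "CONTROL"))
      arm[lab == pairs$ci[r]] <- fl[1]
      arm[lab == pairs$cj[r]] <- fl[2]
    }
    new_design(graph, arm)
  })
}
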