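# Node-pair similarity measures and edge spillover probability assignment.
# Tie strength between two nodes, proxied by covariate similarity, stands in
# for the probability that influence crosses the edge between them.

#' Pairwise node similarity
#'
#' Computes a similarity in `[0, 1]` for each requested node pair:
#'
#' * `"l2"` — one minus the normalized Euclidean distance,
#'   `1 - ||x_i - x_j|| / M`. The normalizer `M` is the theoretical maximum
#'   distance `diff(attr_range) * sqrt(d)` when attribute bounds are known,
#'   otherwise the largest distance observed among the requested pairs.
#' * `"cosine"` — cosine similarity with negative values clamped to 0 (so 0
#'   keeps meaning "no affinity"); a zero vector has similarity 0 to
#'   everything.
#' * `"jaccard"` — the generalized (Ruzicka) form `sum(min) / sum(max)` on
#'   vectors shifted to be non-negative by the attribute lower bound (binary
#'   attributes reduce to classic Jaccard).
#'
#' @param X Numeric matrix of node attributes, one row per node.
#' @param pairs Two-column integer matrix of row indices into `X`; defaults
#'   to all unordered pairs.
#' @param metric `"l2"`, `"cosine"`, or `"jaccard"`.
#' @param attr_range Known attribute bounds, e.g. `c(-1, 1)`; `NULL` to fall
#'   back to observed normalization.
#' @return Numeric vector of similarities, one per pair, each in `[0, 1]`.
#' @export
pair_similarity <- function(X, pairs = NULL, metric = c("l2", "cosine", "jaccard"),
                            attr_range = c(-1, 1)) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  if (is.null(pairs)) {
    pairs <- t(combn(nrow(X), 2))
  }
  pairs <- matrix(as.integer(pairs), ncol = 2)
  xi <- X[pairs[, 1], , drop = FALSE]
  xj <- X[pairs[, 2], , drop = FALSE]
  switch(metric,
    l2 = {
      d2 <- sqrt(rowSums((xi - xj)^2))
      M <- if (!is.null(attr_range)) {
        diff(attr_range) * sqrt(ncol(X))
      } else {
        max(d2, .Machine$double.eps)
      }
      pmin(pmax(1 - d2 / M, 0), 1)
    },
    cosine = {
      ni <- sqrt(rowSums(xi^2))
      nj <- sqrt(rowSums(xj^2))
      s <- rowSums(xi * xj) / pmax(ni * nj, .Machine$double.eps)
      s[ni == 0 | nj == 0] <- 0
      pmin(pmax(s, 0), 1)
    },
    jaccard = {
      lo <- if (!is.null(attr_range)) attr_range[1] else min(X)
      xi <- xi - lo
      xj <- xj - lo
      num <- rowSums(pmin(xi, xj))
      den <- rowSums(pmax(xi, xj))
      ifelse(den == 0, 1, num / den)
    }
  )
}

#' Assign spillover probabilities to every edge
#'
#' Every edge receives a probability `p` of transmitting influence: either a
#' fixed constant or the covariate similarity of its endpoints.
#'
#' @param graph Undirected igraph object (attributes required in
#'   `"similarity"` mode).
#' @param mode `"fixed"` or `"similarity"`.
#' @param p Constant probability for `"fixed"` mode (default 0.1).
#' @param metric Similarity metric for `"similarity"` mode, see
#'   [pair_similarity()].
#' @return The graph with edge attribute `p` set.
#' @export
add_edge_probabilities <- function(graph, mode = c("fixed", "similarity"),
                                   p = 0.1, metric = "l2") {
  assert_graph(graph)
  mode <- match.arg(mode)
  m <- igraph::ecount(graph)
  if (mode == "fixed") {
    stopifnot(length(p) == 1, p >= 0, p <= 1)
    igraph::E(graph)$p <- rep(as.numeric(p), m)
  } else {
    X <- require_attrs(graph, "similarity-based edge probabilities")
    el <- igraph::as_edgelist(graph, names = FALSE)
    rng <- igraph::graph_attr(graph, "attr_range")
    igraph::E(graph)$p <- pair_similarity(X, el, metric = metric, attr_range = rng)
  }
  graph
}
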