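# Graph clustering back-ends for the two-stage designs: Markov clustering
# (weighted, chooses its own number of clusters) and restreamed linear
# deterministic greedy partitioning (unweighted, balanced, k given).

#' Markov clustering (MCL)
#'
#' Simulates random-walk flow on the (self-looped) weighted adjacency
#' matrix, alternating expansion (matrix power) with inflation
#' (element-wise power and column renormalization) and pruning small
#' entries, until the flow matrix stabilizes. Clusters are read off the
#' attractor rows; a node reachable from several attractors goes to the
#' lowest-index one. Disconnected components are never merged.
#'
#' @param graph Undirected igraph object; edge attribute `p` is used as the
#'   weight when present (unweighted edges count 1).
#' @param inflation Inflation exponent (> 1, default 2).
#' @param expansion Expansion power (integer >= 2, default 2).
#' @param add_self_loops Add a self-loop per node weighted by its maximum
#'   incident weight (stabilizes the iteration; default `TRUE`).
#' @param prune_tol Entries below this are dropped each iteration.
#' @param max_iter Iteration cap; non-convergence returns the current state
#'   with attribute `converged = FALSE` and a warning.
#' @param conv_tol Convergence threshold on the largest entry change.
#' @return A clustering tibble (`node`, `name`, `cluster`) with attributes
#'   `converged` and `iterations`.
#' @export
cluster_mcl <- function(graph, inflation = 2, expansion = 2, add_self_loops = TRUE,
                        prune_tol = 1e-5, max_iter = 100, conv_tol = 1e-8) {
  assert_graph(graph)
  stopifnot(inflation > 1, expansion >= 2)
  n <- igraph::vcount(graph)
  if (n == 0) abort("graph has no nodes")
  w <- igraph::edge_attr(graph, "p")
  if (is.null(w)) w <- rep(1, igraph::ecount(graph))
  if (any(w < 0)) abort("MCL requires non-negative edge weights")
  el <- igraph::as_edgelist(graph, names = FALSE)
  i <- c(el[, 1], el[, 2])
  j <- c(el[, 2], el[, 1])
  x <- c(w, w)
  if (add_self_loops) {
    loopw <- rep(1, n)
    if (length(x) > 0) {
      mx <- tapply(x, i, max)
      loopw[as.integer(names(mx))] <- pmax(mx, .Machine$double.eps)
    }
    i <- c(i, seq_len(n))
    j <- c(j, seq_len(n))
    x <- c(x, loopw)
  }
  M <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  normalize_cols <- function(M) {
    cs <- Matrix::colSums(M)
    cs[cs == 0] <- 1
    M %*% Matrix::Diagonal(x = 1 / cs)
  }
  M <- normalize_cols(M)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    Mnew <- M
    for (e in seq_len(expansion - 1)) Mnew <- Mnew %*% M
    Mnew <- Mnew^inflation
    Mnew <- normalize_cols(Mnew)
    Mnew <- Matrix::drop0(Mnew * (Mnew >= prune_tol))
    Mnew <- normalize_cols(Mnew)
    delta <- max(abs(Mnew - M))
    M <- Mnew
    if (delta < conv_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warn("MCL did not converge within max_iter; returning current state")
  M <- as(M, "TsparseMatrix")
  ri <- M@i + 1L
  ci <- M@j + 1L
  attractors <- sort(unique(ri[ri == ci & M@x > prune_tol]))
  label <- integer(n)
  # each column is claimed by its lowest-index attractor row
  for (a in rev(attractors)) {
    label[ci[ri == a]] <- a
  }
  orphan <- which(label == 0)
  for (v in orphan) {
    rows <- ri[ci == v]
    label[v] <- if (length(rows) > 0) min(rows) else v
  }
  cl <- match(label, sort(unique(label)))
  out <- tibble(node = seq_len(n), name = node_names(graph), cluster = cl)
  attr(out, "converged") <- converged
  attr(out, "iterations") <- iter
  out
}

#' Restreamed linear deterministic greedy partitioning (reLDG)
#'
#' Streams the nodes in a seeded random order, assigning each to the cluster
#' maximizing `(neighbours already in the cluster) * (1 - size / capacity)`
#' subject to the capacity `ceiling(n / k)` (ties to the lowest cluster
#' index). Subsequent passes restream against the previous partition's
#' labels, which monotonically tightens the cut in practice.
#'
#' @param graph Undirected igraph object (edge weights are ignored: the
#'   partitioner is deliberately unweighted).
#' @param k Number of clusters (1..n).
#' @param passes Restream passes (default 10).
#' @param seed Optional integer seed for the stream order.
#' @return A clustering tibble (`node`, `name`, `cluster`).
#' @export
cluster_reldg <- function(graph, k, passes = 10, seed = NULL) {
  assert_graph(graph)
  n <- igraph::vcount(graph)
  stopifnot(k >= 1, k <= n, passes >= 1)
  capacity <- ceiling(n / k)
  adj <- adjacency_int(graph)
  with_seed_if(seed, {
    order_ <- sample.int(n)
    label <- integer(n) # 0 = unassigned (first pass only)
    for (pass in seq_len(passes)) {
      sizes <- integer(k)
      newlab <- integer(n)
      for (v in order_) {
        # first pass: greedy against nodes already placed in this stream;
        # later passes: against the full previous partition
        nb <- if (pass == 1) newlab[adj[[v]]] else label[adj[[v]]]
        cnt <- tabulate(nb[nb > 0], nbins = k)
        score <- cnt * (1 - sizes / capacity)
        score[sizes >= capacity] <- -Inf
        best <- which.max(score) # lowest index wins ties
        newlab[v] <- best
        sizes[best] <- sizes[best] + 1L
      }
      if (all(newlab == label)) {
        label <- newlab
        break
      }
      label <- newlab
    }
    tibble(node = seq_len(n), name = node_names(graph), cluster = label)
  })
}

assert_clustering <- function(clustering, graph = NULL) {
  if (!is.data.frame(clustering) || !all(c("node", "cluster") %in% names(clustering))) {
    abort("a clustering is a data frame with columns `node` and `cluster`")
  }
  if (anyDuplicated(clustering$node)) abort("clustering labels some node twice")
  if (!is.null(graph) && nrow(clustering) != igraph::vcount(graph)) {
    abort("clustering must label every graph node")
  }
  invisible(clustering)
}

#' Cut statistics of a clustering
#'
#' @param graph Undirected igraph object.
#' @param clustering A clustering tibble.
#' @return Number of edges crossing clusters.
#' @keywords internal
cut_edges <- function(graph, clustering) {
  el <- igraph::as_edgelist(graph, names = FALSE)
  lab <- clustering$cluster[order(clustering$node)]
  sum(lab[el[, 1]] != lab[el[, 2]])
}
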