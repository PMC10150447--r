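# Reference designs: node-level randomization, similarity-matched pairs,
# and the two stratified cluster designs (node-randomized-within-strata CR
# and cluster-randomized CBR).

#' Node-level randomized design
#'
#' Ignores the network entirely: a seeded uniform split of all nodes into
#' treatment and control with sizes differing by at most one.
#'
#' @param graph Undirected igraph object with at least 2 nodes.
#' @param seed Optional integer seed.
#' @return A design tibble (`node`, `name`, `arm`) with no `EXCLUDED` nodes.
#' @export
design_randomized <- function(graph, seed = NULL) {
  assert_graph(graph)
  n <- igraph::vcount(graph)
  if (n < 2) abort("need at least 2 nodes")
  with_seed_if(seed, {
    nt <- floor(n / 2) + if (n %% 2 == 1) rbinom(1, 1, 0.5) else 0
    arm <- rep("CONTROL", n)
    arm[sample.int(n, nt)] <- "TREATED"
    new_design(graph, arm)
  })
}

#' Matched-pairs design
#'
#' Pairs nodes by maximum-weight matching on attribute similarity and
#' splits every pair across arms by coin flip; with odd `n` the leftover
#' node is randomized. Matching is exact up to 1000 nodes and greedy over
#' top-50 similarity candidates above that.
#'
#' @param graph Undirected igraph object with node attributes.
#' @param seed Optional integer seed.
#' @param metric Similarity metric, see [pair_similarity()].
#' @return A design tibble with no `EXCLUDED` nodes.
#' @export
design_match <- function(graph, seed = NULL, metric = "l2") {
  assert_graph(graph)
  X <- require_attrs(graph, "design_match()")
  rng <- igraph::graph_attr(graph, "attr_range")
  n <- igraph::vcount(graph)
  if (n < 2) abort("need at least 2 nodes")
  with_seed_if(seed, {
    sm <- similarity_matching(X, metric = metric, attr_range = rng)
    arm <- rep(NA_character_, n)
    for (r in seq_len(nrow(sm$pairs))) {
      fl <- sample(c("TREATED", "CONTROL"))
      arm[sm$pairs[r, 1]] <- fl[1]
      arm[sm$pairs[r, 2]] <- fl[2]
    }
    if (length(sm$unmatched) > 0) {
      arm[sm$unmatched] <- sample(c("TREATED", "CONTROL"), length(sm$unmatched), replace = TRUE)
    }
    new_design(graph, arm)
  })
}

# pair clusters into strata of two by repeatedly joining the globally
# closest pair of unpaired cluster attribute means; an odd leftover cluster
# forms a singleton stratum
pair_strata_greedy <- function(means) {
  g <- nrow(means)
  if (g == 1) {
    return(list(c(1L)))
  }
  D <- as.matrix(stats::dist(means))
  diag(D) <- Inf
  unpaired <- seq_len(g)
  strata <- list()
  while (length(unpaired) >= 2) {
    sub <- D[unpaired, unpaired, drop = FALSE]
    ij <- arrayInd(which.min(sub), dim(sub))
    pairn <- unpaired[c(ij[1, 1], ij[1, 2])]
    strata[[length(strata) + 1]] <- sort(pairn)
    unpaired <- setdiff(unpaired, pairn)
  }
  if (length(unpaired) == 1) strata[[length(strata) + 1]] <- unpaired
  strata
}

#' Stratified cluster designs (CR and CBR)
#'
#' Clusters the graph with reLDG into `k` clusters, pairs similar clusters
#' into strata of two (greedy nearest cluster attribute means), then:
#' * **CBR** (`mode = "cbr"`) — per stratum, a coin sends one whole cluster
#'   to treatment and the other to control (a singleton stratum from odd
#'   `k` is randomized whole);
#' * **CR** (`mode = "cr"`) — nodes are individually randomized 50/50
#'   within each stratum.
#'
#' @param graph Undirected igraph object (attributes required for the
#'   stratification step).
#' @param k Number of reLDG clusters (`k >= 2`).
#' @param seed Optional integer seed.
#' @param mode `"cbr"` or `"cr"`.
#' @param clustering Optional precomputed clustering to use instead of
#'   running reLDG.
#' @param pair_clusters Optional hook: a function from the `g x d` matrix
#'   of cluster attribute means to a list of strata (integer vectors),
#'   replacing the default greedy nearest-neighbour pairing.
#' @return A design tibble with no `EXCLUDED` nodes.
#' @export
design_cbr <- function(graph, k, seed = NULL, mode = c("cbr", "cr"),
                       clustering = NULL, pair_clusters = pair_strata_greedy) {
  assert_graph(graph)
  mode <- match.arg(mode)
  X <- require_attrs(graph, "design_cbr()")
  n <- igraph::vcount(graph)
  stopifnot(k >= 2)
  with_seed_if(seed, {
    if (is.null(clustering)) clustering <- cluster_reldg(graph, k)
    assert_clustering(clustering, graph)
    lab <- clustering$cluster[order(clustering$node)]
    g <- max(lab)
    means <- rowsum(X, lab) / as.vector(table(lab))
    strata <- pair_clusters(means)
    arm <- rep(NA_character_, n)
    for (s in strata) {
      if (mode == "cbr") {
        if (length(s) == 2) {
          fl <- sample(c("TREATED", "CONTROL"))
          arm[lab == s[1]] <- fl[1]
          arm[lab == s[2]] <- fl[2]
        } else {
          arm[lab == s[1]] <- sample(c("TREATED", "CONTROL"), 1)
        }
      } else {
        idx <- which(lab %in% s)
        ns <- length(idx)
        nt <- floor(ns / 2) + if (ns %% 2 == 1) rbinom(1, 1, 0.5) else 0
        a <- rep("CONTROL", ns)
        a[sample.int(ns, nt)] <- "TREATED"
        arm[idx] <- a
      }
    }
    new_design(graph, arm)
  })
}
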