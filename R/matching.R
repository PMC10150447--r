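# Maximum-weight matching (general graphs, exact) plus the similarity-graph
# node matching used by matched designs.

#' Exact maximum-weight matching
#'
#' Finds a matching maximizing the total edge weight on an arbitrary
#' weighted graph via the blossom algorithm (compiled, O(n^3)). Edges with
#' non-positive weight never enter a maximum-weight matching and are
#' ignored; ties are broken deterministically.
#'
#' @param edges Data frame with integer columns `i`, `j` (1-based vertex
#'   ids) and numeric `w`. Weights are handled to a resolution of 1e-6.
#' @param n Number of vertices.
#' @return A tibble of matched pairs with columns `i`, `j` (`i < j`) and `w`.
#' @examples
#' edges <- data.frame(i = c(1, 3, 2), j = c(2, 4, 3), w = c(3, 3, 5))
#' max_weight_matching(edges, 4) # picks (1,2) and (3,4): 6 beats 5
#' @export
max_weight_matching <- function(edges, n) {
  stopifnot(n >= 0)
  if (n == 0 || nrow(edges) == 0) {
    return(tibble(i = integer(), j = integer(), w = numeric()))
  }
  key <- pmin(edges$i, edges$j) * (n + 1) + pmax(edges$i, edges$j)
  ord <- order(key, -edges$w)
  first <- !duplicated(key[ord]) # keep the heaviest parallel edge
  ei <- as.integer(edges$i[ord][first])
  ej <- as.integer(edges$j[ord][first])
  ew <- as.numeric(edges$w[ord][first])
  mate <- blossom_matching(ei, ej, ew, as.integer(n))
  i <- which(mate > seq_len(n))
  if (length(i) == 0) {
    return(tibble(i = integer(), j = integer(), w = numeric()))
  }
  j <- mate[i]
  w <- ew[match(i * (n + 1) + j, pmin(ei, ej) * (n + 1) + pmax(ei, ej))]
  tibble(i = i, j = j, w = w)
}

# Match nodes on attribute similarity. Exact maximum-weight matching over
# the complete similarity graph up to `exact_max` nodes; beyond that, each
# node contributes its `k` most similar candidates and a greedy
# highest-weight-first pass matches them (the dense blossom's O(n^2) memory
# makes the exact route impractical for large n).
similarity_matching <- function(X, nodes = seq_len(nrow(X)), metric = "l2",
                                attr_range = c(-1, 1), exact_max = 1000, k = 50) {
  m <- length(nodes)
  if (m < 2) {
    return(list(pairs = matrix(integer(), ncol = 2), unmatched = nodes))
  }
  Xs <- X[nodes, , drop = FALSE]
  if (m <= exact_max) {
    pairs <- t(combn(m, 2))
    w <- pair_similarity(Xs, pairs, metric = metric, attr_range = attr_range)
    matched <- max_weight_matching(data.frame(i = pairs[, 1], j = pairs[, 2], w = w), m)
    pr <- cbind(nodes[matched$i], nodes[matched$j])
  } else {
    cand <- top_k_candidates(Xs, metric, attr_range, k)
    ord <- order(cand$w, decreasing = TRUE)
    used <- logical(m)
    pi <- integer(0)
    pj <- integer(0)
    for (e in ord) {
      a <- cand$i[e]
      b <- cand$j[e]
      if (!used[a] && !used[b]) {
        used[a] <- used[b] <- TRUE
        pi <- c(pi, a)
        pj <- c(pj, b)
      }
    }
    pr <- cbind(nodes[pi], nodes[pj])
  }
  list(pairs = pr, unmatched = setdiff(nodes, as.vector(pr)))
}

# chunked top-k most-similar candidate edges over all rows of X
top_k_candidates <- function(X, metric, attr_range, k) {
  m <- nrow(X)
  chunk <- max(1L, floor(2e6 / m))
  ii <- integer(0)
  jj <- integer(0)
  ww <- numeric(0)
  for (start in seq(1L, m, by = chunk)) {
    rows <- start:min(start + chunk - 1L, m)
    pairs <- cbind(rep(rows, each = m), rep(seq_len(m), length(rows)))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    w <- pair_similarity(X, pairs, metric = metric, attr_range = attr_range)
    for (ri in seq_along(rows)) {
      sel <- which(pairs[, 1] == rows[ri])
      top <- sel[order(w[sel], decreasing = TRUE)[seq_len(min(k, length(sel)))]]
      ii <- c(ii, pairs[top, 1])
      jj <- c(jj, pairs[top, 2])
      ww <- c(ww, w[top])
    }
  }
  a <- pmin(ii, jj)
  b <- pmax(ii, jj)
  keep <- !duplicated(a * (m + 1) + b)
  list(i = a[keep], j = b[keep], w = ww[keep])
}
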