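# Fixture builders and independent oracles used across the suite.

# small named graph from an edge matrix (2 columns of 1-based ids)
mk_graph <- function(edges, n = max(edges)) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

path_graph <- function(n) mk_graph(cbind(seq_len(n - 1), 2:n), n)

star_graph <- function(leaves) mk_graph(cbind(1L, 1L + seq_len(leaves)), leaves + 1)

# two K4 cliques joined by a single bridge edge (1-4 | 5-8)
two_cliques_graph <- function() {
  k4 <- t(combn(4, 2))
  mk_graph(rbind(k4, k4 + 4L, c(4L, 5L)), 8)
}

# planted-partition graph: `g` dense blocks of size `size`, sparse across;
# block members share (nearly) identical attributes
planted_graph <- function(g = 4, size = 10, p_in = 0.8, p_out = 0.02, d = 3, seed = 1,
                          sizes = rep(size, g)) {
  withr::with_seed(seed, {
    n <- sum(sizes)
    block <- rep(seq_along(sizes), times = sizes)
    pairs <- t(combn(n, 2))
    same <- block[pairs[, 1]] == block[pairs[, 2]]
    keep <- runif(nrow(pairs)) < ifelse(same, p_in, p_out)
    gr <- mk_graph(pairs[keep, , drop = FALSE], n)
    centers <- matrix(runif(length(sizes) * d, -1, 1), length(sizes))
    X <- centers[block, ] + matrix(runif(n * d, -0.01, 0.01), n)
    X <- pmin(pmax(X, -1), 1)
    netdesign::node_attr_matrix(gr) <- X
    igraph::graph_attr(gr, "attr_range") <- c(-1, 1)
    gr
  })
}

attach_attrs <- function(g, X) {
  netdesign::node_attr_matrix(g) <- X
  igraph::graph_attr(g, "attr_range") <- c(-1, 1)
  g
}

# --- oracles -----------------------------------------------------------------

# exhaustive maximum-weight matching by recursion over edges
brute_force_mwm <- function(edges, n) {
  best <- 0
  rec <- function(k, used, tot) {
    if (tot > best) best <<- tot
    if (k > nrow(edges)) {
      return()
    }
    rec(k + 1, used, tot)
    u <- edges$i[k]
    v <- edges$j[k]
    if (!used[u] && !used[v] && edges$w[k] > 0) {
      used[c(u, v)] <- TRUE
      rec(k + 1, used, tot + edges$w[k])
    }
  }
  if (nrow(edges) > 0) rec(1, logical(n), 0)
  best
}

# all independent sets of a small graph, by subset enumeration
brute_force_independent_sets <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  sets <- list()
  for (mask in 0:(2^n - 1)) {
    s <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (nrow(el) == 0 || !any(el[, 1] %in% s & el[, 2] %in% s)) {
      sets[[length(sets) + 1]] <- s
    }
  }
  sets
}

# reference forest-fire process, coded independently of the generator under
# test. Growth is directed internally (new nodes point at the nodes they
# burn): from each burned node, geometric numbers of its out-neighbours
# (mean p_f/(1-p_f)) and in-neighbours (mean p_b/(1-p_b)) catch fire
# recursively; every burned link is added undirected. Returns the edge
# count of the simplified undirected graph.
reference_forest_fire <- function(n, p_f, p_b) {
  outs <- vector("list", n)
  ins <- vector("list", n)
  edges <- 0
  for (v in 2:n) {
    amb <- sample.int(v - 1, 1)
    burned <- amb
    frontier <- amb
    while (length(frontier) > 0) {
      w <- frontier[1]
      frontier <- frontier[-1]
      cand_f <- setdiff(outs[[w]], burned)
      cand_b <- setdiff(ins[[w]], burned)
      nf <- stats::rgeom(1, 1 - p_f)
      nb <- stats::rgeom(1, 1 - p_b)
      pick <- c(
        cand_f[sample.int(length(cand_f))][seq_len(min(nf, length(cand_f)))],
        cand_b[sample.int(length(cand_b))][seq_len(min(nb, length(cand_b)))]
      )
      pick <- unique(pick)
      burned <- c(burned, pick)
      frontier <- c(frontier, pick)
    }
    outs[[v]] <- burned
    for (u in burned) ins[[u]] <- c(ins[[u]], v)
    edges <- edges + length(burned)
  }
  edges
}
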