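# Hand-worked fixture used throughout: two clusters {1,2} and {3,4} with
# one-dimensional attributes (0, 0.2, 0.1, 0.5) on [-1,1], so the l2
# similarity is 1 - |x_i - x_j| / 2:
#   cross-cluster sims: (1,3)=0.95 (1,4)=0.75 (2,3)=0.95 (2,4)=0.85
two_cluster_fixture <- function() {
  list(
    clustering = tibble::tibble(node = 1:4, name = as.character(1:4), cluster = c(1, 1, 2, 2)),
    X = matrix(c(0, 0.2, 0.1, 0.5), ncol = 1)
  )
}

test_that("threshold node matching matches all cross-cluster pairs at level 0", {
  fx <- two_cluster_fixture()
  ms <- node_matches(fx$clustering, fx$X, rule = "tnm", alpha_q = 0)
  expect_equal(nrow(ms$matches), 4) # within-cluster pairs excluded
  expect_true(all(fx$clustering$cluster[ms$matches$k] != fx$clustering$cluster[ms$matches$l]))
  expect_equal(sort(ms$matches$sim), c(0.75, 0.85, 0.95, 0.95))

  # stricter quartile thresholds keep a nested subset above the threshold
  ms3 <- node_matches(fx$clustering, fx$X, rule = "tnm", alpha_q = 3)
  expect_true(all(ms3$matches$sim > ms3$alpha))
  expect_true(all(
    paste(ms3$matches$k, ms3$matches$l) %in% paste(ms$matches$k, ms$matches$l)
  ))
})

test_that("best node matching takes the nearest other-cluster node and may be asymmetric", {
  clustering <- tibble::tibble(node = 1:3, name = as.character(1:3), cluster = 1:3)
  X <- matrix(c(0, 0.2, 0.21), ncol = 1)
  ms <- node_matches(clustering, X, rule = "bnm")
  key <- paste(ms$matches$k, ms$matches$l)
  expect_setequal(key, c("1 2", "2 3", "3 2")) # 1->2 and 2->3 coexist
})

test_that("cluster weights reproduce the hand-computed 2x2 values", {
  fx <- two_cluster_fixture()
  ms <- node_matches(fx$clustering, fx$X, rule = "tnm", alpha_q = 0)
  w <- function(m) cluster_weights(ms, fx$clustering, X = fx$X, method = m)$w
  expect_equal(w("c"), 4)
  expect_equal(w("s"), mean(c(0.95, 0.75, 0.95, 0.85)))
  # bipartite matching picks (1,3)+(2,4): 1.80 beats (1,4)+(2,3): 1.70
  expect_equal(w("mc"), 2)
  expect_equal(w("mss"), 1.80)
  expect_equal(w("ms"), 0.90)
  # negated Euclidean distance between cluster attribute means 0.1 and 0.3
  expect_equal(w("e"), -0.2)
  # identical means: E weight 0, the maximum under negation
  Xeq <- matrix(c(0.1, 0.3, 0.3, 0.1), ncol = 1)
  expect_equal(cluster_weights(NULL, fx$clustering, X = Xeq, method = "e")$w, 0)
})

test_that("maximum-matching weight variants reject best-node matching", {
  fx <- two_cluster_fixture()
  ms <- node_matches(fx$clustering, fx$X, rule = "bnm")
  for (m in c("mc", "ms", "mss")) {
    expect_error(cluster_weights(ms, fx$clustering, X = fx$X, method = m), "BNM")
  }
  # but c and s accept it
  expect_no_error(cluster_weights(ms, fx$clustering, X = fx$X, method = "c"))
})

test_that("matched-count bounds hold on random fixtures", {
  withr::with_seed(41, {
    for (trial in 1:10) {
      n <- 24
      clustering <- tibble::tibble(
        node = 1:n, name = as.character(1:n),
        cluster = sample(rep(1:4, each = 6))
      )
      X <- matrix(runif(n * 3, -1, 1), n)
      ms <- node_matches(clustering, X, rule = "tnm", alpha_q = 2)
      wc <- cluster_weights(ms, clustering, X = X, method = "c")
      wmc <- cluster_weights(ms, clustering, X = X, method = "mc")
      wmss <- cluster_weights(ms, clustering, X = X, method = "mss")
      expect_true(all(wmc$w <= wc$w))
      expect_true(all(wmss$w <= wc$w * max(c(ms$matches$sim, 0))))
    }
  })
})

test_that("candidate cluster graphs follow the threshold and greedy rules", {
  wts <- tibble::tibble(ci = c(1, 1, 2), cj = c(2, 3, 3), w = c(5, 3, 1))
  cg0 <- build_cluster_graph(wts, rule = "tcm", beta_q = 0)
  expect_equal(nrow(cg0$candidates), 3) # level 0 allows all pairs

  # greedy: A's best is B, B's best is A, C's best is A -> edges {A-B, A-C}
  cgg <- build_cluster_graph(wts, rule = "gcm")
  expect_setequal(paste(cgg$candidates$ci, cgg$candidates$cj), c("1 2", "1 3"))

  # a threshold at the maximum weight empties the candidate set
  cg3 <- build_cluster_graph(wts, rule = "tcm", beta_q = 3)
  expect_true(all(cg3$candidates$w > cg3$beta))
  expect_lt(nrow(cg3$candidates), 3)
  expect_equal(nrow(build_cluster_graph(
    tibble::tibble(ci = 1, cj = 2, w = c(1)), "tcm", 3
  )$candidates), 0)
})

test_that("cluster matching solves the pairing objective exactly", {
  # single candidate edge: that pair
  cg <- build_cluster_graph(tibble::tibble(ci = 1, cj = 2, w = 1), "tcm", 0)
  expect_equal(match_clusters(cg), tibble::tibble(ci = 1L, cj = 2L, w = 1))

  # (1,2)+(3,4) with total 6 beats the single heavier edge (2,3)=5
  wts <- tibble::tibble(ci = c(1, 3, 2), cj = c(2, 4, 3), w = c(3, 3, 5))
  got <- match_clusters(build_cluster_graph(wts, "tcm", 0))
  expect_setequal(paste(got$ci, got$cj), c("1 2", "3 4"))

  # every cluster used at most once, agreeing with brute force
  withr::with_seed(59, {
    for (trial in 1:20) {
      g <- sample(3:8, 1)
      pairs <- t(combn(g, 2))
      keep <- runif(nrow(pairs)) < 0.7
      if (!any(keep)) next
      wts <- tibble::tibble(ci = pairs[keep, 1], cj = pairs[keep, 2], w = runif(sum(keep)))
      got <- match_clusters(build_cluster_graph(wts, "tcm", 0))
      expect_equal(anyDuplicated(c(got$ci, got$cj)), 0)
      expect_equal(
        sum(got$w),
        brute_force_mwm(data.frame(i = wts$ci, j = wts$cj, w = wts$w), g),
        tolerance = 1e-6
      )
    }
  })
})

test_that("negated-distance weights still pair as many clusters as possible", {
  # all-E weights are <= 0; matching must not collapse to the empty set
  wts <- tibble::tibble(ci = c(1, 1, 2, 3), cj = c(2, 3, 4, 4), w = c(-0.1, -0.5, -0.4, -0.2))
  got <- match_clusters(build_cluster_graph(wts, "tcm", 0))
  expect_equal(nrow(got), 2)
  expect_setequal(paste(got$ci, got$cj), c("1 2", "3 4")) # total distance 0.3
})

test_that("the full cluster-matching design assigns whole clusters to opposite arms", {
  # two clusters with identical attribute profiles on a 6-cycle
  g <- mk_graph(cbind(1:6, c(2:6, 1)), 6)
  X <- matrix(rep(c(0.1, 0.4, 0.7), 2), ncol = 1)
  g <- attach_attrs(g, X)
  clustering <- tibble::tibble(node = 1:6, name = as.character(1:6), cluster = rep(1:2, each = 3))
  d <- design_cmatch(g, clustering = clustering, seed = 4, alpha_q = 0, beta_q = 0)
  expect_equal(sum(d$arm == "EXCLUDED"), 0)
  expect_length(unique(d$arm[1:3]), 1)
  expect_length(unique(d$arm[4:6]), 1)
  expect_true(d$arm[1] != d$arm[4])
})

test_that("an odd cluster left unmatched is excluded from the experiment", {
  # clusters A,B share a centroid; C,D share another; E sits far away with
  # greedy candidates {A-B, C-D, E->nearest}, so E must stay unmatched
  centers <- c(A = 0, B = 0, C = 0.6, D = 0.6, E = -0.95)
  n_per <- 2
  X <- matrix(rep(centers, each = n_per), ncol = 1)
  g <- attach_attrs(igraph::make_ring(10), X)
  clustering <- tibble::tibble(
    node = 1:10, name = as.character(1:10),
    cluster = rep(1:5, each = n_per)
  )
  d <- design_cmatch(g,
    clustering = clustering, seed = 2,
    weight_method = "e", cluster_rule = "gcm"
  )
  expect_equal(which(d$arm == "EXCLUDED"), 9:10)
  expect_equal(sum(d$arm == "TREATED"), 4)
  expect_equal(sum(d$arm == "CONTROL"), 4)
})

test_that("cluster matching balances covariates at least as well as cluster randomization", {
  # heterogeneous planted clusters: matching similar clusters across arms
  # should keep the arm attribute means closer than blind cluster coins
  sizes <- c(8, 8, 10, 10, 12, 12)
  g <- planted_graph(sizes = sizes, p_in = 0.5, p_out = 0.03, d = 3, seed = 15)
  clustering <- tibble::tibble(
    node = seq_len(sum(sizes)), name = as.character(seq_len(sum(sizes))),
    cluster = rep(seq_along(sizes), times = sizes)
  )
  X <- node_attr_matrix(g)
  dist_of <- function(fn) {
    mean(vapply(1:50, function(s) covariate_distance(fn(s), X), numeric(1)))
  }
  d_cmatch <- dist_of(function(s) {
    design_cmatch(g, clustering = clustering, seed = s, weight_method = "e", beta_q = 0)
  })
  d_cbr <- dist_of(function(s) {
    design_cbr(g, k = 6, seed = s, mode = "cbr", clustering = clustering)
  })
  expect_lte(d_cmatch, d_cbr)
})

test_that("no experiment is constructed when no cluster pair survives", {
  g <- attach_attrs(igraph::make_ring(4), matrix(c(0, 0, 1, 1), ncol = 1))
  clustering <- tibble::tibble(node = 1:4, name = as.character(1:4), cluster = rep(1:2, each = 2))
  # beta at the maximum weight leaves no candidate edges
  expect_error(
    design_cmatch(g, clustering = clustering, seed = 1, beta_q = 3),
    "no cluster pair"
  )
})
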