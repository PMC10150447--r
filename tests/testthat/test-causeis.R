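test_that("greedy independent sets are independent and maximal for every seed", {
  withr::with_seed(17, {
    for (trial in 1:50) {
      n <- sample(5:40, 1)
      g <- igraph::sample_gnp(n, runif(1, 0.05, 0.5))
      igraph::V(g)$name <- as.character(seq_len(n))
      mis <- greedy_mis(g, seed = trial)
      el <- igraph::as_edgelist(g, names = FALSE)
      inset <- seq_len(n) %in% mis$members
      # independence: no edge joins two members
      expect_false(any(inset[el[, 1]] & inset[el[, 2]]))
      # maximality: every bystander has a member neighbour
      adj <- igraph::as_adj_list(g)
      for (v in mis$bystanders) {
        expect_true(any(inset[as.integer(adj[[v]])]))
      }
      expect_setequal(c(mis$members, mis$bystanders), seq_len(n))
    }
  })
})

test_that("independent-set sizes match enumeration on canonical graphs", {
  tri <- mk_graph(rbind(c(1, 2), c(2, 3), c(3, 1)), 3)
  expect_length(greedy_mis(tri, seed = 1)$members, 1)

  # path a-b-c: brute force says the unique maximum is {a, c}
  sizes <- lengths(brute_force_independent_sets(path_graph(3)))
  expect_equal(max(sizes), 2)
  mis <- greedy_mis(path_graph(3), seed = 1, restarts = 20)
  expect_equal(sort(mis$members), c(1, 3))

  edgeless <- igraph::make_empty_graph(7, directed = FALSE)
  expect_length(greedy_mis(edgeless, seed = 1)$members, 7)
})

test_that("the independent-set design never places an edge inside the experiment", {
  withr::with_seed(23, {
    for (trial in 1:25) {
      g <- igraph::sample_gnp(sample(8:40, 1), runif(1, 0.1, 0.4))
      if (igraph::ecount(g) == 0) next
      d <- design_causeis(g, seed = trial)
      el <- igraph::as_edgelist(g, names = FALSE)
      arm <- d$arm
      in_exp <- arm != "EXCLUDED"
      expect_false(any(in_exp[el[, 1]] & in_exp[el[, 2]]))
      # split is balanced within one
      expect_lte(abs(sum(arm == "TREATED") - sum(arm == "CONTROL")), 1)
    }
  })
})

test_that("cycle and edgeless designs have the enumerated arm sizes", {
  c4 <- mk_graph(rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)), 4)
  d <- design_causeis(c4, seed = 5)
  expect_equal(sum(d$arm == "TREATED"), 1)
  expect_equal(sum(d$arm == "CONTROL"), 1)
  expect_equal(sum(d$arm == "EXCLUDED"), 2)
  # the two experiment nodes are an opposite (non-adjacent) pair
  exp_nodes <- sort(d$node[d$arm != "EXCLUDED"])
  expect_true(all(abs(diff(exp_nodes)) == 2))

  iso <- igraph::make_empty_graph(10, directed = FALSE)
  d2 <- design_causeis(iso, seed = 1)
  expect_equal(sum(d2$arm == "TREATED"), 5)
  expect_equal(sum(d2$arm == "CONTROL"), 5)
  expect_equal(sum(d2$arm == "EXCLUDED"), 0)
})

test_that("matched independent-set variant balances covariates better", {
  g <- generate_study_graph("ff", 150, seed = 31)
  X <- node_attr_matrix(g)
  dist_plain <- vapply(1:30, function(s) {
    covariate_distance(design_causeis(g, seed = s), X)
  }, numeric(1))
  dist_match <- vapply(1:30, function(s) {
    covariate_distance(design_causeis(g, seed = s, match = TRUE), X)
  }, numeric(1))
  expect_lt(mean(dist_match), mean(dist_plain))
  # matched variant still never joins experiment nodes
  d <- design_causeis(g, seed = 1, match = TRUE)
  el <- igraph::as_edgelist(g, names = FALSE)
  in_exp <- d$arm != "EXCLUDED"
  expect_false(any(in_exp[el[, 1]] & in_exp[el[, 2]]))
})

test_that("bystander balance matches hand counts and centers on zero", {
  # C4: each excluded node touches one treated and one control edge
  c4 <- mk_graph(rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)), 4)
  d <- design_causeis(c4, seed = 5)
  expect_equal(bystander_balance(c4, d), 0)

  # star, center excluded, 2 treated + 1 control leaves: 100*(2-1)/3
  st <- star_graph(3)
  d2 <- tibble::tibble(
    node = 1:4, name = as.character(1:4),
    arm = c("EXCLUDED", "TREATED", "TREATED", "CONTROL")
  )
  expect_equal(bystander_balance(st, d2), 100 / 3)

  # no excluded nodes at all: identically zero
  d3 <- design_randomized(star_graph(3), seed = 1)
  expect_equal(bystander_balance(st, d3), 0)

  # randomization argument: mean over seeds within 3 standard errors of 0
  g <- generate_study_graph("ff", 300, seed = 13)
  bb <- vapply(1:200, function(s) {
    bystander_balance(g, design_causeis(g, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(bb)), 3 * stats::sd(bb) / sqrt(length(bb)))
})
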