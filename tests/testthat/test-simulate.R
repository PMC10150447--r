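test_that("base activation rates match the arm probabilities", {
  g <- igraph::make_empty_graph(20000, directed = FALSE)
  igraph::V(g)$name <- as.character(1:20000)
  d <- design_randomized(g, seed = 1)
  out <- simulate_outcomes(g, d, mode = "none", seed = 2)
  yt <- mean(out$y[d$arm == "TREATED"])
  yc <- mean(out$y[d$arm == "CONTROL"])
  expect_lt(abs(yt - 0.4), 4 * sqrt(0.4 * 0.6 / 10000))
  expect_lt(abs(yc - 0.2), 4 * sqrt(0.2 * 0.8 / 10000))
  expect_identical(simulate_outcomes(g, d, mode = "none", seed = 2), out)
})

test_that("direct interference with zero spillover is a no-op", {
  g <- generate_ff(300, seed = 4)
  d <- design_randomized(g, seed = 1)
  base <- simulate_outcomes(g, d, mode = "none", seed = 9)
  off <- simulate_outcomes(g, d, mode = "direct", ep = 0, seed = 9)
  expect_identical(off$y, base$y)
})

test_that("direct interference is forced at spillover probability one", {
  st <- star_graph(5)
  d <- tibble::tibble(
    node = 1:6, name = as.character(1:6),
    arm = c("TREATED", rep("CONTROL", 5))
  )
  out <- simulate_outcomes(st, d, mode = "direct", ep = 1, seed = 3)
  expect_true(all(out$y == 1)) # every control leaf has a treated neighbour
})

test_that("direct interference only flows from treated onto control nodes", {
  # control hub with treated leaves activates; treated nodes never receive
  st <- star_graph(4)
  d <- tibble::tibble(
    node = 1:5, name = as.character(1:5),
    arm = c("CONTROL", rep("TREATED", 4))
  )
  withr::with_seed(10, {
    for (r in 1:20) {
      out <- simulate_outcomes(st, d, mode = "direct", ep = 1,
                               p_treat = 0, p_control = 0)
      expect_equal(out$y, c(1, 0, 0, 0, 0))
    }
  })
})

test_that("multiple treated neighbours compound the activation probability", {
  # control hub with k treated neighbours: P(activate) = 1 - (1-p)^k
  st <- star_graph(3)
  d <- tibble::tibble(
    node = 1:4, name = as.character(1:4),
    arm = c("CONTROL", rep("TREATED", 3))
  )
  hits <- vapply(1:2000, function(s) {
    simulate_outcomes(st, d, mode = "direct", ep = 0.3, p_treat = 0, p_control = 0, seed = s)$y[1]
  }, numeric(1))
  p_expect <- 1 - 0.7^3
  expect_lt(abs(mean(hits) - p_expect), 4 * sqrt(p_expect * (1 - p_expect) / 2000))
})

test_that("contagion cascades across classes, is monotone, and respects bystanders", {
  # chain T - C - C: with e.p = 1 activation propagates down the chain
  p3 <- path_graph(3)
  d <- tibble::tibble(
    node = 1:3, name = as.character(1:3),
    arm = c("TREATED", "CONTROL", "TREATED")
  )
  out <- simulate_outcomes(p3, d, mode = "contagion", ep = 1, p_treat = 1, p_control = 0, seed = 1)
  expect_equal(out$y, c(1, 1, 1))

  # bystanders transmit their base activation but never receive spillover
  d2 <- tibble::tibble(
    node = 1:3, name = as.character(1:3),
    arm = c("TREATED", "EXCLUDED", "CONTROL")
  )
  # excluded node base-inactive (p_control = 0): nothing can reach the control
  out2 <- simulate_outcomes(p3, d2, mode = "contagion", ep = 1, p_treat = 1, p_control = 0, seed = 1)
  expect_equal(out2$y, c(1, 0, 0))
  # excluded node base-active: control neighbour catches it
  out3 <- simulate_outcomes(p3, d2, mode = "contagion", ep = 1, p_treat = 1, p_control = 1, seed = 1)
  expect_equal(out3$y[2], 1)

  # activation never reverts: y is monotone over increasing e.p rounds
  g <- generate_ff(200, seed = 8)
  d4 <- design_randomized(g, seed = 2)
  y_none <- simulate_outcomes(g, d4, mode = "none", seed = 5)$y
  y_cont <- simulate_outcomes(g, d4, mode = "contagion", ep = 0.5, seed = 5)$y
  expect_true(all(y_cont >= y_none))
})

test_that("each node draws at most one contagion trial", {
  # hub control node surrounded by active treated leaves, e.p = 0.4: the
  # hub's single combined trial succeeds with 1-(1-.4)^k, not with
  # repeated per-round retrials that would push it to 1
  st <- star_graph(4)
  d <- tibble::tibble(
    node = 1:5, name = as.character(1:5),
    arm = c("CONTROL", rep("TREATED", 4))
  )
  hits <- vapply(1:2000, function(s) {
    simulate_outcomes(st, d, mode = "contagion", ep = 0.4, p_treat = 1, p_control = 0, seed = s)$y[1]
  }, numeric(1))
  p_expect <- 1 - 0.6^4
  expect_lt(abs(mean(hits) - p_expect), 4 * sqrt(p_expect * (1 - p_expect) / 2000))
})

test_that("the difference-in-means estimator ignores excluded nodes", {
  d <- tibble::tibble(
    node = 1:9, name = as.character(1:9),
    arm = c(rep("TREATED", 4), rep("CONTROL", 4), "EXCLUDED")
  )
  out <- tibble::tibble(node = 1:9, name = d$name, y = c(1, 1, 0, 0, 1, 0, 0, 0, 1))
  expect_equal(effect_estimate(d, out), 0.5 - 0.25)
  out2 <- tibble::tibble(node = 1:9, name = d$name, y = c(rep(1, 4), rep(0, 4), 0))
  expect_equal(effect_estimate(d, out2), 1)
  d_empty <- d
  d_empty$arm[5:8] <- "EXCLUDED"
  expect_error(effect_estimate(d_empty, out), "non-empty")
})

test_that("interference requires spillover probabilities", {
  g <- generate_ff(50, seed = 2)
  d <- design_randomized(g, seed = 1)
  expect_error(simulate_outcomes(g, d, mode = "contagion"), "spillover")
  g2 <- add_edge_probabilities(g, "fixed", 0.2)
  expect_no_error(simulate_outcomes(g2, d, mode = "contagion", seed = 1))
})
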