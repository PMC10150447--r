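# Replicated design -> simulate -> estimate experiments, with tidy results.

design_methods <- c(
  "randomized", "match", "causeis", "causeis_match",
  "cr", "cbr", "cmatch_reldg", "cmatch_mcl"
)

make_design_fn <- function(design, design_args = list()) {
  if (is.function(design)) {
    return(function(g, seed) do.call(design, c(list(g, seed = seed), design_args)))
  }
  if (!design %in% design_methods) {
    abort(paste0(
      "unknown design `", design, "`; available: ",
      paste(design_methods, collapse = ", ")
    ))
  }
  function(g, seed) {
    args <- c(list(g, seed = seed), design_args)
    switch(design,
      randomized = do.call(design_randomized, args),
      match = do.call(design_match, args),
      causeis = do.call(design_causeis, args),
      causeis_match = do.call(design_causeis, c(args, list(match = TRUE))),
      cr = do.call(design_cbr, c(args, list(mode = "cr"))),
      cbr = do.call(design_cbr, c(args, list(mode = "cbr"))),
      cmatch_reldg = do.call(design_cmatch, c(args, list(cluster_algo = "reldg"))),
      cmatch_mcl = do.call(design_cmatch, c(args, list(cluster_algo = "mcl")))
    )
  }
}

#' Run a replicated design-and-simulate experiment
#'
#' Repeats, for `S` seeded runs: realize (or reuse) the graph, assign edge
#' spillover probabilities, construct the design, simulate outcomes, and
#' record the difference-in-means estimate together with the balance and
#' cut diagnostics. Per-run seeds are derived deterministically from
#' `base_seed` and the run index, stage by stage, so two designs evaluated
#' with the same `base_seed` see identical run-r graphs.
#'
#' @param graph An attributed igraph object reused across runs, or a
#'   generator `function(seed)` returning a fresh graph per run (e.g.
#'   `function(s) generate_study_graph("ff", 1000, seed = s)`).
#' @param design A design method name (`"randomized"`, `"match"`,
#'   `"causeis"`, `"causeis_match"`, `"cr"`, `"cbr"`, `"cmatch_reldg"`,
#'   `"cmatch_mcl"`) or a function `(graph, seed, ...)` returning a design
#'   tibble.
#' @param S Number of replicate runs (default 10).
#' @param base_seed Integer seed driving all stages.
#' @param p_treat,p_control Base activation probabilities; their difference
#'   is the true effect every estimate is compared against.
#' @param mode Interference mode, see [simulate_outcomes()].
#' @param ep Edge spillover probabilities: a number for a fixed value,
#'   `"edge_weight"` for attribute-similarity weights, or `NULL` to leave
#'   the graph's existing `p` (if any) untouched.
#' @param metric Similarity metric for `ep = "edge_weight"`.
#' @param design_args Extra arguments passed to the design function (e.g.
#'   `list(k = 20)` for the stratified cluster designs).
#' @param excluded_as_control Bystander behaviour, see
#'   [simulate_outcomes()].
#' @return A `netdesign_experiment` tibble with one row per run (`run`,
#'   `tau_hat`, `truth`, `covariate_distance`, `edge_fraction`,
#'   `weight_fraction`, `theta_hat`, `bystander_balance`, arm sizes);
#'   summarize with [glance()] or plot with [autoplot()].
#' @export
run_experiment <- function(graph, design = "causeis", S = 10, base_seed = 1,
                           p_treat = 0.4, p_control = 0.2,
                           mode = c("none", "direct", "contagion"),
                           ep = NULL, metric = "l2", design_args = list(),
                           excluded_as_control = TRUE) {
  mode <- match.arg(mode)
  stopifnot(S >= 1)
  design_fn <- make_design_fn(design, design_args)
  design_name <- if (is.function(design)) "custom" else design
  truth <- p_treat - p_control
  rows <- purrr::map(seq_len(S), function(r) {
    g <- if (is.function(graph)) graph(derive_seed(base_seed, r, "graph")) else graph
    assert_graph(g)
    if (!is.null(ep)) {
      g <- if (identical(ep, "edge_weight")) {
        add_edge_probabilities(g, "similarity", metric = metric)
      } else {
        add_edge_probabilities(g, "fixed", p = ep)
      }
    }
    d <- design_fn(g, derive_seed(base_seed, r, "design"))
    assert_design(d, g)
    out <- simulate_outcomes(g, d,
      p_treat = p_treat, p_control = p_control, mode = mode,
      excluded_as_control = excluded_as_control,
      seed = derive_seed(base_seed, r, "outcome")
    )
    X <- node_attr_matrix(g)
    cuts <- if (igraph::ecount(g) > 0) {
      cut_statistics(g, d)
    } else {
      tibble(edge_fraction = NA_real_, weight_fraction = NA_real_, theta_hat = NA_real_)
    }
    tibble(
      run = r,
      tau_hat = effect_estimate(d, out),
      truth = truth,
      covariate_distance = if (is.null(X)) NA_real_ else covariate_distance(d, X),
      edge_fraction = cuts$edge_fraction,
      weight_fraction = cuts$weight_fraction,
      theta_hat = cuts$theta_hat,
      bystander_balance = if (igraph::ecount(g) > 0) bystander_balance(g, d) else NA_real_,
      n_treated = sum(d$arm == "TREATED"),
      n_control = sum(d$arm == "CONTROL"),
      n_excluded = sum(d$arm == "EXCLUDED")
    )
  })
  res <- bind_rows(rows)
  class(res) <- c("netdesign_experiment", class(res))
  attr(res, "design") <- design_name
  attr(res, "mode") <- mode
  attr(res, "ep") <- if (is.null(ep)) NA else as.character(ep)
  attr(res, "base_seed") <- base_seed
  attr(res, "truth") <- truth
  res
}

#' @method tidy netdesign_experiment
#' @export
tidy.netdesign_experiment <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "netdesign_experiment")
  out
}

#' @method glance netdesign_experiment
#' @export
glance.netdesign_experiment <- function(x, ...) {
  tibble(
    design = attr(x, "design"),
    mode = attr(x, "mode"),
    ep = attr(x, "ep"),
    S = nrow(x),
    truth = attr(x, "truth"),
    rmse = rmse(x$tau_hat, x$truth),
    bias = mean(x$tau_hat - x$truth),
    mean_covariate_distance = mean(x$covariate_distance),
    mean_edge_fraction = mean(x$edge_fraction),
    mean_bystander_balance = mean(x$bystander_balance)
  )
}

#' @method autoplot netdesign_experiment
#' @export
autoplot.netdesign_experiment <- function(object, ...) {
  ggplot2::ggplot(
    tidy(object),
    ggplot2::aes(x = .data$run, y = .data$tau_hat)
  ) +
    ggplot2::geom_hline(
      yintercept = attr(object, "truth"),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "run", y = expression(hat(tau)),
      title = paste0(
        attr(object, "design"), " design (", attr(object, "mode"),
        " interference)"
      ),
      subtitle = sprintf(
        "RMSE = %.4f against true effect %.2f",
        rmse(object$tau_hat, object$truth), attr(object, "truth")
      )
    ) +
    ggplot2::theme_minimal()
}

#' All admissible cluster-matching option bundles
#'
#' Enumerates every valid combination of node-matching rule, cluster-weight
#' method, and cluster-graph rule (115 in total: best-node matching is
#' incompatible with the maximum-matching weight variants, and the
#' Euclidean weight uses no node matching).
#'
#' @return A tibble with columns `node_rule`, `alpha_q`, `weight_method`,
#'   `cluster_rule`, `beta_q`, and a human-readable `label`.
#' @export
cmatch_option_grid <- function() {
  node_opts <- tibble(
    node_rule = c(rep("tnm", 4), "bnm"),
    alpha_q = c(0:3, NA_integer_),
    node_label = c(paste0("TNM", 0:3), "BNM")
  )
  cluster_opts <- tibble(
    cluster_rule = c(rep("tcm", 4), "gcm"),
    beta_q = c(0:3, NA_integer_),
    cluster_label = c(paste0("TCM", 0:3), "GCM")
  )
  weights <- tibble(weight_method = c("c", "s", "mc", "ms", "mss", "e"))
  grid <- tidyr::crossing(node_opts, weights, cluster_opts)
  grid <- grid[!(grid$node_rule == "bnm" & grid$weight_method %in% c("mc", "ms", "mss")), ]
  grid <- grid[!(grid$weight_method == "e" & grid$node_label != "TNM0"), ]
  grid$node_label[grid$weight_method == "e"] <- NA_character_
  grid$node_rule[grid$weight_method == "e"] <- NA_character_
  grid$alpha_q[grid$weight_method == "e"] <- NA_integer_
  grid$label <- paste0(
    ifelse(is.na(grid$node_label), "", paste0(grid$node_label, "+")),
    toupper(grid$weight_method), "+", grid$cluster_label
  )
  grid[, c("node_rule", "alpha_q", "weight_method", "cluster_rule", "beta_q", "label")]
}
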