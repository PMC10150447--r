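# Ground-truth outcome engine. Stage 1 draws each node's base activation
# from its arm's probability; stage 2 adds interference: one-shot direct
# spillover from treated neighbours onto control nodes, or a contagion
# cascade in which activation spreads across treatment classes along edges
# with spillover probability e.p. The implied true total treatment effect
# is p_treat - p_control.

#' Simulate binary outcomes under a design
#'
#' Stage 1: every node activates independently with its arm's base
#' probability (`p_treat` for `TREATED`, `p_control` for `CONTROL`;
#' `EXCLUDED` bystanders behave like controls when
#' `excluded_as_control = TRUE`, otherwise they stay inactive and inert).
#'
#' Stage 2 (interference):
#' * `"none"` — no spillover; the difference in means is unbiased for
#'   `p_treat - p_control`.
#' * `"direct"` — every `TREATED` neighbour of an inactive `CONTROL` node
#'   contributes an independent activation trial with the edge's spillover
#'   probability, so a control node with treated neighbour edges
#'   `p_1..p_k` activates with probability `1 - prod(1 - p_k)`.
#' * `"contagion"` — an independent-cascade: when an inactive experiment
#'   node (either arm) first has at least one *activated* neighbour in a
#'   different treatment class, it draws a single activation trial with
#'   probability `1 - prod(1 - p_e)` over those neighbours' edges; newly
#'   activated nodes extend the frontier until no activation occurs.
#'   Activated bystanders transmit but never receive spillover. Activation
#'   is monotone.
#'
#' @param graph Undirected igraph object; edge attribute `p` is required
#'   for interference unless `ep` is given.
#' @param design Design tibble covering the graph.
#' @param p_treat,p_control Base activation probabilities (defaults 0.4 and
#'   0.2).
#' @param mode `"none"`, `"direct"`, or `"contagion"`.
#' @param ep Optional fixed spillover probability overriding the edge
#'   attribute.
#' @param excluded_as_control Bystanders draw control-level base
#'   activations and can transmit (default `TRUE`).
#' @param seed Optional integer seed.
#' @return An outcome tibble with columns `node`, `name`, `y` (0/1).
#' @export
simulate_outcomes <- function(graph, design, p_treat = 0.4, p_control = 0.2,
                              mode = c("none", "direct", "contagion"),
                              ep = NULL, excluded_as_control = TRUE, seed = NULL) {
  assert_graph(graph)
  assert_design(design, graph)
  mode <- match.arg(mode)
  stopifnot(p_treat >= 0, p_treat <= 1, p_control >= 0, p_control <= 1)
  n <- igraph::vcount(graph)
  arm <- design$arm[order(design$node)]
  base_p <- ifelse(arm == "TREATED", p_treat,
    ifelse(arm == "CONTROL", p_control,
      if (excluded_as_control) p_control else 0
    )
  )
  el <- NULL
  pvec <- NULL
  if (mode != "none") {
    el <- igraph::as_edgelist(graph, names = FALSE)
    pvec <- if (!is.null(ep)) {
      stopifnot(length(ep) == 1, ep >= 0, ep <= 1)
      rep(as.numeric(ep), nrow(el))
    } else {
      p <- igraph::edge_attr(graph, "p")
      if (is.null(p)) abort("interference needs edge spillover probabilities; set `ep` or add_edge_probabilities()")
      p
    }
  }
  with_seed_if(seed, {
    y <- runif(n) < base_p
    if (mode == "direct") {
      y <- spillover_direct(y, arm, el, pvec)
    } else if (mode == "contagion") {
      y <- spillover_contagion(y, arm, el, pvec, excluded_as_control)
    }
    tibble(node = seq_len(n), name = node_names(graph), y = as.integer(y))
  })
}

# one-shot: inactive CONTROL nodes draw independent trials from each
# TREATED neighbour (treated status, not treated outcome, spills over)
spillover_direct <- function(y, arm, el, pvec) {
  a1 <- arm[el[, 1]]
  a2 <- arm[el[, 2]]
  # orient edges treated -> control
  snd <- ifelse(a1 == "TREATED" & a2 == "CONTROL", el[, 1],
    ifelse(a2 == "TREATED" & a1 == "CONTROL", el[, 2], NA_integer_)
  )
  rcv <- ifelse(a1 == "TREATED" & a2 == "CONTROL", el[, 2],
    ifelse(a2 == "TREATED" & a1 == "CONTROL", el[, 1], NA_integer_)
  )
  keep <- !is.na(rcv) & !y[ifelse(is.na(rcv), 1L, rcv)]
  if (!any(keep)) return(y)
  logq <- tapply(log1p(-pvec[keep]), rcv[keep], sum)
  targets <- as.integer(names(logq))
  p_hit <- 1 - exp(as.numeric(logq))
  y[targets] <- y[targets] | (runif(length(targets)) < p_hit)
  y
}

# independent-cascade rounds; receivers are experiment nodes only, each
# gets exactly one trial upon first cross-class exposure
spillover_contagion <- function(y, arm, el, pvec, excluded_as_control) {
  n <- length(y)
  receiver <- arm %in% c("TREATED", "CONTROL")
  if (!excluded_as_control) {
    transmit_ok <- arm != "EXCLUDED"
  } else {
    transmit_ok <- rep(TRUE, n)
  }
  tried <- logical(n)
  # both orientations of each edge; class comparison uses the arm label, so
  # bystanders count as a distinct class from either arm
  src <- c(el[, 1], el[, 2])
  dst <- c(el[, 2], el[, 1])
  pe <- c(pvec, pvec)
  cross <- arm[src] != arm[dst]
  keep <- cross & receiver[dst] & transmit_ok[src]
  src <- src[keep]
  dst <- dst[keep]
  pe <- pe[keep]
  repeat {
    elig_edge <- y[src] & !y[dst] & !tried[dst]
    if (!any(elig_edge)) break
    logq <- tapply(log1p(-pe[elig_edge]), dst[elig_edge], sum)
    targets <- as.integer(names(logq))
    p_hit <- 1 - exp(as.numeric(logq))
    hit <- runif(length(targets)) < p_hit
    tried[targets] <- TRUE
    if (!any(hit)) break
    y[targets[hit]] <- TRUE
  }
  y
}

#' Difference-in-means effect estimate
#'
#' Mean outcome of treated nodes minus mean outcome of control nodes;
#' `EXCLUDED` nodes never enter the estimate.
#'
#' @param design Design tibble.
#' @param outcome Outcome tibble from [simulate_outcomes()].
#' @return The estimated treatment effect (scalar).
#' @export
effect_estimate <- function(design, outcome) {
  assert_design(design)
  d <- left_join(design, outcome[, c("node", "y")], by = "node")
  yt <- d$y[d$arm == "TREATED"]
  yc <- d$y[d$arm == "CONTROL"]
  if (length(yt) == 0 || length(yc) == 0) abort("both arms must be non-empty")
  mean(yt) - mean(yc)
}
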