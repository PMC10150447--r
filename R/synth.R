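# Synthetic graph and attribute generators used for simulation studies:
# preferential attachment (Barabasi-Albert) and forest-fire growth, with
# i.i.d. uniform node covariates generated independently of structure.

#' Generate a Barabási–Albert preferential-attachment graph
#'
#' Growth starts from a complete seed graph on `m` nodes; each arriving node
#' attaches to `m` distinct existing nodes with probability proportional to
#' their current degree. Under this seed convention the edge count is exactly
#' `choose(m, 2) + m * (n - m)`.
#'
#' @param n Number of nodes (`n > m`).
#' @param m Edges added per arriving node (default 3).
#' @param seed Optional integer seed for reproducible generation.
#' @return An undirected, connected, simple igraph object with vertex names
#'   `"1" .. "n"`.
#' @export
generate_ba <- function(n, m = 3, seed = NULL) {
  stopifnot(n >= 1, m >= 1)
  if (n <= m) abort("`n` must exceed the attachment count `m`")
  g <- with_seed_if(seed, igraph::sample_pa(
    n,
    m = m, directed = FALSE,
    start.graph = igraph::make_full_graph(m),
    algorithm = "psumtree"
  ))
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

#' Generate a forest-fire graph
#'
#' Each arriving node picks a uniform ambassador, links to it, and then
#' recursively "burns" through the ambassador's neighbourhood: the number of
#' links followed from each burned node is geometric with mean
#' `p_f / (1 - p_f)` (and `p_b / (1 - p_b)` along reverse links during
#' growth). The graph is treated as undirected.
#'
#' @param n Number of nodes.
#' @param p_f Forward burning probability (default 0.3).
#' @param p_b Backward burning probability (default 0.3).
#' @param seed Optional integer seed.
#' @return An undirected, connected, simple igraph object.
#' @export
generate_ff <- function(n, p_f = 0.3, p_b = 0.3, seed = NULL) {
  stopifnot(n >= 1, p_f >= 0, p_f < 1, p_b >= 0, p_b < 1)
  g <- with_seed_if(seed, {
    bw <- if (p_f > 0) p_b / p_f else 0
    igraph::sample_forestfire(n, fw.prob = p_f, bw.factor = bw, directed = FALSE)
  })
  g <- igraph::simplify(g)
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

#' Attach i.i.d. uniform node attributes
#'
#' Draws an `n x d` matrix of independent Uniform(`attr_range`) covariates
#' and attaches it to the graph. Attributes are generated independently of
#' the graph structure (no homophily).
#'
#' @param graph Undirected igraph object.
#' @param d Attribute dimension (default 10).
#' @param attr_range Lower and upper bound of the uniform distribution
#'   (default `c(-1, 1)`).
#' @param seed Optional integer seed.
#' @return The graph with attributes attached (see [node_attr_matrix()]).
#' @export
add_uniform_attributes <- function(graph, d = 10, attr_range = c(-1, 1), seed = NULL) {
  assert_graph(graph)
  stopifnot(d >= 1, length(attr_range) == 2, attr_range[1] < attr_range[2])
  n <- igraph::vcount(graph)
  X <- with_seed_if(seed, matrix(runif(n * d, attr_range[1], attr_range[2]), nrow = n))
  node_attr_matrix(graph) <- X
  igraph::graph_attr(graph, "attr_range") <- attr_range
  graph
}

#' Generate a fully attributed synthetic study graph
#'
#' Convenience wrapper producing the default simulation-study conditions:
#' a BA (`m = 3`) or forest-fire (`p_f = p_b = 0.3`) graph with 10
#' Uniform(-1, 1) attributes per node.
#'
#' @param model `"ba"` or `"ff"`.
#' @inheritParams generate_ba
#' @inheritParams generate_ff
#' @inheritParams add_uniform_attributes
#' @export
generate_study_graph <- function(model = c("ff", "ba"), n, m = 3, p_f = 0.3,
                                 p_b = 0.3, d = 10, attr_range = c(-1, 1),
                                 seed = NULL) {
  model <- match.arg(model)
  with_seed_if(seed, {
    g <- switch(model,
      ba = generate_ba(n, m = m),
      ff = generate_ff(n, p_f = p_f, p_b = p_b)
    )
    add_uniform_attributes(g, d = d, attr_range = attr_range)
  })
}
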