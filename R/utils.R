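# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed when `seed` is given, otherwise use
# the session RNG stream as-is.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Deterministic per-stage seed derivation: every stochastic stage of a
# replicated experiment draws its seed from (base_seed, run, stage) so stages
# are independently reproducible and two designs see the same run-r graph.
derive_seed <- function(base_seed, run, stage) {
  stopifnot(is.numeric(base_seed), length(base_seed) == 1)
  stage_id <- switch(stage,
    graph = 1L, weights = 2L, clustering = 3L, design = 4L, outcome = 5L,
    abort(paste0("unknown seed stage: ", stage))
  )
  as.integer((abs(base_seed) %% 1000003L) * 2011L + run * 131L + stage_id) %% 2147483629L
}

assert_graph <- function(graph, arg = "graph") {
  if (!igraph::is_igraph(graph)) {
    abort(paste0("`", arg, "` must be an igraph object"))
  }
  if (igraph::is_directed(graph)) {
    abort(paste0("`", arg, "` must be undirected"))
  }
  invisible(graph)
}

#' Node attribute matrix of a graph
#'
#' Attributed graphs carry their node covariates as a numeric matrix with one
#' row per node (graph attribute `"X"`), in vertex order.
#'
#' @param graph An undirected igraph object.
#' @return A numeric matrix with `vcount(graph)` rows, or `NULL` when the
#'   graph has no attributes attached.
#' @export
node_attr_matrix <- function(graph) {
  assert_graph(graph)
  X <- igraph::graph_attr(graph, "X")
  if (is.null(X)) return(NULL)
  X
}

#' @rdname node_attr_matrix
#' @param X Numeric matrix, one row per node, columns are covariates.
#' @export
`node_attr_matrix<-` <- function(graph, value) {
  assert_graph(graph)
  if (!is.null(value)) {
    value <- as.matrix(value)
    if (!is.numeric(value)) abort("node attributes must be numeric")
    if (nrow(value) != igraph::vcount(graph)) {
      abort(sprintf(
        "attribute matrix has %d rows but the graph has %d nodes",
        nrow(value), igraph::vcount(graph)
      ))
    }
    if (anyNA(value)) abort("node attributes must not contain NA")
  }
  igraph::graph_attr(graph, "X") <- value
  graph
}

require_attrs <- function(graph, what = "this operation") {
  X <- node_attr_matrix(graph)
  if (is.null(X)) abort(paste0(what, " requires node attributes; see add_uniform_attributes() or set_node_attributes()"))
  X
}

node_names <- function(graph) {
  nm <- igraph::vertex_attr(graph, "name")
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(graph)))
  nm
}

# integer adjacency list (1-based), much faster to index than igraph.vs
adjacency_int <- function(graph) {
  lapply(igraph::as_adj_list(graph, mode = "all"), as.integer)
}

assert_design <- function(design, graph = NULL) {
  if (!is.data.frame(design) || !all(c("node", "arm") %in% names(design))) {
    abort("a design is a data frame with columns `node` and `arm`")
  }
  bad <- setdiff(unique(design$arm), ARM_LEVELS)
  if (length(bad) > 0) {
    abort(paste0("invalid arm label(s): ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(design$node)) abort("design assigns some node more than once")
  if (!is.null(graph)) {
    n <- igraph::vcount(graph)
    if (nrow(design) != n || !setequal(design$node, seq_len(n))) {
      abort("design must cover every graph node exactly once")
    }
  }
  invisible(design)
}

new_design <- function(graph, arm) {
  stopifnot(length(arm) == igraph::vcount(graph))
  tibble(node = seq_along(arm), name = node_names(graph), arm = arm)
}

arm_nodes <- function(design, arm) design$node[design$arm == arm]
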