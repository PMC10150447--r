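# Readers and writers for the plain-text interchange formats: edge lists
# ("u v [p]" per line), node attribute tables, design and clustering tables.
# Node ids in files are arbitrary labels; internally nodes are contiguous
# 1..n with the original label kept as the vertex `name`.

split_fields <- function(lines) {
  strsplit(trimws(lines), "[,\t ]+")
}

#' Read an undirected graph from an edge-list file
#'
#' Each non-comment line holds two node ids and, if `weighted`, a spillover
#' probability in `[0, 1]`. Reversed duplicate edges are collapsed to one
#' (keeping the first weight seen); comment lines start with `#`. Fields may
#' be separated by whitespace or commas.
#'
#' @param path Path to the edge-list file.
#' @param weighted Logical; when `TRUE` a third column with edge spillover
#'   probabilities is expected and stored as edge attribute `p`.
#' @return An undirected igraph object whose vertex `name`s are the original
#'   node ids (sorted numerically when all ids are numeric).
#' @seealso [write_edge_list()], [filter_min_degree()]
#' @export
read_edge_list <- function(path, weighted = FALSE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) abort("edge list contains no edges")
  fields <- split_fields(lines[keep])
  want <- if (weighted) 3L else 2L
  nf <- lengths(fields)
  if (any(nf != want)) {
    bad <- keep[which(nf != want)[1]]
    abort(sprintf("line %d: expected %d fields, found %d", bad, want, nf[which(nf != want)[1]]))
  }
  u <- vapply(fields, `[[`, "", 1L)
  v <- vapply(fields, `[[`, "", 2L)
  if (any(u == v)) {
    bad <- keep[which(u == v)[1]]
    abort(sprintf("line %d: self-loop on node %s", bad, u[u == v][1]))
  }
  p <- NULL
  if (weighted) {
    p <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    if (anyNA(p)) {
      bad <- keep[which(is.na(p))[1]]
      abort(sprintf("line %d: non-numeric edge weight", bad))
    }
    if (any(p < 0 | p > 1)) {
      bad <- keep[which(p < 0 | p > 1)[1]]
      abort(sprintf("line %d: edge probability outside [0, 1]", bad))
    }
  }
  ids <- unique(c(u, v))
  num <- suppressWarnings(as.numeric(ids))
  ids <- if (anyNA(num)) sort(ids) else ids[order(num)]
  el <- cbind(match(u, ids), match(v, ids))
  graph <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::V(graph)$name <- ids
  if (weighted) igraph::E(graph)$p <- p
  graph <- igraph::simplify(graph,
    remove.multiple = TRUE, remove.loops = TRUE,
    edge.attr.comb = list(p = "first")
  )
  graph
}

#' Write a graph to an edge-list file
#'
#' @param graph Undirected igraph object.
#' @param path Output path.
#' @param weighted Write the `p` edge attribute as a third column.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path, weighted = FALSE) {
  assert_graph(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  nm <- node_names(graph)
  lines <- paste(nm[el[, 1]], nm[el[, 2]])
  if (weighted) {
    p <- igraph::edge_attr(graph, "p")
    if (is.null(p)) abort("graph has no edge probabilities to write")
    lines <- paste(lines, format(p, digits = 15, trim = TRUE, scientific = FALSE))
  }
  writeLines(lines, path)
  invisible(path)
}

detect_delim <- function(line) {
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else ""
}

#' Read a node attribute table
#'
#' Expects a header row with a node-id column (first column, conventionally
#' `node_id`) followed by numeric covariate columns. The delimiter is
#' auto-detected among tab, comma, and whitespace.
#'
#' @param path Path to the delimited table.
#' @return A data frame whose first column holds node ids as character.
#' @export
read_node_attributes <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  first <- readLines(path, n = 1)
  tab <- utils::read.table(path,
    header = TRUE, sep = detect_delim(first),
    comment.char = "#", stringsAsFactors = FALSE, check.names = FALSE
  )
  if (ncol(tab) < 2) abort("attribute table needs a node-id column and at least one covariate")
  tab[[1]] <- as.character(tab[[1]])
  tab
}

#' Attach a node attribute table to a graph
#'
#' Rows are matched to graph nodes by id; every graph node must appear
#' exactly once and every covariate cell must be numeric.
#'
#' @param graph Undirected igraph object.
#' @param attrs Data frame from [read_node_attributes()] (or equivalent):
#'   first column node id, remaining columns numeric covariates.
#' @return The graph with the covariate matrix attached
#'   (see [node_attr_matrix()]).
#' @export
set_node_attributes <- function(graph, attrs) {
  assert_graph(graph)
  ids <- as.character(attrs[[1]])
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate attribute row for node ", ids[duplicated(ids)][1]))
  }
  vals <- attrs[, -1, drop = FALSE]
  num <- vapply(vals, is.numeric, logical(1))
  if (!all(num)) abort(paste0("non-numeric attribute column: ", names(vals)[!num][1]))
  nm <- node_names(graph)
  unknown <- setdiff(ids, nm)
  if (length(unknown) > 0) {
    abort(paste0("attribute table id not in graph: ", unknown[1]))
  }
  idx <- match(nm, ids)
  if (anyNA(idx)) {
    abort(paste0("attribute table is missing node ", nm[is.na(idx)][1]))
  }
  X <- as.matrix(vals)[idx, , drop = FALSE]
  dimnames(X) <- NULL
  node_attr_matrix(graph) <- X
  graph
}

#' @rdname set_node_attributes
#' @param path Path to the attribute table file.
#' @export
read_attributes_into <- function(graph, path) {
  set_node_attributes(graph, read_node_attributes(path))
}

#' Write the node attribute matrix of a graph
#'
#' @inheritParams write_edge_list
#' @export
write_node_attributes <- function(graph, path) {
  X <- require_attrs(graph, "write_node_attributes()")
  d <- ncol(X)
  tab <- data.frame(node_id = node_names(graph), X)
  names(tab) <- c("node_id", paste0("f", seq_len(d)))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Drop low-degree nodes
#'
#' Removes, in a single pass, every node whose degree is below `dmin`
#' together with its incident edges, then re-indexes the remaining nodes.
#' The pass is deliberately not iterated to a k-core: nodes whose degree
#' drops below `dmin` only because a neighbour was removed are kept.
#'
#' @param graph Undirected igraph object (node attributes, if present, are
#'   subset along with the nodes).
#' @param dmin Minimum degree to keep; `dmin = 0` returns the graph
#'   unchanged, `dmin = 2` removes singletons and degree-1 nodes.
#' @return The filtered graph.
#' @export
filter_min_degree <- function(graph, dmin) {
  assert_graph(graph)
  stopifnot(length(dmin) == 1, dmin >= 0)
  keep <- which(igraph::degree(graph) >= dmin)
  X <- node_attr_matrix(graph)
  out <- igraph::induced_subgraph(graph, keep)
  if (!is.null(X)) node_attr_matrix(out) <- X[keep, , drop = FALSE]
  out
}

#' Read and write treatment designs and clusterings
#'
#' Designs are stored as `node_id,arm` with arm in
#' `TREATED`/`CONTROL`/`EXCLUDED`; clusterings as `node_id,cluster`.
#'
#' @param design A design tibble (columns `node`, `name`, `arm`).
#' @param path File path.
#' @param graph Graph the file refers to (used to map ids back to indices).
#' @return `read_design()` / `read_clustering()` return tibbles aligned to
#'   the graph's vertex order.
#' @name design_io
NULL

#' @rdname design_io
#' @export
write_design <- function(design, path) {
  assert_design(design)
  utils::write.csv(
    data.frame(node_id = design$name, arm = design$arm),
    path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname design_io
#' @export
read_design <- function(path, graph) {
  assert_graph(graph)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- node_names(graph)
  idx <- match(nm, as.character(tab[[1]]))
  if (anyNA(idx)) abort(paste0("design file is missing node ", nm[is.na(idx)][1]))
  design <- tibble(node = seq_along(nm), name = nm, arm = tab[[2]][idx])
  assert_design(design, graph)
  design
}

#' @rdname design_io
#' @param clustering A clustering tibble (columns `node`, `name`, `cluster`).
#' @export
write_clustering <- function(clustering, path) {
  utils::write.csv(
    data.frame(node_id = clustering$name, cluster = clustering$cluster),
    path,
    row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname design_io
#' @export
read_clustering <- function(path, graph) {
  assert_graph(graph)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- node_names(graph)
  idx <- match(nm, as.character(tab[[1]]))
  if (anyNA(idx)) abort(paste0("clustering file is missing node ", nm[is.na(idx)][1]))
  lab <- as.integer(tab[[2]][idx])
  tibble(node = seq_along(nm), name = nm, cluster = match(lab, sort(unique(lab))))
}
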