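# Independent-set experiment design for direct treatment effects: treatment
# and control are assigned only to a maximal independent set, so no edge
# joins two experiment nodes and peer effects cannot cross arms. Remaining
# nodes are bystanders (EXCLUDED): outside the experiment, but still able to
# transmit influence into it.

#' Greedy maximal independent set
#'
#' Scans a seeded random permutation of the nodes, adding each node whose
#' neighbours have not already been added — O(|E|) and maximal by
#' construction. With `restarts > 1` the largest set over independent
#' permutations is returned, approximating a maximum independent set.
#'
#' @param graph Undirected igraph object (non-empty).
#' @param seed Optional integer seed.
#' @param restarts Number of random permutations to try (default 1).
#' @return An object of class `mis_result`: a list with integer vectors
#'   `members` and `bystanders`, and `restarts_used`.
#' @export
greedy_mis <- function(graph, seed = NULL, restarts = 1) {
  assert_graph(graph)
  n <- igraph::vcount(graph)
  if (n == 0) abort("graph has no nodes")
  stopifnot(restarts >= 1)
  adj <- adjacency_int(graph)
  with_seed_if(seed, {
    best <- integer(0)
    for (r in seq_len(restarts)) {
      perm <- sample.int(n)
      blocked <- logical(n)
      members <- logical(n)
      for (v in perm) {
        if (!blocked[v]) {
          members[v] <- TRUE
          blocked[adj[[v]]] <- TRUE
        }
      }
      mem <- which(members)
      if (length(mem) > length(best)) best <- mem
    }
    structure(
      list(
        members = best,
        bystanders = setdiff(seq_len(n), best),
        restarts_used = as.integer(restarts)
      ),
      class = "mis_result"
    )
  })
}

#' @export
print.mis_result <- function(x, ...) {
  cat(
    "Maximal independent set:", length(x$members), "members,",
    length(x$bystanders), "bystanders (", x$restarts_used, "restart(s))\n"
  )
  invisible(x)
}

#' Independent-set experiment design
#'
#' Finds a greedy maximal independent set and randomizes its members into
#' treatment and control; everything outside the set becomes a bystander
#' (`EXCLUDED`). By construction no edge joins two experiment nodes, so the
#' difference in means over this design estimates the direct treatment
#' effect free of cross-arm peer effects.
#'
#' With `match = TRUE`, independent-set members are first paired by exact
#' maximum-weight matching on attribute similarity and each pair is split
#' across arms (the matched variant trades a little randomization for
#' covariate balance in small graphs); any unmatched member is assigned by
#' coin flip.
#'
#' @param graph Undirected igraph object (attributes required when
#'   `match = TRUE`).
#' @param seed Optional integer seed.
#' @param match Pair members on attribute similarity before splitting.
#' @param restarts Restarts for [greedy_mis()].
#' @param metric Similarity metric for the matched variant.
#' @return A design tibble with columns `node`, `name`, `arm`.
#' @export
design_causeis <- function(graph, seed = NULL, match = FALSE, restarts = 1,
                           metric = "l2") {
  assert_graph(graph)
  n <- igraph::vcount(graph)
  with_seed_if(seed, {
    mis <- greedy_mis(graph, restarts = restarts)
    mem <- mis$members
    if (length(mem) < 2) abort("independent set has fewer than 2 nodes; no experiment possible")
    arm <- rep("EXCLUDED", n)
    if (match) {
      X <- require_attrs(graph, "design_causeis(match = TRUE)")
      rng <- igraph::graph_attr(graph, "attr_range")
      sm <- similarity_matching(X, mem, metric = metric, attr_range = rng)
      for (r in seq_len(nrow(sm$pairs))) {
        fl <- sample(c("TREATED", "CONTROL"))
        arm[sm$pairs[r, 1]] <- fl[1]
        arm[sm$pairs[r, 2]] <- fl[2]
      }
      if (length(sm$unmatched) > 0) {
        arm[sm$unmatched] <- sample(c("TREATED", "CONTROL"), length(sm$unmatched), replace = TRUE)
      }
    } else {
      k <- length(mem)
      nt <- floor(k / 2) + if (k %% 2 == 1) rbinom(1, 1, 0.5) else 0
      shuffled <- sample(mem)
      arm[shuffled[seq_len(nt)]] <- "TREATED"
      arm[shuffled[(nt + 1):k]] <- "CONTROL"
    }
    new_design(graph, arm)
  })
}

#' Bystander balance diagnostic
#'
#' Signed percentage measuring how evenly bystander edges split between the
#' arms: `100 / |E| * (#edges TREATED-EXCLUDED - #edges CONTROL-EXCLUDED)`.
#' Values near zero indicate that influence flowing in from bystanders
#' cancels between treatment and control in expectation.
#'
#' @param graph Undirected igraph object.
#' @param design A design tibble covering the graph.
#' @return A signed percentage (0 when there are no bystanders).
#' @export
bystander_balance <- function(graph, design) {
  assert_graph(graph)
  assert_design(design, graph)
  m <- igraph::ecount(graph)
  if (m == 0) abort("graph has no edges")
  el <- igraph::as_edgelist(graph, names = FALSE)
  arm <- design$arm[order(design$node)]
  a1 <- arm[el[, 1]]
  a2 <- arm[el[, 2]]
  te <- sum((a1 == "TREATED" & a2 == "EXCLUDED") | (a1 == "EXCLUDED" & a2 == "TREATED"))
  ce <- sum((a1 == "CONTROL" & a2 == "EXCLUDED") | (a1 == "EXCLUDED" & a2 == "CONTROL"))
  100 * (te - ce) / m
}
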