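# Shared asynchronous sweep kernel for the three engines.
#
# Labels live as integer vertex indices (each node starts with its own
# index, i.e. labels are unique at t = 0, and the vertex order is the
# canonical node order, so "smallest label" = smallest vertex index =
# smallest node id). A sweep visits nodes in the given order; each node
# immediately adopts the plurality label of its neighbors (weighted by w_ij
# on weighted graphs), so updates within a sweep see earlier updates
# (asynchronous updating, which prevents bipartite label oscillation).
# Ties among the maximal labels (the set l_max) are resolved by `tie`:
#   random — uniform draw from l_max (classic LPA / KBLPA behavior);
#   li     — label-influence argmax, residual exact ties to the smallest
#            label id (deterministic).
# Stops when a full sweep changes no label, or after max_iter sweeps.
# `iterations` counts the sweeps that changed at least one label; the final
# zero-change sweep only confirms the fixed point.
lp_engine <- function(graph, order_type, tie, fixed_order = NULL,
                      influence = NULL, max_iter = 100L, seed = NULL) {
  stopifnot(max_iter >= 1L)
  n <- igraph::vcount(graph)
  al <- adjacency_lists(graph)
  adj <- al$adj
  wadj <- al$w
  weighted <- is_weighted_graph(graph)
  count_tol <- if (weighted) 1e-9 else 0

  li_contrib <- NULL
  if (tie == "li") {
    deg <- lengths(adj)
    li_contrib <- ifelse(deg > 0, as.numeric(influence) / deg, 0)
  }
  if (!is.null(seed)) set.seed(seed)

  labels <- seq_len(n)
  iterations <- 0L
  converged <- FALSE
  for (sweep in seq_len(max_iter)) {
    ord <- if (order_type == "random") sample.int(n) else fixed_order
    changed <- 0L
    for (v in ord) {
      nb <- adj[[v]]
      if (!length(nb)) next
      labs <- labels[nb]
      tab <- vapply(split(wadj[[v]], labs), sum, numeric(1))
      lmax <- as.integer(names(tab)[tab >= max(tab) - count_tol])
      new_lab <- if (length(lmax) == 1L) {
        lmax
      } else if (tie == "random") {
        lmax[sample.int(length(lmax), 1L)]
      } else {
        # lmax is ascending, so the first maximal entry is the smallest label
        li <- vapply(lmax, function(l) sum(li_contrib[nb[labs == l]]),
                     numeric(1))
        li <- round(li / INFLUENCE_TOL)
        lmax[which.max(li)]
      }
      if (new_lab != labels[v]) {
        labels[v] <- new_lab
        changed <- changed + 1L
      }
    }
    if (changed == 0L) {
      converged <- TRUE
      break
    }
    iterations <- iterations + 1L
  }
  list(labels = labels, iterations = iterations, converged = converged)
}

lp_result <- function(graph, eng, algorithm, seed = NULL, alpha = NULL) {
  nodes <- graph_nodes(graph)
  if (!eng$converged) {
    warning(algorithm, " did not converge within the sweep cap ",
            "(partition returned as-is)", call. = FALSE)
  }
  structure(
    list(partition = canonicalize(setNames(nodes[eng$labels], nodes), graph),
         iterations = eng$iterations,
         converged = eng$converged,
         algorithm = algorithm,
         seed = seed,
         alpha = alpha),
    class = "lp_result"
  )
}

#' @export
print.lp_result <- function(x, ...) {
  cat(toupper(x$algorithm), "run:",
      n_communities(x$partition), "communities after",
      x$iterations, "changing sweep(s);",
      if (x$converged) "converged" else "NOT converged", "\n")
  if (!is.null(x$alpha)) cat("alpha:", x$alpha, "\n")
  if (!is.null(x$seed)) cat("seed:", x$seed, "\n")
  invisible(x)
}

#' Per-label neighbor support of a node
#'
#' For an unweighted graph, the number of neighbors of `node` holding each
#' label; for a weighted graph, the sum of the incident edge weights `w_ij`
#' per label. This is the quantity whose argmax drives every label update;
#' the node's own label counts only through neighbors that hold it.
#'
#' @param graph An undirected `igraph` graph.
#' @param labeling Named vector of current labels covering the graph's nodes.
#' @param node A node id.
#' @return Named numeric vector label -> support; empty for isolated nodes.
#' @export
neighbor_label_counts <- function(graph, labeling, node) {
  nodes <- graph_nodes(graph)
  if (!node %in% nodes) stop("unknown node: ", node, call. = FALSE)
  v <- match(node, nodes)
  al <- adjacency_lists(graph)
  nb <- al$adj[[v]]
  if (!length(nb)) return(setNames(numeric(0), character(0)))
  labs <- as.character(labeling[nodes[nb]])
  vapply(split(al$w[[v]], labs), sum, numeric(1))
}

#' Classic label propagation (LPA)
#'
#' Every node starts with a unique label. Each sweep visits the nodes in a
#' fresh uniform-random order (re-shuffled every sweep) and each node
#' asynchronously adopts the label carried by the largest number of its
#' neighbors (largest total edge weight on weighted graphs); ties are broken
#' uniformly at random. Converged label groups become communities. Results
#' are reproducible given `seed` but vary across seeds — the instability the
#' influence-ordered variant removes.
#'
#' @param graph An undirected `igraph` graph.
#' @param seed Integer RNG seed (or `NULL` to use the current RNG state).
#' @param max_iter Cap on the number of sweeps. Default 100.
#' @return An `lp_result`: list with `partition` (canonical [as_partition()]
#'   object), `iterations` (sweeps that changed a label), `converged`,
#'   `algorithm`, `seed`, `alpha`.
#' @export
#' @examples
#' g <- clique_ring(5, 2)$graph
#' run_lpa(g, seed = 1)
run_lpa <- function(graph, seed = NULL, max_iter = 100L) {
  eng <- lp_engine(graph, order_type = "random", tie = "random",
                   max_iter = max_iter, seed = seed)
  lp_result(graph, eng, "lpa", seed = seed)
}

#' k-shell-ordered label propagation (KBLPA)
#'
#' As [run_lpa()], but the visiting order is fixed for all sweeps: nodes in
#' descending k-shell index, ties by ascending node id. Label ties are still
#' broken uniformly at random (seeded), so results remain stochastic.
#'
#' @inheritParams run_lpa
#' @return An `lp_result`; see [run_lpa()].
#' @export
run_kblpa <- function(graph, seed = NULL, max_iter = 100L) {
  ks <- kshell_decompose(graph)
  ord <- order(-as.integer(ks), seq_along(ks), method = "radix")
  eng <- lp_engine(graph, order_type = "fixed", tie = "random",
                   fixed_order = ord, max_iter = max_iter, seed = seed)
  lp_result(graph, eng, "kblpa", seed = seed)
}

#' Node-influence-based label propagation (NIBLPA)
#'
#' Deterministic label propagation: (1) compute the k-shell decomposition,
#' node-influence scores `NI` (see [node_influence()]) and the fixed update
#' order they induce (influence descending, ties by node id); (2) give every
#' node a unique label; (3) sweep the fixed order asynchronously — each node
#' adopts the plurality label of its neighbors, and when several labels tie
#' for the maximal count (the set `l_max`) the one with the largest label
#' influence `LI` wins (see [label_influence()]), residual exact `LI` ties
#' going to the smallest label id; (4) stop when a sweep changes nothing.
#' No randomness anywhere: repeated runs give identical partitions.
#'
#' On weighted graphs the weights enter only the neighbor-support counts;
#' shells, `NI` and `LI` use the unweighted structure (a note is emitted).
#'
#' @param graph An undirected `igraph` graph.
#' @param alpha Neighborhood weight of the influence score, in `[0, 1]`.
#'   Default 1.
#' @param max_iter Cap on the number of sweeps. Default 100.
#' @return An `lp_result`; see [run_lpa()].
#' @export
#' @examples
#' cr <- clique_ring(5, 5)
#' res <- run_niblpa(cr$graph)
#' nmi(res$partition, cr$truth)
run_niblpa <- function(graph, alpha = 1, max_iter = 100L) {
  if (is_weighted_graph(graph)) {
    message("weighted graph: weights affect neighbor support only; ",
            "shells and influence use the unweighted structure")
  }
  ks <- kshell_decompose(graph)
  ni <- node_influence(graph, ks, alpha)
  ord <- order(-round(as.numeric(ni) / INFLUENCE_TOL), seq_along(ni),
               method = "radix")
  eng <- lp_engine(graph, order_type = "fixed", tie = "li",
                   fixed_order = ord, influence = ni, max_iter = max_iter)
  lp_result(graph, eng, "niblpa", alpha = alpha)
}
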