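#' k-shell decomposition
#'
#' Assigns every node its shell index `Ks(i)`: the largest `k` such that the
#' node survives in the k-core, the maximal subgraph of minimum degree `k`.
#' Computed by the standard iterative peeling — repeatedly delete all nodes
#' of remaining degree at most `k`, assign them shell `k`, increment `k` —
#' which is deterministic and independent of deletion order within a round.
#' Isolated nodes receive shell 0. Edge weights, if present, are ignored:
#' shells are a property of the unweighted structure.
#'
#' @param graph An undirected `igraph` graph (may be disconnected).
#' @return Named integer vector of shell indices, one entry per node, in the
#'   graph's canonical node order. The largest shell present is `max()` of
#'   the result.
#' @export
#' @examples
#' g <- graph_from_edges(c("a", "b", "c"), c("b", "c", "d"))
#' kshell_decompose(g)  # a path: every node in shell 1
kshell_decompose <- function(graph) {
  g <- graph
  if (is_weighted_graph(g)) g <- igraph::delete_edge_attr(g, "weight")
  ks <- igraph::coreness(g, mode = "all")
  setNames(as.integer(ks), graph_nodes(graph))
}
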