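# Resolution at which real-valued influence scores are considered tied.
# Node-influence sums over neighbors accumulate in adjacency order, so values
# that are equal in exact arithmetic can differ by a few ulp; comparing at
# 1e-10 makes such ties break deterministically by node id instead.
INFLUENCE_TOL <- 1e-10

#' Node influence
#'
#' The centrality that fixes the label-update order:
#' `NI(i) = Ks(i) + alpha * sum over neighbors j of Ks(j) / d(j)`,
#' blending a node's own k-shell index with the (degree-normalized) shell
#' indices of its neighbors. With `alpha = 0` it reduces to the k-shell
#' index; larger `alpha` weighs the neighborhood more. Isolated nodes have
#' an empty neighbor sum, so `NI = Ks = 0`. Shells and degrees are always
#' the unweighted ones.
#'
#' @param graph An undirected `igraph` graph.
#' @param shells Named integer vector of shell indices for exactly the
#'   graph's nodes; computed via [kshell_decompose()] when omitted.
#' @param alpha Neighborhood weight, normally in `[0, 1]` (values outside
#'   warn but proceed). Default 1.
#' @return Named numeric vector of influence scores in canonical node order,
#'   with the `alpha` used attached as an attribute.
#' @export
node_influence <- function(graph, shells = NULL, alpha = 1) {
  nodes <- graph_nodes(graph)
  if (is.null(shells)) {
    shells <- kshell_decompose(graph)
  } else if (!setequal(names(shells), nodes)) {
    stop("shell index does not match the graph's node set", call. = FALSE)
  }
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (alpha < 0 || alpha > 1) {
    warning("alpha = ", alpha, " is outside [0, 1]", call. = FALSE)
  }
  ks <- as.numeric(shells[nodes])
  deg <- igraph::degree(graph)
  contrib <- ifelse(deg > 0, ks / deg, 0)

  n <- length(nodes)
  al <- adjacency_lists(graph)
  nbr <- vapply(al$adj, function(js) sum(contrib[js]), numeric(1))
  ni <- setNames(ks + alpha * nbr, nodes)
  attr(ni, "alpha") <- alpha
  ni
}

#' Node update order induced by influence scores
#'
#' Sorts nodes by influence descending; exact (and numerically near-exact,
#' within 1e-10) ties break by ascending node id under the canonical order.
#' The result is the fixed visiting sequence used by the influence-ordered
#' propagation engines.
#'
#' @param influence Named numeric vector of node-influence scores
#'   (see [node_influence()]).
#' @return Character vector: a permutation of the node ids.
#' @export
update_order <- function(influence) {
  ids <- names(influence)
  if (is.null(ids)) stop("influence table must be named", call. = FALSE)
  key <- round(as.numeric(influence) / INFLUENCE_TOL)
  ids[order(-key, node_id_rank(ids), method = "radix")]
}

#' Label influence
#'
#' The tie-breaking score of a candidate label `l` at node `i`:
#' `LI(l) = sum over neighbors j of i currently holding l of NI(j) / d(j)`.
#' When several labels are held by the same maximal number of neighbors, the
#' propagation engine adopts the candidate with the largest label influence.
#' Returns 0 when no neighbor holds the label.
#'
#' @param graph An undirected `igraph` graph.
#' @param influence Named numeric node-influence vector over the graph's
#'   nodes (see [node_influence()]).
#' @param node A node id present in the graph.
#' @param label The candidate label value.
#' @param labeling Named vector of current labels covering the graph.
#' @return Non-negative numeric scalar.
#' @export
label_influence <- function(graph, influence, node, label, labeling) {
  nodes <- graph_nodes(graph)
  if (!node %in% nodes) stop("unknown node: ", node, call. = FALSE)
  nb <- igraph::neighbors(graph, node)$name
  hold <- nb[as.character(labeling[nb]) == as.character(label)]
  if (!length(hold)) return(0)
  deg <- igraph::degree(graph)
  sum(as.numeric(influence[hold]) / deg[hold])
}
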