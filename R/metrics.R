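# Contingency table between two partitions over an identical node set.
# Rows: communities of x; columns: communities of y; cells |X_i ∩ Y_j|.
partition_contingency <- function(x, y) {
  x <- as_partition(x)
  y <- as_partition(y)
  if (!setequal(names(x), names(y))) {
    stop("partitions cover different node sets", call. = FALSE)
  }
  nodes <- names(x)
  table(x = unclass(x), y = unclass(y)[match(nodes, names(y))])
}

#' Newman modularity of a partition
#'
#' `Q = (1/2m) * sum over node pairs (i, j) of
#' (A_ij - d_i d_j / 2m) * delta(c_i, c_j)`, where `A` is the 0/1 adjacency
#' matrix, `d_i` the degrees and `delta` the same-community indicator: the
#' fraction of edges inside communities minus its expectation under the
#' degree-preserving null model. Always evaluated on the unweighted
#' structure (weights, if present, are ignored with a warning).
#' `Q` lies in `[-1/2, 1)`; a single all-nodes community scores exactly 0.
#'
#' @param graph An undirected `igraph` graph with at least one edge.
#' @param partition A `partition` (or coercible labeling) over exactly the
#'   graph's nodes.
#' @return Numeric scalar `Q`.
#' @export
#' @examples
#' cr <- clique_ring(5, 5)
#' modularity_q(cr$graph, cr$truth)
modularity_q <- function(graph, partition) {
  m <- igraph::ecount(graph)
  if (m == 0L) stop("modularity is undefined on an edgeless graph",
                    call. = FALSE)
  if (is_weighted_graph(graph)) {
    warning("edge weights ignored: modularity uses the 0/1 adjacency",
            call. = FALSE)
  }
  p <- as_partition(partition)
  nodes <- graph_nodes(graph)
  if (!setequal(names(p), nodes)) {
    stop("partition does not cover exactly the graph's nodes", call. = FALSE)
  }
  comm <- unclass(p)[match(nodes, names(p))] + 1L
  k <- max(comm)
  ends <- igraph::ends(graph, igraph::E(graph), names = FALSE)
  same <- comm[ends[, 1]] == comm[ends[, 2]]
  inner <- tabulate(comm[ends[, 1]][same], nbins = k)   # edges inside c
  degsum <- vapply(split(igraph::degree(graph), comm), sum, numeric(1))
  sum(inner / m - (degsum / (2 * m))^2)
}

#' Pair-based F-measure between a detected and a reference partition
#'
#' Treats community detection as retrieval of unordered same-cluster node
#' pairs: with `S` the pairs co-clustered by `pred` and `T` those
#' co-clustered by `truth`, precision `= |S ∩ T| / |S|`, recall
#' `= |S ∩ T| / |T|`, and the F-measure is their harmonic mean.
#' Degenerate cases: precision is 0 when `S` is empty; when both `S` and
#' `T` are empty (two all-singleton partitions) the F-measure is 1.
#'
#' @param pred Detected `partition` (or coercible labeling).
#' @param truth Reference `partition` over the same node set.
#' @return Numeric in `[0, 1]`.
#' @export
f_measure <- function(pred, truth) {
  ct <- partition_contingency(pred, truth)
  st <- sum(choose(ct, 2))                    # |S ∩ T|
  s <- sum(choose(rowSums(ct), 2))            # |S|
  t_ <- sum(choose(colSums(ct), 2))           # |T|
  if (s == 0 && t_ == 0) return(1)
  precision <- if (s > 0) st / s else 0
  recall <- if (t_ > 0) st / t_ else 0
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Normalized mutual information between two partitions
#'
#' `NMI(X, Y) = -2 * sum_ij n_ij * log(n * n_ij / (|X_i| |Y_j|)) /
#' (sum_i |X_i| log(|X_i| / n) + sum_j |Y_j| log(|Y_j| / n))`
#' with `n_ij = |X_i ∩ Y_j|` and the convention `0 * log 0 = 0`; natural
#' logarithms (the ratio is base-invariant). Symmetric in its arguments and
#' equal to 1 exactly when the partitions coincide up to relabeling.
#' Degenerate cases: both partitions the single all-nodes community
#' (denominator 0) give 1 — they are identical; if exactly one is trivial
#' the numerator vanishes and the value is 0.
#'
#' @param x,y Two `partition`s (or coercible labelings) over the same node
#'   set.
#' @return Numeric in `[0, 1]`.
#' @export
nmi <- function(x, y) {
  ct <- partition_contingency(x, y)
  n <- sum(ct)
  rs <- rowSums(ct)
  cs <- colSums(ct)
  den <- sum(rs * log(rs / n)) + sum(cs * log(cs / n))
  if (den == 0) return(1)  # both trivial one-community partitions
  nz <- ct > 0
  num <- -2 * sum(ct[nz] * log(n * ct[nz] /
                                 (outer(rs, cs)[nz])))
  num / den
}
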