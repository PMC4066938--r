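#' Clique-Ring benchmark network
#'
#' `m_cliques` complete subgraphs \eqn{K_n} on disjoint node sets, closed
#' into a ring by single bridge edges: the last node of clique `q` is joined
#' to the first node of clique `q + 1` (wrapping around). The graph has
#' `N = m_cliques * n` nodes and `M = m_cliques * n * (n - 1) / 2 +
#' m_cliques` edges; the ground truth is the clique membership. Node ids are
#' `c{q}_{r}` with zero-padded clique index `q` and within-clique index `r`,
#' so lexicographic order equals construction order. Fully deterministic.
#'
#' @param n Clique size (at least 3).
#' @param m_cliques Number of cliques in the ring (at least 2).
#' @return List with `graph` (an `igraph`) and `truth` (the planted
#'   `partition`).
#' @export
#' @examples
#' cr <- clique_ring(5, 5)
#' igraph::vcount(cr$graph)  # 25
#' igraph::ecount(cr$graph)  # 55
clique_ring <- function(n, m_cliques) {
  if (!is.numeric(n) || n < 3) {
    stop("clique size n must be at least 3", call. = FALSE)
  }
  if (!is.numeric(m_cliques) || m_cliques < 2) {
    stop("need at least 2 cliques", call. = FALSE)
  }
  n <- as.integer(n)
  m_cliques <- as.integer(m_cliques)
  fmt <- paste0("c%0", nchar(m_cliques), "d_%0", nchar(n), "d")
  clique_nodes <- lapply(seq_len(m_cliques),
                         function(q) sprintf(fmt, q, seq_len(n)))
  within <- lapply(clique_nodes, function(v) combn(v, 2))
  from <- unlist(lapply(within, function(p) p[1, ]))
  to <- unlist(lapply(within, function(p) p[2, ]))
  # one bridge per adjacent clique pair: last node of q -> first of q+1
  nxt <- c(seq_len(m_cliques)[-1], 1L)
  from <- c(from, vapply(clique_nodes, function(v) v[n], ""))
  to <- c(to, vapply(seq_len(m_cliques),
                     function(q) clique_nodes[[nxt[q]]][1], ""))
  truth <- as_partition(setNames(rep(seq_len(m_cliques), each = n),
                                 unlist(clique_nodes)))
  list(graph = graph_from_edges(from, to), truth = truth)
}

#' Planted-partition random network
#'
#' A stochastic block model with equal mixing: nodes are split into
#' `k_communities` groups of near-equal size (differing by at most one);
#' every within-group pair is independently an edge with probability `p_in`
#' and every between-group pair with probability `p_out <= p_in`. Used as
#' the in-repo robustness benchmark with a tunable community contrast:
#' `p_in >> p_out` gives crisp modules, `p_in ~ p_out` an unstructured
#' graph. The same `seed` reproduces the identical graph.
#'
#' @param n_nodes Number of nodes (at least `k_communities`).
#' @param k_communities Number of planted groups.
#' @param p_in,p_out Within- and between-group edge probabilities, with
#'   `0 <= p_out <= p_in <= 1`.
#' @param seed Integer RNG seed (or `NULL` to use the current RNG state).
#' @return List with `graph` (isolated nodes retained) and `truth` (the
#'   planted `partition`).
#' @export
planted_partition <- function(n_nodes, k_communities, p_in, p_out,
                              seed = NULL) {
  if (!is.numeric(n_nodes) || n_nodes < 1 ||
      !is.numeric(k_communities) || k_communities < 1 ||
      n_nodes < k_communities) {
    stop("need n_nodes >= k_communities >= 1", call. = FALSE)
  }
  if (!is.numeric(p_in) || !is.numeric(p_out) ||
      p_out < 0 || p_in > 1 || p_out > p_in) {
    stop("need 0 <= p_out <= p_in <= 1", call. = FALSE)
  }
  n <- as.integer(n_nodes)
  k <- as.integer(k_communities)
  ids <- sprintf(paste0("n%0", nchar(n), "d"), seq_len(n))
  mem <- sort(rep_len(seq_len(k), n))
  if (!is.null(seed)) set.seed(seed)
  if (n >= 2) {
    pr <- combn(n, 2)
    p <- ifelse(mem[pr[1, ]] == mem[pr[2, ]], p_in, p_out)
    keep <- runif(ncol(pr)) < p
    g <- graph_from_edges(ids[pr[1, keep]], ids[pr[2, keep]], nodes = ids)
  } else {
    g <- graph_from_edges(character(0), character(0), nodes = ids)
  }
  list(graph = g, truth = as_partition(setNames(mem, ids)))
}
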