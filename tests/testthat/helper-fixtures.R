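# Shared fixtures and independent brute-force oracles.

# Two triangle modules {v1,v2,v3} and {v4,v5,v6} joined by bridges v1-v4 and
# v3-v6; degrees (3,2,3,3,2,3), all shell indices 2.
toy_graph <- function() {
  e <- rbind(c("v1", "v2"), c("v1", "v3"), c("v2", "v3"), c("v1", "v4"),
             c("v4", "v5"), c("v4", "v6"), c("v5", "v6"), c("v3", "v6"))
  graph_from_edges(e[, 1], e[, 2])
}

toy_truth <- function() {
  as_partition(c(v1 = 1, v2 = 1, v3 = 1, v4 = 2, v5 = 2, v6 = 2))
}

# Erdos-Renyi-style random graph over named nodes (isolates retained)
random_gnp <- function(n, p, seed) {
  planted_partition(n, 1, p, p, seed = seed)$graph
}

random_partition <- function(n, kmax, seed) {
  set.seed(seed)
  as_partition(setNames(sample.int(kmax, n, replace = TRUE),
                        sprintf("p%02d", seq_len(n))))
}

# Brute-force k-core membership: repeatedly delete nodes of degree < k until
# none remain; returns the surviving node ids. Independent of the shell code.
brute_kcore <- function(graph, k) {
  nodes <- igraph::V(graph)$name
  adj <- lapply(igraph::as_adj_list(graph, mode = "all"),
                function(v) igraph::V(graph)$name[as.integer(v)])
  names(adj) <- nodes
  alive <- nodes
  repeat {
    deg <- vapply(alive,
                  function(v) sum(adj[[v]] %in% alive), integer(1))
    drop <- alive[deg < k]
    if (!length(drop)) return(alive)
    alive <- setdiff(alive, drop)
  }
}

# Direct pair-enumeration F-measure (quadratic; oracle for small n)
brute_f_measure <- function(pred, truth) {
  pred <- as_partition(pred)
  truth <- as_partition(truth)
  nodes <- names(pred)
  pairs <- utils::combn(nodes, 2)
  same <- function(p) unclass(p)[pairs[1, ]] == unclass(p)[pairs[2, ]]
  s <- same(pred)
  t_ <- same(truth[match(nodes, names(truth))])
  st <- sum(s & t_)
  if (!sum(s) && !sum(t_)) return(1)
  prec <- if (sum(s)) st / sum(s) else 0
  rec <- if (sum(t_)) st / sum(t_) else 0
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

# Independent NMI reference: igraph's compare() on 1-based membership vectors
ref_nmi <- function(x, y) {
  x <- as_partition(x)
  y <- as_partition(y)
  igraph::compare(unclass(x) + 1L,
                  unclass(y)[match(names(x), names(y))] + 1L,
                  method = "nmi")
}

edge_count <- function(graph) igraph::ecount(graph)
node_count <- function(graph) igraph::vcount(graph)
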