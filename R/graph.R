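#' @importFrom stats runif setNames
#' @importFrom utils combn read.delim write.table
NULL

# Canonical node-identifier order used for every "by node id" tie-break:
# identifiers that parse as (possibly signed) integers sort numerically and
# precede all other identifiers, which sort lexicographically in the C locale.
node_id_order <- function(ids) {
  ids <- as.character(ids)
  is_num <- grepl("^[+-]?[0-9]+$", ids)
  key <- suppressWarnings(as.numeric(ids))
  key[!is_num] <- NA_real_
  order(!is_num, key, ids, method = "radix")
}

#' Sort node identifiers into canonical order
#'
#' Identifiers parseable as integers are ordered numerically and come first;
#' all remaining identifiers follow in C-locale lexicographic order. This
#' single convention fixes every deterministic tie-break in the package
#' (update orders, community numbering, file output order).
#'
#' @param ids Character vector of node identifiers.
#' @return `ids` reordered canonically.
#' @export
#' @examples
#' sort_node_ids(c("v10", "v2", "3", "12"))
sort_node_ids <- function(ids) {
  ids <- as.character(ids)
  ids[node_id_order(ids)]
}

# rank of each id under the canonical order (1 = first)
node_id_rank <- function(ids) {
  r <- integer(length(ids))
  r[node_id_order(ids)] <- seq_along(ids)
  r
}

#' Build an undirected simple graph from edge endpoints
#'
#' Constructs the package's graph representation (an [igraph] graph whose
#' vertex order is the canonical node order, see [sort_node_ids()]).
#' Self-loops are dropped with a warning; duplicate and reversed edges are
#' collapsed. For weighted input, duplicates must agree on the weight.
#'
#' @param from,to Character vectors of edge endpoints (recycled pairwise).
#' @param weight Optional numeric vector of positive edge weights.
#' @param nodes Optional character vector of node ids to include even when
#'   isolated (degree 0).
#' @return An undirected simple `igraph` graph; weighted iff `weight` given.
#' @export
graph_from_edges <- function(from, to, weight = NULL, nodes = NULL) {
  from <- as.character(from)
  to <- as.character(to)
  stopifnot(length(from) == length(to))
  weighted <- !is.null(weight)
  if (weighted) {
    weight <- as.numeric(weight)
    stopifnot(length(weight) == length(from))
    if (any(!is.finite(weight) | weight <= 0)) {
      stop("edge weights must be positive finite numbers", call. = FALSE)
    }
  }

  loops <- from == to
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped", call. = FALSE)
  }
  keep_nodes <- unique(c(from, to, as.character(nodes)))
  from2 <- from[!loops]
  to2 <- to[!loops]
  w2 <- if (weighted) weight[!loops]

  # collapse reversed/duplicate edges on an unordered-pair key
  a <- pmin(from2, to2)
  b <- pmax(from2, to2)
  key <- paste(a, b, sep = "\r")
  first <- !duplicated(key)
  if (weighted && any(!first)) {
    ref <- setNames(w2[first], key[first])
    bad <- !first & abs(w2 - ref[key]) > 1e-12
    if (any(bad)) {
      stop("duplicate edge with conflicting weight: ",
           paste(a[bad][1], b[bad][1]), call. = FALSE)
    }
  }

  vnames <- sort_node_ids(keep_nodes)
  if (length(vnames) == 0L) stop("graph has no nodes", call. = FALSE)
  g <- igraph::make_empty_graph(n = length(vnames), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = vnames)
  if (any(first)) {
    idx <- rbind(match(a[first], vnames), match(b[first], vnames))
    g <- igraph::add_edges(g, as.vector(idx))
    if (weighted) igraph::E(g)$weight <- w2[first]
  }
  g
}

#' Read an undirected graph from a whitespace-delimited edge list
#'
#' Each non-comment line holds two node identifiers (plus a positive weight
#' when `weighted = TRUE`), separated by any whitespace. Lines starting with
#' `#` and blank lines are ignored. Node identifiers are kept verbatim as
#' strings. Self-loops are dropped (with a warning) and duplicate or
#' reversed edges collapsed; duplicated weighted edges must carry equal
#' weights.
#'
#' @param path Path to the edge-list file.
#' @param weighted Logical; expect a third column of positive edge weights.
#' @return An undirected simple `igraph` graph.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("# toy", "a b", "b c"), f)
#' g <- read_edge_list(f)
#' igraph::vcount(g)
read_edge_list <- function(path, weighted = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  data <- !grepl("^\\s*(#|$)", lines)
  if (!any(data)) stop("empty edge list: ", path, call. = FALSE)
  fields <- strsplit(trimws(lines[data]), "\\s+")
  nf <- lengths(fields)
  want <- if (weighted) 3L else 2L
  if (any(nf != want)) {
    bad <- which(data)[which(nf != want)[1]]
    stop("malformed edge list line ", bad, " in ", path,
         " (expected ", want, " fields, got ", nf[which(nf != want)[1]], ")",
         call. = FALSE)
  }
  from <- vapply(fields, `[[`, "", 1L)
  to <- vapply(fields, `[[`, "", 2L)
  weight <- NULL
  if (weighted) {
    wtxt <- vapply(fields, `[[`, "", 3L)
    weight <- suppressWarnings(as.numeric(wtxt))
    if (any(is.na(weight) | weight <= 0)) {
      bad <- which(data)[which(is.na(weight) | weight <= 0)[1]]
      stop("invalid weight on line ", bad, " in ", path, call. = FALSE)
    }
  }
  graph_from_edges(from, to, weight)
}

#' Write a graph as a whitespace-delimited edge list
#'
#' Inverse of [read_edge_list()]: one `u v` (or `u v w` for weighted graphs)
#' line per edge. Reading the file back reproduces the node set, edge set
#' and adjacency exactly.
#'
#' @param graph An `igraph` graph as produced by this package.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(graph, path) {
  ends <- igraph::ends(graph, igraph::E(graph), names = TRUE)
  lines <- character(0)
  if (nrow(ends) > 0) {
    lines <- paste(ends[, 1], ends[, 2])
    if ("weight" %in% igraph::edge_attr_names(graph)) {
      lines <- paste(lines, format(igraph::E(graph)$weight, digits = 15))
    }
  }
  iso <- setdiff(igraph::V(graph)$name, unique(as.vector(ends)))
  if (length(iso)) {
    lines <- c(lines, paste("#", "isolated:", paste(iso, collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

# internal accessors -------------------------------------------------------

graph_nodes <- function(graph) igraph::V(graph)$name

is_weighted_graph <- function(graph) {
  "weight" %in% igraph::edge_attr_names(graph)
}

# adjacency (and aligned weights) as lists of integer vertex indices;
# isolated vertices get zero-length entries
adjacency_lists <- function(graph) {
  n <- igraph::vcount(graph)
  if (igraph::ecount(graph) == 0L) {
    return(list(adj = rep(list(integer(0)), n),
                w = rep(list(numeric(0)), n)))
  }
  ends <- igraph::ends(graph, igraph::E(graph), names = FALSE)
  src <- c(ends[, 1], ends[, 2])
  dst <- c(ends[, 2], ends[, 1])
  w <- if (is_weighted_graph(graph)) {
    rep(igraph::E(graph)$weight, 2)
  } else {
    rep(1, length(src))
  }
  f <- factor(src, levels = seq_len(n))
  list(adj = unname(split(dst, f)), w = unname(split(w, f)))
}
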