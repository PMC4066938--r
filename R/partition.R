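# A partition is a named integer vector of 0-based community ids in canonical
# form, wrapped in class "partition":
#   * entries ordered by canonical node order (sort_node_ids),
#   * community ids consecutive from 0,
#   * communities numbered by their smallest member under node-id order.
# Only the grouping matters: any injective relabeling of the input labels
# yields the identical canonical object.

new_partition <- function(membership) {
  structure(membership, class = "partition")
}

#' Coerce labels to a canonical partition
#'
#' Groups nodes sharing a label into communities and renumbers the
#' communities canonically: ids are consecutive integers from 0, assigned in
#' order of each community's smallest member under the canonical node-id
#' order. The original label values are irrelevant beyond their grouping.
#'
#' @param x A named vector mapping node id to label (any atomic type), or an
#'   existing `partition`.
#' @return A `partition`: named integer vector of 0-based community ids.
#' @export
#' @examples
#' as_partition(c(a = 7, b = 7, c = 9))
as_partition <- function(x) {
  if (inherits(x, "partition")) return(x)
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
    stop("labels must be a fully named vector (node -> label)", call. = FALSE)
  }
  if (anyNA(x)) stop("labels contain NA", call. = FALSE)
  if (anyDuplicated(names(x))) {
    stop("duplicate node ids in labeling", call. = FALSE)
  }
  ids <- sort_node_ids(names(x))
  lab <- as.character(x)[match(ids, names(x))]
  # first occurrence along canonical node order = community's smallest member
  comm <- as.integer(factor(lab, levels = unique(lab))) - 1L
  new_partition(setNames(comm, ids))
}

#' Group a labeling over a graph into a canonical partition
#'
#' Nodes of `graph` sharing the same label form one community
#' ("nodes with the same label are divided into a community").
#'
#' @param labeling Named vector mapping node id to label; must cover every
#'   node of `graph` (extra entries are an error).
#' @param graph The graph whose node set the labeling describes.
#' @return A `partition` over the graph's nodes.
#' @export
canonicalize <- function(labeling, graph) {
  nodes <- graph_nodes(graph)
  missing <- setdiff(nodes, names(labeling))
  if (length(missing)) {
    stop("labeling does not cover node(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(labeling), nodes)
  if (length(extra)) {
    stop("labeling names node(s) absent from the graph: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  }
  as_partition(labeling[nodes])
}

#' Communities of a partition as node-id sets
#'
#' @param partition A `partition` (or coercible labeling).
#' @return List of character vectors, one per community, in community-id
#'   order; members sorted canonically.
#' @export
communities <- function(partition) {
  p <- as_partition(partition)
  ids <- unclass(p)
  unname(split(names(p), factor(ids, levels = sort(unique(ids)))))
}

#' Number of communities
#' @param partition A `partition` (or coercible labeling).
#' @return Integer count of communities.
#' @export
n_communities <- function(partition) {
  length(unique(unclass(as_partition(partition))))
}

#' @export
print.partition <- function(x, ...) {
  k <- n_communities(x)
  cat("Partition of", length(x), "nodes into", k,
      if (k == 1L) "community\n" else "communities\n")
  sizes <- tabulate(unclass(x) + 1L, nbins = k)
  cat("community sizes:", paste(sizes, collapse = " "), "\n")
  invisible(x)
}

#' Write a partition as a membership table
#'
#' Writes a two-column TSV with header `node<TAB>community`, one row per
#' node, rows in canonical node-id order, community ids 0-based.
#' Round-trips through [read_membership()].
#'
#' @param partition A `partition` (or coercible labeling) with at least one
#'   node.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_membership <- function(partition, path) {
  p <- as_partition(partition)
  if (length(p) == 0L) stop("cannot write an empty partition", call. = FALSE)
  df <- data.frame(node = names(p), community = unclass(p))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a membership table into a partition
#'
#' Expects the format written by [write_membership()]: TSV with columns
#' `node` and `community`. The result is canonicalized, so arbitrary
#' community labels are accepted.
#'
#' @param path Path to the membership TSV.
#' @return A `partition`.
#' @export
read_membership <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, colClasses = "character")
  if (!all(c("node", "community") %in% names(df))) {
    stop("membership file must have 'node' and 'community' columns: ", path,
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("empty membership file: ", path, call. = FALSE)
  as_partition(setNames(df$community, df$node))
}
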