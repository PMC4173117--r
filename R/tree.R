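# ID-addressed dendrogram trees: the bridge between a merge sequence and the
# JSON document. Leaves are named leaf_0..leaf_{n-1} in input row order,
# inner nodes node_0..node_{n-2} in merge order (0-based, the package's
# fixed convention).

new_dendro_tree <- function(nodes, root_id) {
  structure(list(nodes = nodes, root_id = root_id), class = "dendro_tree")
}

#' @export
print.dendro_tree <- function(x, ...) {
  nl <- sum(vapply(x$nodes, function(nd) is.null(nd$left_child), logical(1L)))
  cat(sprintf("<dendro_tree: %d leaves, %d nodes, root '%s'>\n",
              nl, length(x$nodes), x$root_id))
  invisible(x)
}

leaf_ids_of <- function(tree) {
  names(tree$nodes)[vapply(tree$nodes, function(nd) is.null(nd$left_child),
                           logical(1L))]
}

is_leaf_node <- function(tree, id) is.null(tree$nodes[[id]]$left_child)

#' Build an ID-addressed dendrogram tree from a merge sequence
#'
#' Each node is identified by a unique ID string; every inner node has a
#' `left_child` and a `right_child`, leaves have none, and the only node
#' without a `parent` is the root. `count` is the number of heatmap rows
#' below a node (1 at every leaf, even when the leaf aggregates several data
#' points); `distance` is the merge height (0 at leaves). Row-axis leaves
#' additionally carry `features` (displayed values) and `objects` (the data
#' point IDs the row represents); column-axis trees carry neither.
#'
#' @param merges a `merge_sequence` from [compute_linkage] or
#'   [naive_linkage].
#' @param leaf_objects list of character vectors, one per leaf in input row
#'   order, or `NULL` for a column tree.
#' @param leaf_features list of numeric vectors (equal lengths), one per
#'   leaf, or `NULL`.
#' @return An object of class `dendro_tree`.
#' @export
build_tree <- function(merges, leaf_objects = NULL, leaf_features = NULL) {
  stopifnot(inherits(merges, "merge_sequence"))
  n <- n_leaves(merges)
  k <- nrow(merges)
  if (k != n - 1L) stop("merge sequence must contain exactly n-1 merges")
  if (!is.null(leaf_objects) && length(leaf_objects) != n) {
    stop("leaf_objects must have one entry per leaf")
  }
  if (!is.null(leaf_features)) {
    if (length(leaf_features) != n) stop("leaf_features must have one entry per leaf")
    flen <- unique(lengths(leaf_features))
    if (length(flen) != 1L) stop("leaf feature vectors must share one length")
  }
  used <- logical(2L * n - 1L)
  id_of <- function(c0) {
    if (c0 < n) paste0("leaf_", c0) else paste0("node_", c0 - n)
  }
  nodes <- vector("list", 2L * n - 1L)
  names(nodes) <- c(paste0("leaf_", 0:(n - 1L)),
                    if (k > 0L) paste0("node_", 0:(k - 1L)))
  for (i in seq_len(n)) {
    nd <- list(count = 1L, distance = 0)
    if (!is.null(leaf_features)) nd$features <- as.numeric(leaf_features[[i]])
    if (!is.null(leaf_objects)) nd$objects <- as.character(leaf_objects[[i]])
    nodes[[i]] <- nd
  }
  for (i in seq_len(k)) {
    a <- merges$left[i]; b <- merges$right[i]
    if (a < 0L || b < 0L || a >= n + i - 1L || b >= n + i - 1L) {
      stop(sprintf("merge %d references an out-of-range cluster index", i - 1L))
    }
    if (used[a + 1L] || used[b + 1L]) {
      stop(sprintf("merge %d reuses an already-merged cluster index", i - 1L))
    }
    used[a + 1L] <- used[b + 1L] <- TRUE
    la <- id_of(a); lb <- id_of(b)
    nodes[[n + i]] <- list(count = nodes[[la]]$count + nodes[[lb]]$count,
                           distance = merges$height[i],
                           left_child = la, right_child = lb)
    nodes[[la]]$parent <- id_of(n + i - 1L)
    nodes[[lb]]$parent <- id_of(n + i - 1L)
  }
  new_dendro_tree(nodes, paste0("node_", k - 1L))
}

#' Extract the merge sequence encoded by a dendrogram tree
#'
#' Inverse of [build_tree] on topology and heights: leaves are numbered by
#' their `leaf_i` suffix, inner nodes by their `node_i` suffix (merge order).
#'
#' @param tree a `dendro_tree` built by [build_tree].
#' @return A `merge_sequence`.
#' @export
merges_from_tree <- function(tree) {
  stopifnot(inherits(tree, "dendro_tree"))
  ids <- names(tree$nodes)
  leaf_ids <- ids[grepl("^leaf_[0-9]+$", ids)]
  node_ids <- ids[grepl("^node_[0-9]+$", ids)]
  n <- length(leaf_ids)
  idx_of <- function(id) {
    num <- as.integer(sub("^(leaf|node)_", "", id))
    if (startsWith(id, "leaf_")) num else n + num
  }
  node_ids <- node_ids[order(as.integer(sub("^node_", "", node_ids)))]
  left <- integer(length(node_ids)); right <- integer(length(node_ids))
  height <- numeric(length(node_ids))
  for (i in seq_along(node_ids)) {
    nd <- tree$nodes[[node_ids[i]]]
    left[i] <- idx_of(nd$left_child)
    right[i] <- idx_of(nd$right_child)
    height[i] <- nd$distance
  }
  orient_merges(left, right, height, n)
}
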