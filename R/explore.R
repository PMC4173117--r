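# Programmatic equivalents of the interactive exploration semantics:
# display order, cluster selection, row lookup by object ID, and cutting a
# tree into k subtree roots.

#' Display order of a tree's leaves
#'
#' Depth-first in-order traversal, left child before right child. This is
#' the top-to-bottom order of heatmap rows (or left-to-right order of
#' columns).
#'
#' @param tree a `dendro_tree`.
#' @return Character vector of leaf IDs.
#' @export
leaf_order <- function(tree) {
  stopifnot(inherits(tree, "dendro_tree"))
  out <- character(0L)
  stack <- tree$root_id
  while (length(stack) > 0L) {
    id <- stack[length(stack)]; stack <- stack[-length(stack)]
    nd <- tree$nodes[[id]]
    if (is.null(nd)) stop(sprintf("node '%s' not found", id))
    if (is.null(nd$left_child)) {
      out <- c(out, id)
    } else {
      # push right first so left is visited first
      stack <- c(stack, nd$right_child, nd$left_child)
    }
  }
  out
}

#' Select the subtree below a node
#'
#' The programmatic counterpart of clicking a dendrogram node: returns the
#' leaves below it (in display order) and the flattened object IDs they
#' carry.
#'
#' @param tree a `dendro_tree`.
#' @param node_id ID of an existing node (leaf or inner).
#' @return An object of class `selection`: list with `node_id`, `leaf_ids`
#'   and `object_ids`.
#' @export
objects_under <- function(tree, node_id) {
  stopifnot(inherits(tree, "dendro_tree"))
  if (is.null(tree$nodes[[node_id]])) {
    stop(sprintf("unknown node '%s'", node_id))
  }
  sub <- tree
  sub$root_id <- node_id
  leaves <- leaf_order(sub)
  objs <- unlist(lapply(leaves, function(id) tree$nodes[[id]]$objects))
  structure(list(node_id = node_id, leaf_ids = leaves,
                 object_ids = as.character(if (is.null(objs)) character(0L) else objs)),
            class = "selection")
}

#' Leaves whose rows contain any of the queried objects
#'
#' The highlight query: given object (data point) IDs, find every heatmap
#' row — leaf — whose objects intersect the query, in display order. IDs
#' matching no leaf are reported separately, not errored.
#'
#' @param doc a `heatmap_document`.
#' @param object_ids character vector of object IDs.
#' @return List with `leaf_ids` (display order) and `unknown` (unmatched
#'   query IDs).
#' @export
rows_for_objects <- function(doc, object_ids) {
  stopifnot(inherits(doc, "heatmap_document"))
  object_ids <- as.character(object_ids)
  tree <- doc$data$nodes
  ord <- leaf_order(tree)
  hit <- vapply(ord, function(id) {
    any(tree$nodes[[id]]$objects %in% object_ids)
  }, logical(1L))
  known <- unlist(lapply(ord, function(id) tree$nodes[[id]]$objects))
  list(leaf_ids = ord[hit],
       unknown = setdiff(object_ids, known))
}

#' Cut a tree into k subtree roots
#'
#' Undoes the k-1 highest merges of the tree: starting from the root, the
#' current root with the largest distance is repeatedly replaced by its two
#' children. Ties in distance are resolved by merge order (the later merge,
#' i.e. the node with the larger numeric suffix, is removed first). The
#' returned nodes' leaf sets partition the tree's leaves.
#'
#' @param tree a `dendro_tree`.
#' @param k integer, `1 <= k <=` leaf count.
#' @return Character vector of k node IDs, ordered by display position of
#'   their leftmost leaf.
#' @export
cut_at <- function(tree, k) {
  stopifnot(inherits(tree, "dendro_tree"))
  nl <- length(leaf_ids_of(tree))
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > nl) {
    stop(sprintf("k must satisfy 1 <= k <= %d", nl))
  }
  roots <- tree$root_id
  merge_rank <- function(id) {
    s <- suppressWarnings(as.integer(sub("^node_", "", id)))
    if (is.na(s)) -1L else s
  }
  while (length(roots) < k) {
    inner <- roots[!vapply(roots, function(id) is_leaf_node(tree, id), logical(1L))]
    dists <- vapply(inner, function(id) tree$nodes[[id]]$distance, numeric(1L))
    ranks <- vapply(inner, merge_rank, integer(1L))
    pick <- inner[order(-dists, -ranks)][1L]
    nd <- tree$nodes[[pick]]
    roots <- c(setdiff(roots, pick), nd$left_child, nd$right_child)
  }
  ord <- leaf_order(tree)
  first_leaf <- vapply(roots, function(id) {
    match(objects_under(tree, id)$leaf_ids[1L], ord)
  }, integer(1L))
  roots[order(first_leaf)]
}
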