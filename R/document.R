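# The three-block cluster-heatmap JSON document: build, serialize, parse,
# validate. The data block holds feature names and the row dendrogram whose
# leaves carry features and objects; the optional metadata block maps leaf
# IDs to annotation value lists; the optional column_dendrogram block is a
# payload-free tree over the features.

new_heatmap_document <- function(data, metadata = NULL, column_dendrogram = NULL) {
  structure(list(data = data, metadata = metadata,
                 column_dendrogram = column_dendrogram),
            class = "heatmap_document")
}

#' @export
print.heatmap_document <- function(x, ...) {
  nl <- length(leaf_ids_of(x$data$nodes))
  cat(sprintf("<heatmap_document: %d rows x %d features%s%s>\n",
              nl, length(x$data$feature_names),
              if (!is.null(x$metadata)) ", metadata" else "",
              if (!is.null(x$column_dendrogram)) ", column dendrogram" else ""))
  invisible(x)
}

#' Assemble a cluster-heatmap document
#'
#' Combines a row dendrogram (whose leaves carry features and objects), an
#' optional column dendrogram and an optional metadata table into one
#' document. When a column tree is supplied, the feature names and every
#' leaf's feature array are permuted into the column tree's leaf order, so
#' the document's column order is materialized. Metadata are keyed by leaf
#' IDs: a leaf holding a single object takes that object's metadata row
#' verbatim; a leaf holding several (compressed) objects aggregates them with
#' `stat` (categorical columns take the modal label).
#'
#' @param row_tree a `dendro_tree` with leaf features and objects.
#' @param col_tree optional `dendro_tree` over the features (no payload).
#' @param metadata optional [metadata_table] keyed by object IDs.
#' @param feature_names character vector naming the data features, in the
#'   original column order.
#' @param stat statistic for metadata aggregation on compressed leaves.
#' @return A `heatmap_document`.
#' @export
build_document <- function(row_tree, col_tree = NULL, metadata = NULL,
                           feature_names, stat = c("mean", "median")) {
  stopifnot(inherits(row_tree, "dendro_tree"))
  stat <- match.arg(stat)
  feature_names <- as.character(feature_names)
  leaf_ids <- leaf_order(row_tree)
  flen <- length(row_tree$nodes[[leaf_ids[1L]]]$features)
  if (flen != length(feature_names)) {
    stop("feature_names length does not match the leaves' feature vectors")
  }
  if (!is.null(col_tree)) {
    col_leaves <- leaf_order(col_tree)
    if (length(col_leaves) != length(feature_names)) {
      stop(sprintf("column tree has %d leaves but there are %d features",
                   length(col_leaves), length(feature_names)))
    }
    perm <- as.integer(sub("^leaf_", "", col_leaves)) + 1L
    feature_names <- feature_names[perm]
    for (id in leaf_ids) {
      row_tree$nodes[[id]]$features <- row_tree$nodes[[id]]$features[perm]
    }
  }
  meta_block <- NULL
  if (!is.null(metadata)) {
    stopifnot(inherits(metadata, "metadata_table"))
    nodes <- list()
    matched <- character(0L)
    for (id in leaf_ids) {
      objs <- row_tree$nodes[[id]]$objects
      idx <- match(objs, metadata$row_ids)
      matched <- c(matched, objs[!is.na(idx)])
      nodes[[id]] <- metadata_cell_values(metadata, idx, stat)
    }
    unmatched <- setdiff(metadata$row_ids, matched)
    if (length(unmatched) > 0L) {
      warning(sprintf("%d metadata row(s) match no leaf object and were dropped",
                      length(unmatched)))
    }
    meta_block <- list(feature_names = metadata$feature_names, nodes = nodes)
  }
  new_heatmap_document(
    data = list(feature_names = feature_names, nodes = row_tree),
    metadata = meta_block,
    column_dendrogram = col_tree)
}

# Value list for one leaf: verbatim for a single matched object, aggregated
# otherwise. Unmatched objects contribute nothing; no match at all -> NAs.
metadata_cell_values <- function(metadata, idx, stat) {
  hit <- idx[!is.na(idx)]
  f <- stat_fun(stat)
  lapply(seq_along(metadata$feature_names), function(j) {
    col <- metadata$values[[j]]
    if (length(hit) == 0L) {
      if (is.numeric(col)) NA_real_ else NA_character_
    } else if (length(hit) == 1L) {
      col[hit]
    } else if (is.numeric(col)) {
      if (all(is.na(col[hit]))) NA_real_ else f(col[hit])
    } else {
      aggregate_categorical(col[hit])
    }
  })
}

# ---- serialization ----------------------------------------------------------

# Deterministic node ordering: leaf_* by numeric suffix, then node_* by
# numeric suffix, then anything else alphabetically.
natural_node_order <- function(ids) {
  suffix <- suppressWarnings(as.integer(sub("^(leaf|node)_", "", ids)))
  grp <- ifelse(grepl("^leaf_[0-9]+$", ids), 0L,
                ifelse(grepl("^node_[0-9]+$", ids), 1L, 2L))
  ids[order(grp, suffix, ids)]
}

tree_to_json_list <- function(tree) {
  ids <- natural_node_order(names(tree$nodes))
  out <- vector("list", length(ids))
  names(out) <- ids
  for (id in ids) {
    nd <- tree$nodes[[id]]
    rec <- list(count = nd$count, distance = nd$distance)
    if (!is.null(nd$features)) rec$features <- I(unname(as.numeric(nd$features)))
    if (!is.null(nd$parent)) rec$parent <- nd$parent
    if (!is.null(nd$objects)) rec$objects <- I(unname(as.character(nd$objects)))
    if (!is.null(nd$left_child)) {
      rec$left_child <- nd$left_child
      rec$right_child <- nd$right_child
    }
    if (!is.null(nd$extra)) rec <- c(rec, nd$extra[order(names(nd$extra))])
    out[[id]] <- rec
  }
  out
}

#' Serialize a cluster-heatmap document to JSON text
#'
#' Emits the three-block JSON format with the fixed key vocabulary (`count`,
#' `distance`, `features`, `parent`, `objects`, `left_child`, `right_child`,
#' `feature_names`, `nodes`). The root node is written without a `parent`
#' key; key order and node order are deterministic; numbers are written at
#' full precision unless `digits` is given. Invalid documents are refused
#' with the validator's report.
#'
#' @param doc a `heatmap_document`.
#' @param digits optional number of significant digits for compact output;
#'   `NA` (default) keeps full precision.
#' @param pretty logical; pretty-print the JSON.
#' @return A JSON string (character scalar).
#' @export
serialize_document <- function(doc, digits = NA, pretty = FALSE) {
  problems <- validate_document(doc)
  if (length(problems) > 0L) {
    stop(paste(c("refusing to serialize an invalid document:",
                 paste0("  - ", problems)), collapse = "\n"))
  }
  x <- list(data = list(feature_names = I(doc$data$feature_names),
                        nodes = tree_to_json_list(doc$data$nodes)))
  if (!is.null(doc$metadata)) {
    leaf_seq <- natural_node_order(names(doc$metadata$nodes))
    x$metadata <- list(
      feature_names = I(doc$metadata$feature_names),
      nodes = lapply(doc$metadata$nodes[leaf_seq], function(v) lapply(v, identity)))
  }
  if (!is.null(doc$column_dendrogram)) {
    x$column_dendrogram <- list(nodes = tree_to_json_list(doc$column_dendrogram))
  }
  # I() makes `digits` significant digits; 17 of them reproduce any double
  # bit-exactly on re-parsing
  digits <- I(if (is.na(digits)) 17 else digits)
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = digits,
                                na = "null", pretty = pretty))
}

# ---- parsing ----------------------------------------------------------------

KNOWN_NODE_KEYS <- c("count", "distance", "features", "parent", "objects",
                     "left_child", "right_child")

parse_tree_block <- function(nodes_raw, block, payload) {
  if (is.null(nodes_raw) || length(nodes_raw) == 0L) {
    stop(sprintf("%s block has no nodes", block))
  }
  ids <- names(nodes_raw)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop(sprintf("%s block: every node needs an ID key", block))
  }
  nodes <- vector("list", length(ids))
  names(nodes) <- ids
  need <- function(rec, id, key) {
    if (is.null(rec[[key]])) {
      stop(sprintf("%s block: node '%s' is missing mandatory key '%s'",
                   block, id, key))
    }
    rec[[key]]
  }
  for (id in ids) {
    rec <- nodes_raw[[id]]
    inner <- !is.null(rec$left_child) || !is.null(rec$right_child)
    nd <- list(count = as.numeric(need(rec, id, "count")),
               distance = as.numeric(need(rec, id, "distance")))
    if (inner) {
      nd$left_child <- as.character(need(rec, id, "left_child"))
      nd$right_child <- as.character(need(rec, id, "right_child"))
    } else if (payload) {
      nd$features <- as.numeric(unlist(need(rec, id, "features")))
      nd$objects <- as.character(unlist(need(rec, id, "objects")))
    }
    if (!is.null(rec$parent)) nd$parent <- as.character(rec$parent)
    extra <- rec[setdiff(names(rec), KNOWN_NODE_KEYS)]
    if (length(extra) > 0L) nd$extra <- extra
    if (!inner && !payload) {
      # a payload-free tree must not carry features/objects; keep them as
      # parsed extras so the validator can flag them
      if (!is.null(rec$features) || !is.null(rec$objects)) {
        nd$extra <- c(nd$extra, rec[intersect(names(rec), c("features", "objects"))])
      }
    }
    nodes[[id]] <- nd
  }
  parentless <- ids[vapply(nodes, function(nd) is.null(nd$parent), logical(1L))]
  if (length(parentless) == 0L) {
    stop(sprintf("%s block: no root (every node has a parent)", block))
  }
  new_dendro_tree(nodes, parentless[1L])
}

#' Parse a cluster-heatmap JSON document
#'
#' Reconstructs a `heatmap_document` from its JSON text. Unknown node keys
#' are preserved opaquely (and re-emitted on serialization) for forward
#' compatibility. A missing mandatory key is an error naming the node and
#' the key.
#'
#' @param text JSON string, or a connection/path accepted by
#'   [jsonlite::fromJSON].
#' @return A `heatmap_document`.
#' @export
parse_document <- function(text) {
  x <- jsonlite::fromJSON(text, simplifyVector = FALSE)
  if (!is.list(x) || is.null(x$data)) stop("data block missing")
  data_tree <- parse_tree_block(x$data$nodes, "data", payload = TRUE)
  feature_names <- as.character(unlist(x$data$feature_names))
  meta <- NULL
  if (!is.null(x$metadata)) {
    vals <- lapply(x$metadata$nodes, function(v) {
      lapply(v, function(cell) if (is.null(cell)) NA else cell)
    })
    meta <- list(feature_names = as.character(unlist(x$metadata$feature_names)),
                 nodes = vals)
  }
  col_tree <- NULL
  if (!is.null(x$column_dendrogram)) {
    col_tree <- parse_tree_block(x$column_dendrogram$nodes,
                                 "column_dendrogram", payload = FALSE)
  }
  new_heatmap_document(
    data = list(feature_names = feature_names, nodes = data_tree),
    metadata = meta, column_dendrogram = col_tree)
}

# ---- validation -------------------------------------------------------------

validate_tree <- function(tree, label, payload, n_features = NULL) {
  v <- character(0L)
  say <- function(fmt, ...) v <<- c(v, sprintf(paste0(label, ": ", fmt), ...))
  nodes <- tree$nodes
  ids <- names(nodes)
  parentless <- ids[vapply(nodes, function(nd) is.null(nd$parent), logical(1L))]
  if (length(parentless) != 1L) {
    say("multiple roots (%s)", paste(parentless, collapse = ", "))
  }
  for (id in ids) {
    nd <- nodes[[id]]
    inner <- !is.null(nd$left_child)
    if (inner) {
      for (side in c("left_child", "right_child")) {
        ch <- nd[[side]]
        if (is.null(ch)) {
          say("node '%s' lacks %s", id, side)
        } else if (is.null(nodes[[ch]])) {
          say("node '%s' %s '%s' does not exist", id, side, ch)
        } else if (!identical(nodes[[ch]]$parent, id)) {
          say("node '%s': child '%s' does not point back to it", id, ch)
        }
      }
      if (!is.null(nodes[[nd$left_child]]) && !is.null(nodes[[nd$right_child]])) {
        expect <- nodes[[nd$left_child]]$count + nodes[[nd$right_child]]$count
        if (!isTRUE(all.equal(as.numeric(nd$count), as.numeric(expect)))) {
          say("node '%s' count %s != sum of children counts %s",
              id, nd$count, expect)
        }
      }
    } else {
      if (!isTRUE(all.equal(as.numeric(nd$count), 1))) {
        say("leaf '%s' has count %s (must be 1)", id, nd$count)
      }
      if (!isTRUE(all.equal(as.numeric(nd$distance), 0))) {
        say("leaf '%s' has non-zero distance %s", id, nd$distance)
      }
      if (payload) {
        if (is.null(nd$features)) {
          say("leaf '%s' lacks features", id)
        } else if (!is.null(n_features) && length(nd$features) != n_features) {
          say("leaf '%s' has %d features, expected %d", id,
              length(nd$features), n_features)
        }
        if (is.null(nd$objects) || length(nd$objects) == 0L) {
          say("leaf '%s' has no objects", id)
        }
      } else {
        if (!is.null(nd$features) || !is.null(nd$objects) ||
            any(c("features", "objects") %in% names(nd$extra))) {
          say("leaf '%s' of a column dendrogram must carry neither features nor objects", id)
        }
      }
    }
    if (is.numeric(nd$distance) && nd$distance < 0) {
      say("node '%s' has negative distance", id)
    }
    if (!is.null(nd$parent) && is.null(nodes[[nd$parent]])) {
      say("node '%s' parent '%s' does not exist", id, nd$parent)
    }
  }
  # reachability from the root
  if (length(parentless) == 1L) {
    seen <- character(0L)
    stack <- parentless
    while (length(stack) > 0L) {
      id <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (id %in% seen || is.null(nodes[[id]])) next
      seen <- c(seen, id)
      nd <- nodes[[id]]
      if (!is.null(nd$left_child)) stack <- c(stack, nd$left_child, nd$right_child)
    }
    orphan <- setdiff(ids, seen)
    if (length(orphan) > 0L) {
      say("node '%s' is unreachable from the root", orphan[1L])
    }
  }
  v
}

#' Validate a cluster-heatmap document
#'
#' Checks every structural invariant of the format: single root per tree,
#' consistent parent/child links, counts (1 at leaves, sum of children at
#' inner nodes), non-negative distances (0 at leaves), feature-vector
#' lengths, non-empty and globally disjoint leaf objects, metadata keyed by
#' existing data leaves with value lists of the metadata width, and a column
#' dendrogram with exactly one payload-free leaf per feature.
#'
#' @param doc a `heatmap_document`.
#' @return Character vector of violations; empty when the document is valid.
#' @export
validate_document <- function(doc) {
  v <- character(0L)
  if (!inherits(doc, "heatmap_document") || is.null(doc$data)) {
    return("data block missing")
  }
  nf <- length(doc$data$feature_names)
  v <- c(v, validate_tree(doc$data$nodes, "data", payload = TRUE,
                          n_features = nf))
  leaf_ids <- leaf_ids_of(doc$data$nodes)
  all_objs <- unlist(lapply(leaf_ids, function(id) doc$data$nodes$nodes[[id]]$objects))
  dup <- unique(all_objs[duplicated(all_objs)])
  if (length(dup) > 0L) {
    v <- c(v, sprintf("data: object '%s' appears in more than one leaf", dup[1L]))
  }
  if (!is.null(doc$metadata)) {
    mk <- names(doc$metadata$nodes)
    stray <- setdiff(mk, leaf_ids)
    if (length(stray) > 0L) {
      v <- c(v, sprintf("metadata: key '%s' is not a data leaf", stray[1L]))
    }
    mw <- length(doc$metadata$feature_names)
    for (id in mk) {
      if (length(doc$metadata$nodes[[id]]) != mw) {
        v <- c(v, sprintf("metadata: '%s' has %d values, expected %d",
                          id, length(doc$metadata$nodes[[id]]), mw))
      }
    }
  }
  if (!is.null(doc$column_dendrogram)) {
    v <- c(v, validate_tree(doc$column_dendrogram, "column_dendrogram",
                            payload = FALSE))
    ncl <- length(leaf_ids_of(doc$column_dendrogram))
    if (ncl != nf) {
      v <- c(v, sprintf("column_dendrogram has %d leaves but there are %d features",
                        ncl, nf))
    }
  }
  v
}
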