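# Row compression: cut the row dendrogram into k groups and aggregate each
# group into one vector (mean or median). The reduced rows are re-clustered
# from scratch to produce the output dendrogram.

#' Cut a merge sequence into k groups
#'
#' Undoes the k-1 last merges: the groups are the clusters present just
#' before those merges were applied. Groups are ordered by their smallest
#' original row index.
#'
#' @param merges a `merge_sequence` over n rows.
#' @param k integer number of groups, `2 <= k <= n`.
#' @return An object of class `row_grouping`: list with `groups` (list of
#'   1-based integer row-index vectors) and `n_rows`.
#' @export
cut_to_k <- function(merges, k) {
  stopifnot(inherits(merges, "merge_sequence"))
  n <- n_leaves(merges)
  k <- as.integer(k)
  if (is.na(k) || k < 2L || k > n) {
    stop(sprintf("k must satisfy 2 <= k <= %d (got %s)", n, k))
  }
  comp <- seq_len(n)            # component id per original row
  for (i in seq_len(n - k)) {   # apply all but the last k-1 merges
    a <- merges$left[i]; b <- merges$right[i]
    rows_a <- member_rows(merges, a)
    rows_b <- member_rows(merges, b)
    comp[c(rows_a, rows_b)] <- min(comp[c(rows_a, rows_b)])
  }
  groups <- unname(split(seq_len(n), comp))
  groups <- groups[order(vapply(groups, min, 0L))]
  structure(list(groups = groups, n_rows = n), class = "row_grouping")
}

# 1-based original row indices contained in 0-based cluster id.
member_rows <- function(merges, id) {
  n <- n_leaves(merges)
  if (id < n) return(id + 1L)
  i <- id - n + 1L
  c(member_rows(merges, merges$left[i]), member_rows(merges, merges$right[i]))
}

stat_fun <- function(stat) {
  switch(match.arg(stat, c("mean", "median")),
         mean = function(x) mean(x, na.rm = TRUE),
         median = function(x) stats::median(x, na.rm = TRUE))
}

#' Aggregate data rows group-wise
#'
#' Each group of original rows is collapsed to a single vector whose elements
#' are the per-feature mean or median of the group's rows. The output carries
#' one object list per reduced row holding the original row IDs it merges.
#'
#' @param data a [data_matrix].
#' @param grouping a `row_grouping` partitioning `data`'s rows.
#' @param stat `"mean"` or `"median"`.
#' @return List with `data` (the reduced [data_matrix], rows named
#'   `group_1..group_k`) and `objects` (list of original-row-ID vectors).
#' @export
aggregate_rows <- function(data, grouping, stat = c("mean", "median")) {
  stopifnot(inherits(data, "data_matrix"), inherits(grouping, "row_grouping"))
  stat <- match.arg(stat)
  check_partition(grouping, length(data$row_ids))
  f <- stat_fun(stat)
  vals <- t(vapply(grouping$groups, function(g) {
    apply(data$values[g, , drop = FALSE], 2L, f)
  }, numeric(length(data$feature_names))))
  if (length(data$feature_names) == 1L) vals <- matrix(vals, ncol = 1L)
  objects <- lapply(grouping$groups, function(g) data$row_ids[g])
  list(data = data_matrix(vals,
                          row_ids = paste0("group_", seq_along(grouping$groups)),
                          feature_names = data$feature_names),
       objects = objects)
}

check_partition <- function(grouping, n) {
  all_idx <- sort(unlist(grouping$groups))
  if (!identical(all_idx, seq_len(n))) {
    stop("grouping does not partition the data rows")
  }
  invisible(TRUE)
}

#' Aggregate a metadata table group-wise
#'
#' Numeric columns are collapsed with the chosen statistic; categorical
#' columns take the most frequent label of the group, ties broken by the
#' lexicographically smallest label. `NA` cells are ignored; an all-`NA`
#' group yields `NA`.
#'
#' @param meta a [metadata_table] aligned to the original row order.
#' @param grouping a `row_grouping`.
#' @param stat `"mean"` or `"median"` for numeric columns.
#' @return A reduced [metadata_table] with rows `group_1..group_k`.
#' @export
aggregate_metadata <- function(meta, grouping, stat = c("mean", "median")) {
  stopifnot(inherits(meta, "metadata_table"), inherits(grouping, "row_grouping"))
  stat <- match.arg(stat)
  f <- stat_fun(stat)
  cols <- lapply(meta$values, function(col) {
    vapply(grouping$groups, function(g) {
      cells <- col[g]
      if (is.numeric(cells)) {
        if (all(is.na(cells))) NA_real_ else f(cells)
      } else {
        aggregate_categorical(cells)
      }
    }, if (is.numeric(col)) numeric(1L) else character(1L))
  })
  names(cols) <- meta$feature_names
  metadata_table(as.data.frame(cols, optional = TRUE, stringsAsFactors = FALSE),
                 row_ids = paste0("group_", seq_along(grouping$groups)),
                 feature_names = meta$feature_names)
}

aggregate_categorical <- function(cells) {
  cells <- cells[!is.na(cells)]
  if (length(cells) == 0L) return(NA_character_)
  tab <- table(cells)
  best <- names(tab)[tab == max(tab)]
  sort(best)[1L]
}
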