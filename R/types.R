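# Core containers shared by every module.

#' Numeric data matrix with row IDs and feature names
#'
#' The clustering input: a rectangular grid of finite numeric values, one row
#' per data point. Row IDs must be unique; feature names are auto-generated
#' (`feature_1`, `feature_2`, ...) when not supplied.
#'
#' @param values numeric matrix (or object coercible to one).
#' @param row_ids character vector of unique row identifiers; defaults to the
#'   matrix rownames.
#' @param feature_names character vector of column names; defaults to the
#'   matrix colnames, or auto-generated names when absent.
#' @return An object of class `data_matrix`: a list with elements `row_ids`,
#'   `feature_names` and `values` (a named numeric matrix).
#' @examples
#' data_matrix(matrix(1:4, 2), row_ids = c("a", "b"))
#' @export
data_matrix <- function(values, row_ids = rownames(values),
                        feature_names = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(row_ids)) {
    stop("row_ids are required (no rownames on 'values')")
  }
  row_ids <- as.character(row_ids)
  if (is.null(feature_names)) {
    feature_names <- paste0("feature_", seq_len(ncol(values)))
  }
  feature_names <- as.character(feature_names)
  if (length(row_ids) != nrow(values)) {
    stop("length(row_ids) must equal nrow(values)")
  }
  if (length(feature_names) != ncol(values)) {
    stop("length(feature_names) must equal ncol(values)")
  }
  dup <- duplicated(row_ids)
  if (any(dup)) {
    stop(sprintf("duplicate row ID '%s'", row_ids[dup][1L]))
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at row '%s', feature '%s'",
                 row_ids[bad[1L]], feature_names[bad[2L]]))
  }
  dimnames(values) <- list(row_ids, feature_names)
  structure(list(row_ids = row_ids, feature_names = feature_names,
                 values = values),
            class = "data_matrix")
}

#' @export
print.data_matrix <- function(x, ...) {
  cat(sprintf("<data_matrix: %d rows x %d features>\n",
              length(x$row_ids), length(x$feature_names)))
  print(utils::head(x$values, 6L))
  invisible(x)
}

#' Per-row annotation table with numeric or categorical columns
#'
#' Metadata rows are keyed by the same IDs as the data matrix but are never
#' clustered. Every column must be homogeneously numeric or categorical
#' (character); factors are converted to character.
#'
#' @param values data.frame whose columns are numeric or character.
#' @param row_ids character vector of unique row identifiers.
#' @param feature_names column names; defaults to `names(values)`.
#' @return An object of class `metadata_table`.
#' @export
metadata_table <- function(values, row_ids = rownames(values),
                           feature_names = colnames(values)) {
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  for (j in seq_along(values)) {
    if (is.factor(values[[j]])) values[[j]] <- as.character(values[[j]])
    if (!is.numeric(values[[j]]) && !is.character(values[[j]])) {
      stop(sprintf("metadata column %d is neither numeric nor categorical", j))
    }
  }
  if (is.null(row_ids)) stop("row_ids are required")
  row_ids <- as.character(row_ids)
  if (is.null(feature_names)) feature_names <- paste0("meta_", seq_along(values))
  feature_names <- as.character(feature_names)
  if (length(row_ids) != nrow(values)) {
    stop("length(row_ids) must equal nrow(values)")
  }
  if (length(feature_names) != ncol(values)) {
    stop("length(feature_names) must equal ncol(values)")
  }
  dup <- duplicated(row_ids)
  if (any(dup)) stop(sprintf("duplicate row ID '%s'", row_ids[dup][1L]))
  rownames(values) <- row_ids
  colnames(values) <- feature_names
  structure(list(row_ids = row_ids, feature_names = feature_names,
                 values = values),
            class = "metadata_table")
}

#' @export
print.metadata_table <- function(x, ...) {
  cat(sprintf("<metadata_table: %d rows x %d features>\n",
              length(x$row_ids), length(x$feature_names)))
  print(utils::head(x$values, 6L))
  invisible(x)
}
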