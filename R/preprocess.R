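# Min-max feature scaling and the normalized-cluster / original-display
# pairing. Scaling is per feature (column-wise) only.

#' Fit min-max scaling parameters
#'
#' Records, per feature, the column minimum and maximum of the matrix the
#' scaler is fitted on.
#'
#' @param data a [data_matrix].
#' @return An object of class `minmax_params`: named numeric vectors `min`
#'   and `max`, one entry per feature.
#' @export
fit_minmax <- function(data) {
  stopifnot(inherits(data, "data_matrix"))
  if (length(data$row_ids) == 0L) stop("cannot fit on an empty matrix")
  mins <- apply(data$values, 2L, min)
  maxs <- apply(data$values, 2L, max)
  names(mins) <- names(maxs) <- data$feature_names
  structure(list(min = mins, max = maxs), class = "minmax_params")
}

#' Apply min-max scaling
#'
#' Transforms every cell by `x' = (x - min(x)) / (max(x) - min(x))` using the
#' fitted per-feature minima and maxima, so each feature of the fitting
#' matrix is mapped onto the interval `[0, 1]`. A constant feature
#' (`max == min`, a 0/0 in the formula) maps to 0 everywhere, which keeps the
#' output inside the range.
#'
#' @param data a [data_matrix]; every feature must be covered by `params`.
#' @param params a `minmax_params` object from [fit_minmax].
#' @return A [data_matrix] of the same shape.
#' @examples
#' d <- data_matrix(matrix(c(1, 3, 5), 3), row_ids = c("a", "b", "c"))
#' apply_minmax(d, fit_minmax(d))$values
#' @export
apply_minmax <- function(data, params) {
  stopifnot(inherits(data, "data_matrix"), inherits(params, "minmax_params"))
  missing_feat <- setdiff(data$feature_names, names(params$min))
  if (length(missing_feat) > 0L) {
    stop(sprintf("no scaling parameters for feature '%s'", missing_feat[1L]))
  }
  lo <- params$min[data$feature_names]
  hi <- params$max[data$feature_names]
  span <- hi - lo
  out <- sweep(data$values, 2L, lo, "-")
  out <- sweep(out, 2L, ifelse(span > 0, span, 1), "/")
  out[, span == 0] <- 0
  data_matrix(out, row_ids = data$row_ids, feature_names = data$feature_names)
}

#' Pair a normalized matrix (for clustering) with original values (for display)
#'
#' When normalization is used, row order is always given by clustering the
#' normalized values, but the document's heatmap can carry the original
#' values instead. This pairing states that contract: `cluster` is consumed
#' by the linkage, `display` fills the leaves' feature arrays, and both share
#' the same rows and features.
#'
#' @param normalized a [data_matrix] to cluster on.
#' @param original a [data_matrix] with identical `row_ids` and
#'   `feature_names`, to display.
#' @return An object of class `display_pairing` with elements `cluster` and
#'   `display`.
#' @export
pair_display_values <- function(normalized, original) {
  stopifnot(inherits(normalized, "data_matrix"),
            inherits(original, "data_matrix"))
  if (!identical(normalized$row_ids, original$row_ids)) {
    stop("row_ids of the normalized and original matrices differ")
  }
  if (!identical(normalized$feature_names, original$feature_names)) {
    stop("feature_names of the normalized and original matrices differ")
  }
  structure(list(cluster = normalized, display = original),
            class = "display_pairing")
}
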