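# Synthetic data generation: Gaussian blobs with controllable separation,
# a two-column metadata table (one numeric, one categorical) and full
# random-but-valid documents. All generators are pure functions of their
# seed and never touch the global random state.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate Gaussian cluster blobs
#'
#' Draws `n_clusters` random centres and rescales them so that the smallest
#' pairwise centre distance equals `separation * noise_sd`; rows are then
#' sampled around their centre with isotropic Gaussian noise of standard
#' deviation `noise_sd`. `separation` is therefore the centre spacing in
#' units of the noise — 0 gives overlapping clusters whose labels are
#' uninformative, large values give blobs that hierarchical clustering must
#' recover exactly. Rows are assigned to clusters as evenly as possible and
#' named `r0, r1, ...`.
#'
#' @param n_rows number of rows (data points).
#' @param n_features number of features.
#' @param n_clusters number of blobs, `<= n_rows`.
#' @param separation non-negative centre spacing in noise-sd units.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed; the output is a pure function of it.
#' @return List with `data` (a [data_matrix]) and `labels` (integer vector
#'   of true cluster labels).
#' @export
make_blobs <- function(n_rows, n_features = 5L, n_clusters = 3L,
                       separation = 6, noise_sd = 1, seed = 1L) {
  if (n_clusters > n_rows) stop("n_clusters must not exceed n_rows")
  if (separation < 0) stop("separation must be non-negative")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  with_seed(seed, {
    centres <- matrix(stats::rnorm(n_clusters * n_features),
                      nrow = n_clusters)
    if (n_clusters > 1L) {
      dmin <- min(stats::dist(centres))
      centres <- if (dmin > 0) centres * (separation * noise_sd / dmin)
                 else centres * 0
    }
    labels <- sort(rep_len(seq_len(n_clusters), n_rows))
    vals <- centres[labels, , drop = FALSE] +
      matrix(stats::rnorm(n_rows * n_features, sd = noise_sd), nrow = n_rows)
    list(data = data_matrix(vals, row_ids = paste0("r", seq_len(n_rows) - 1L)),
         labels = labels)
  })
}

#' Generate a two-column metadata table
#'
#' One numeric column (`Numeric`, uniform on `[0, 1]`) and one categorical
#' column (`Categoric`, labels `"positive"`/`"negative"`), deterministic per
#' seed.
#'
#' @param row_ids character vector of row IDs (non-empty).
#' @param seed integer seed.
#' @return A [metadata_table] with feature names `Numeric` and `Categoric`.
#' @export
make_metadata <- function(row_ids, seed = 1L) {
  row_ids <- as.character(row_ids)
  if (length(row_ids) == 0L) stop("row_ids must be non-empty")
  with_seed(seed, {
    metadata_table(
      data.frame(Numeric = stats::runif(length(row_ids)),
                 Categoric = sample(c("positive", "negative"),
                                    length(row_ids), replace = TRUE),
                 stringsAsFactors = FALSE),
      row_ids = row_ids,
      feature_names = c("Numeric", "Categoric"))
  })
}

#' Generate a random valid heatmap document
#'
#' Runs the full pipeline (blob generation, optional metadata, optional
#' normalization, optional compression, clustering, document assembly) and
#' returns the resulting document, which always passes
#' [validate_document].
#'
#' @inheritParams make_blobs
#' @param axis `"row"` or `"both"`.
#' @param normalize,write_original,compress,compress_stat,linkage,distance
#'   pipeline options as in [run_config].
#' @param with_metadata attach a generated metadata table.
#' @return A `heatmap_document`.
#' @export
make_document <- function(n_rows = 10L, n_features = 4L, n_clusters = 3L,
                          separation = 6, noise_sd = 1, seed = 1L,
                          axis = "row", normalize = FALSE,
                          write_original = FALSE, compress = NULL,
                          compress_stat = "mean", with_metadata = TRUE,
                          linkage = "ward", distance = "euclidean") {
  blobs <- make_blobs(n_rows, n_features, n_clusters, separation, noise_sd,
                      seed)
  meta <- if (with_metadata) make_metadata(blobs$data$row_ids, seed + 1L)
          else NULL
  cfg <- run_config(axis = axis, normalize = normalize,
                    write_original = write_original, compress = compress,
                    compress_stat = compress_stat, linkage = linkage,
                    distance = distance)
  api_run(cfg, blobs$data, meta)
}
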