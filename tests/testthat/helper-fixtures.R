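# Shared helpers: small deterministic inputs built in code.

random_matrix <- function(n, m, seed) {
  make_blobs(n, m, n_clusters = 1L, separation = 0, seed = seed)$data
}

one_d_matrix <- function(values, ids = paste0("p", seq_along(values))) {
  data_matrix(matrix(values, ncol = 1L), row_ids = ids)
}

# a tiny hand-checkable document: two leaves under one root at height 3.32
tiny_document <- function(metadata = TRUE) {
  merges <- dendroheat:::new_merge_sequence(0L, 1L, 3.32, 2L, 2L)
  tree <- build_tree(merges,
                     leaf_objects = list(c("object_1", "object_2"), "object_3"),
                     leaf_features = list(c(1.4, 3.5, 5.1), c(2.0, 3.0, 4.0)))
  meta <- if (metadata) {
    metadata_table(data.frame(Numeric = c(0.03, 0.02, 0.05),
                              Categoric = c("positive", "positive", "negative"),
                              stringsAsFactors = FALSE),
                   row_ids = c("object_1", "object_2", "object_3"),
                   feature_names = c("Numeric", "Categoric"))
  } else NULL
  build_document(tree, metadata = meta, feature_names = c("f1", "f2", "f3"))
}

expect_same_hierarchy <- function(a, b, tol = 1e-9) {
  expect_true(dendroheat:::same_hierarchy(a, b, tol))
}
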