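test_that("cutting into k groups undoes the last k-1 merges", {
  d <- one_d_matrix(c(0, 0.1, 10))
  m <- compute_linkage(d, "row", "ward")
  g <- cut_to_k(m, 2)
  expect_equal(g$groups, list(c(1L, 2L), 3L))

  n <- 7
  dm <- random_matrix(n, 3, 9)
  mm <- compute_linkage(dm, "row", "average")
  expect_equal(cut_to_k(mm, n)$groups, as.list(seq_len(n)))
  # k = 2 gives the two children of the root
  g2 <- cut_to_k(mm, 2)
  tree <- build_tree(mm, as.list(dm$row_ids),
                     lapply(seq_len(n), function(i) dm$values[i, ]))
  root <- tree$nodes[[tree$root_id]]
  kids <- lapply(c(root$left_child, root$right_child), function(id) {
    sort(match(objects_under(tree, id)$object_ids, dm$row_ids))
  })
  expect_setequal(lapply(g2$groups, sort), kids)
  expect_error(cut_to_k(mm, 1), "k must satisfy")
  expect_error(cut_to_k(mm, n + 1), "k must satisfy")
})

test_that("group aggregation computes mean/median and conserves objects", {
  d <- one_d_matrix(c(1, 2, 9), ids = c("a", "b", "c"))
  g <- structure(list(groups = list(1:3), n_rows = 3L), class = "row_grouping")
  expect_equal(unname(aggregate_rows(d, g, "mean")$data$values[1, 1]), 4)
  expect_equal(unname(aggregate_rows(d, g, "median")$data$values[1, 1]), 2)

  for (seed in 1:6) {
    n <- 9 + seed
    dm <- random_matrix(n, 4, 70 + seed)
    m <- compute_linkage(dm, "row", "ward")
    k <- sample(2:(n - 1), 1)
    gg <- cut_to_k(m, k)
    agg <- aggregate_rows(dm, gg, "mean")
    expect_equal(length(agg$objects), k)
    expect_setequal(unlist(agg$objects), dm$row_ids)
    expect_equal(sum(lengths(gg$groups)), n)
    # singleton groups pass their row through unchanged
    singles <- which(lengths(gg$groups) == 1L)
    for (s in singles) {
      expect_equal(unname(agg$data$values[s, ]),
                   unname(dm$values[gg$groups[[s]], ]))
    }
  }
})

test_that("metadata aggregation follows stat and modal-label rules", {
  meta <- metadata_table(data.frame(Ki = c(0.03, 0.02, 0.10),
                                    cls = c("positive", "positive", "negative"),
                                    stringsAsFactors = FALSE),
                         row_ids = c("a", "b", "c"))
  g <- structure(list(groups = list(1:2, 3L), n_rows = 3L),
                 class = "row_grouping")
  r <- aggregate_metadata(meta, g, "mean")
  expect_equal(r$values$Ki, c(0.025, 0.10))
  expect_identical(r$values$cls, c("positive", "negative"))

  tie <- metadata_table(data.frame(x = c("b", "a"), stringsAsFactors = FALSE),
                        row_ids = c("r1", "r2"))
  g2 <- structure(list(groups = list(1:2), n_rows = 2L),
                  class = "row_grouping")
  expect_identical(aggregate_metadata(tie, g2)$values$x, "a")
})

test_that("k = n reduction re-clusters to the original merge heights", {
  d <- random_matrix(9, 3, 33)
  m <- compute_linkage(d, "row", "ward")
  g <- cut_to_k(m, 9)
  red <- aggregate_rows(d, g, "mean")
  m2 <- compute_linkage(red$data, "row", "ward")
  expect_equal(sort(m2$height), sort(m$height))
})

test_that("compressed pipelines emit valid documents with conserved objects", {
  for (k in c(2, 4, 7)) {
    doc <- make_document(12, 4, 3, separation = 5, seed = 40 + k,
                         compress = k, normalize = TRUE)
    expect_length(validate_document(doc), 0)
    leaves <- leaf_order(doc$data$nodes)
    expect_length(leaves, k)
    objs <- unlist(lapply(leaves, function(id) doc$data$nodes$nodes[[id]]$objects))
    expect_setequal(objs, paste0("r", 0:11))
    expect_equal(anyDuplicated(objs), 0L)
  }
})
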