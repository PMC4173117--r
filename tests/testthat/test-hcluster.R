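test_that("single linkage on 1-D points merges at gap distances", {
  d <- one_d_matrix(c(0, 1, 10))
  m <- compute_linkage(d, "row", "single", "euclidean")
  expect_equal(m$height, c(1, 9))
  expect_equal(m$left, c(0L, 3L))   # {p1,p2} first, then p3 joins it
  expect_equal(m$right, c(1L, 2L))
  expect_equal(m$size, c(2L, 3L))
})

test_that("two identical rows merge at height zero", {
  d <- data_matrix(rbind(c(1, 2), c(1, 2)), row_ids = c("a", "b"))
  m <- compute_linkage(d, "row", "average")
  expect_equal(m$height, 0)
})

test_that("ward merges two singletons at their euclidean distance", {
  d <- data_matrix(rbind(c(0, 0), c(3, 4)), row_ids = c("a", "b"))
  m <- compute_linkage(d, "row", "ward")
  expect_equal(m$height, 5)
  mn <- naive_linkage(d, "row", "ward")
  expect_equal(mn$height, 5)
})

test_that("column axis clusters the transposed matrix", {
  d <- random_matrix(6, 4, 31)
  mc <- compute_linkage(d, "column", "average")
  dt <- data_matrix(t(d$values), row_ids = d$feature_names,
                    feature_names = d$row_ids)
  mr <- compute_linkage(dt, "row", "average")
  expect_equal(mc$height, mr$height)
  expect_identical(n_leaves(mc), 4L)
})

test_that("unsupported inputs are rejected", {
  d <- random_matrix(5, 3, 1)
  expect_error(compute_linkage(d, "row", "fancy"), "arg")
  expect_error(compute_linkage(d, "row", "ward", "chebyshev"), "arg")
  expect_error(compute_linkage(one_d_matrix(1), "row"), "at least 2")
  flat <- data_matrix(rbind(c(1, 1, 1), c(1, 2, 3)), row_ids = c("a", "b"))
  expect_error(compute_linkage(flat, "row", "average", "correlation"),
               "constant")
})

test_that("naive agglomeration handles forced and degenerate cases", {
  d2 <- data_matrix(rbind(c(0, 0), c(1, 1)), row_ids = c("a", "b"))
  m <- naive_linkage(d2, "row", "complete")
  expect_equal(nrow(m), 1L)
  expect_equal(m$height, sqrt(2))

  # duplicated points merge first at height zero, lexicographically
  dd <- one_d_matrix(c(5, 0, 5, 0))
  mn <- naive_linkage(dd, "row", "single")
  expect_equal(mn$height[1:2], c(0, 0))
  expect_equal(c(mn$left[1], mn$right[1]), c(0L, 2L))
  expect_equal(c(mn$left[2], mn$right[2]), c(1L, 3L))
})

test_that("hclust-backed linkage equals the naive oracle on random data", {
  cases <- expand.grid(seed = 1:6,
                       linkage = c("single", "complete", "average", "ward",
                                   "weighted", "centroid", "median"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    d <- make_blobs(20, 5, 2, separation = 2, seed = 100 + cases$seed[i])$data
    a <- suppressWarnings(compute_linkage(d, "row", cases$linkage[i]))
    b <- suppressWarnings(naive_linkage(d, "row", cases$linkage[i]))
    expect_same_hierarchy(a, b)
  }
  # non-euclidean metrics for the graph-based linkages
  for (metric in c("manhattan", "correlation", "cosine")) {
    d <- make_blobs(15, 4, 2, separation = 2, seed = 7)$data
    for (lk in c("single", "complete", "average", "weighted")) {
      expect_same_hierarchy(compute_linkage(d, "row", lk, metric),
                            naive_linkage(d, "row", lk, metric))
    }
  }
})

test_that("monotone linkages produce non-decreasing merge heights", {
  for (seed in 1:5) {
    d <- make_blobs(18, 3, 3, separation = 3, seed = seed)$data
    for (lk in c("single", "complete", "average", "ward")) {
      m <- compute_linkage(d, "row", lk)
      expect_true(all(diff(m$height) >= -1e-12))
    }
  }
})

test_that("hamming distance counts mismatching coordinate fractions", {
  d <- data_matrix(rbind(c(0, 1, 1, 0), c(0, 1, 0, 1), c(0, 1, 1, 0)),
                   row_ids = c("a", "b", "c"))
  D <- as.matrix(dendroheat:::pairwise_distance(d$values, "hamming"))
  expect_equal(D[1, 2], 0.5)
  expect_equal(D[1, 3], 0)
})
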