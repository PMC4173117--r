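test_that("metadata are keyed by leaf IDs through each leaf's objects", {
  doc <- tiny_document()
  expect_identical(names(doc$metadata$nodes), c("leaf_0", "leaf_1"))
  # leaf_0 compresses object_1+object_2: mean Ki, modal class
  expect_equal(doc$metadata$nodes[["leaf_0"]][[1]], 0.025)
  expect_identical(doc$metadata$nodes[["leaf_0"]][[2]], "positive")
  # leaf_1 holds a single object: values verbatim
  expect_equal(doc$metadata$nodes[["leaf_1"]][[1]], 0.05)
  expect_identical(doc$metadata$nodes[["leaf_1"]][[2]], "negative")
})

test_that("a column tree permutes feature names and every leaf's features", {
  doc_plain <- make_document(8, 3, 2, separation = 4, seed = 5, axis = "row",
                             with_metadata = FALSE)
  doc_both <- make_document(8, 3, 2, separation = 4, seed = 5, axis = "both",
                            with_metadata = FALSE)
  ord <- leaf_order(doc_both$column_dendrogram)
  perm <- as.integer(sub("^leaf_", "", ord)) + 1L
  expect_identical(doc_both$data$feature_names,
                   doc_plain$data$feature_names[perm])
  for (id in leaf_order(doc_both$data$nodes)) {
    expect_equal(doc_both$data$nodes$nodes[[id]]$features,
                 doc_plain$data$nodes$nodes[[id]]$features[perm])
  }
})

test_that("serialization emits the fixed key vocabulary and a parentless root", {
  doc <- tiny_document()
  js <- serialize_document(doc)
  x <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  leaf <- x$data$nodes$leaf_0
  expect_identical(names(leaf),
                   c("count", "distance", "features", "parent", "objects"))
  expect_equal(leaf$distance, 0)
  expect_equal(leaf$count, 1)
  root <- x$data$nodes$node_0
  expect_identical(names(root),
                   c("count", "distance", "left_child", "right_child"))
  expect_false("parent" %in% names(root))
  expect_equal(root$distance, 3.32)
  expect_identical(unlist(x$metadata$feature_names), c("Numeric", "Categoric"))
  # distance 0 must serialize as the bare number 0
  expect_match(js, "\"distance\":0[,}]")
})

test_that("numbers survive serialization at full precision", {
  merges <- dendroheat:::new_merge_sequence(0L, 1L, pi, 2L, 2L)
  tree <- build_tree(merges, list("a", "b"),
                     list(1 / 3, 0.1234567890123456))
  doc <- build_document(tree, feature_names = "f")
  got <- parse_document(serialize_document(doc))
  expect_identical(got$data$nodes$nodes[["node_0"]]$distance, pi)
  expect_identical(got$data$nodes$nodes[["leaf_0"]]$features, 1 / 3)
  # and the digits option rounds
  js <- serialize_document(doc, digits = 3)
  expect_equal(parse_document(js)$data$nodes$nodes[["node_0"]]$distance, 3.14)
})

test_that("parsing recovers the worked-format example", {
  js <- '{
    "data": {
      "feature_names": ["f1", "f2", "f3"],
      "nodes": {
        "leaf_1": {"count": 1, "distance": 0,
                   "features": [1.4, 3.5, 5.1], "parent": "node_1",
                   "objects": ["object_1", "object_2"]},
        "leaf_2": {"count": 1, "distance": 0,
                   "features": [2.0, 3.0, 4.0], "parent": "node_1",
                   "objects": ["object_3"]},
        "node_1": {"count": 2, "distance": 3.32,
                   "left_child": "leaf_1", "right_child": "leaf_2"}
      }
    }
  }'
  doc <- parse_document(js)
  expect_length(validate_document(doc), 0)
  leaf <- doc$data$nodes$nodes[["leaf_1"]]
  expect_equal(leaf$count, 1)
  expect_equal(leaf$distance, 0)
  expect_equal(leaf$features, c(1.4, 3.5, 5.1))
  expect_identical(leaf$parent, "node_1")
  expect_identical(leaf$objects, c("object_1", "object_2"))
  node <- doc$data$nodes$nodes[["node_1"]]
  expect_equal(node$distance, 3.32)
  expect_identical(node$left_child, "leaf_1")
  expect_identical(node$right_child, "leaf_2")
  expect_identical(doc$data$nodes$root_id, "node_1")
})

test_that("parse errors name the problem", {
  expect_error(parse_document("{}"), "data block missing")
  expect_error(parse_document('{"data": {"nodes": {
    "leaf_0": {"distance": 0, "features": [1], "objects": ["a"]}}}}'),
    "node 'leaf_0' is missing mandatory key 'count'")
  expect_error(parse_document("{not json"), "lexical|parse|invalid")
})

test_that("unknown node keys survive a round trip", {
  js <- serialize_document(tiny_document(metadata = FALSE))
  x <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  x$data$nodes$leaf_0$custom_tag <- "kept"
  js2 <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE))
  doc <- parse_document(js2)
  out <- serialize_document(doc)
  expect_match(out, "\"custom_tag\":\"kept\"", fixed = TRUE)
})

test_that("serialize/parse round-trips random documents across all options", {
  grid <- expand.grid(axis = c("row", "both"), normalize = c(FALSE, TRUE),
                      compress = c(NA, 4), meta = c(FALSE, TRUE),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    doc <- make_document(9, 3, 2, separation = 3, seed = 200 + i,
                         axis = grid$axis[i], normalize = grid$normalize[i],
                         compress = if (is.na(grid$compress[i])) NULL else grid$compress[i],
                         with_metadata = grid$meta[i])
    js <- serialize_document(doc)
    again <- serialize_document(parse_document(js))
    expect_identical(again, js)
  }
})

test_that("the validator reports structural violations precisely", {
  doc <- tiny_document()
  expect_length(validate_document(doc), 0)

  bad <- doc
  bad$data$nodes$nodes[["node_0"]]$count <- 5L
  v <- validate_document(bad)
  expect_match(v, "count 5 != sum of children counts 2", all = FALSE)

  two_roots <- doc
  two_roots$data$nodes$nodes[["leaf_1"]]$parent <- NULL
  expect_match(validate_document(two_roots), "multiple roots", all = FALSE)

  dup <- doc
  dup$data$nodes$nodes[["leaf_1"]]$objects <- "object_1"
  expect_match(validate_document(dup), "more than one leaf", all = FALSE)

  stray <- doc
  names(stray$metadata$nodes)[2] <- "leaf_9"
  expect_match(validate_document(stray), "not a data leaf", all = FALSE)

  neg <- doc
  neg$data$nodes$nodes[["node_0"]]$distance <- -1
  expect_match(validate_document(neg), "negative distance", all = FALSE)

  expect_error(serialize_document(bad), "refusing to serialize")
})
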