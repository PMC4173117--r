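test_that("leaf order is the left-first depth-first traversal", {
  doc <- tiny_document()
  expect_identical(leaf_order(doc$data$nodes), c("leaf_0", "leaf_1"))
  for (seed in 1:5) {
    tree <- make_document(10, 3, 2, separation = 3, seed = seed,
                          with_metadata = FALSE)$data$nodes
    ord <- leaf_order(tree)
    expect_length(ord, tree$nodes[[tree$root_id]]$count)
    # reversing every left/right pair reverses the order
    rev_tree <- tree
    for (id in names(rev_tree$nodes)) {
      nd <- rev_tree$nodes[[id]]
      if (!is.null(nd$left_child)) {
        rev_tree$nodes[[id]]$left_child <- nd$right_child
        rev_tree$nodes[[id]]$right_child <- nd$left_child
      }
    }
    expect_identical(leaf_order(rev_tree), rev(ord))
  }
})

test_that("node selection returns the leaves below and their objects", {
  doc <- tiny_document()
  tree <- doc$data$nodes
  sel <- objects_under(tree, "leaf_0")
  expect_identical(sel$object_ids, c("object_1", "object_2"))
  root_sel <- objects_under(tree, tree$root_id)
  expect_identical(root_sel$object_ids,
                   c("object_1", "object_2", "object_3"))
  expect_error(objects_under(tree, "node_99"), "unknown node")

  big <- make_document(12, 4, 3, separation = 4, seed = 3,
                       with_metadata = FALSE)$data$nodes
  for (id in names(big$nodes)) {
    nd <- big$nodes[[id]]
    if (is.null(nd$left_child)) next
    l <- objects_under(big, nd$left_child)$object_ids
    r <- objects_under(big, nd$right_child)$object_ids
    expect_length(intersect(l, r), 0)
    expect_identical(objects_under(big, id)$object_ids, c(l, r))
  }
})

test_that("object queries find the holding rows in display order", {
  doc <- make_document(10, 3, 2, separation = 4, seed = 9, compress = 4,
                       with_metadata = FALSE)
  tree <- doc$data$nodes
  ord <- leaf_order(tree)
  expect_identical(rows_for_objects(doc, character(0))$leaf_ids, character(0))
  all_objs <- unlist(lapply(ord, function(id) tree$nodes[[id]]$objects))
  expect_identical(rows_for_objects(doc, all_objs)$leaf_ids, ord)
  one <- rows_for_objects(doc, "r3")
  expect_length(one$leaf_ids, 1)
  expect_true("r3" %in% tree$nodes[[one$leaf_ids]]$objects)
  res <- rows_for_objects(doc, c("r0", "nope"))
  expect_identical(res$unknown, "nope")
})

test_that("cut_at yields subtree roots partitioning the leaves", {
  tree <- make_document(14, 4, 3, separation = 4, seed = 11,
                        with_metadata = FALSE)$data$nodes
  expect_identical(cut_at(tree, 1), tree$root_id)
  all_leaves <- leaf_order(tree)
  expect_identical(sort(cut_at(tree, length(all_leaves))), sort(all_leaves))
  for (k in 2:6) {
    roots <- cut_at(tree, k)
    expect_length(roots, k)
    leaf_sets <- lapply(roots, function(id) objects_under(tree, id)$leaf_ids)
    expect_identical(unlist(leaf_sets), all_leaves) # disjoint, display order
    # selection objects form a disjoint union of the root's objects
    objs <- lapply(roots, function(id) objects_under(tree, id)$object_ids)
    expect_setequal(unlist(objs),
                    objects_under(tree, tree$root_id)$object_ids)
    expect_equal(anyDuplicated(unlist(objs)), 0L)
  }
  expect_error(cut_at(tree, 0), "k must satisfy")
})
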