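test_that("voxel linearization is x-fastest and invertible", {
  dims <- c(10, 10, 10)
  expect_identical(voxel_id(c(2, 3, 4), dims), 432L)
  expect_identical(voxel_coords(432L, dims),
                   cbind(x = 2L, y = 3L, z = 4L))
  set.seed(5)
  ids <- sample(0:999, 100)
  expect_identical(voxel_id(voxel_coords(ids, dims), dims), as.integer(ids))
  expect_error(voxel_id(c(10, 0, 0), dims), "bounds")
  expect_error(voxel_coords(1000L, dims), "bounds")
})

test_that("point strokes voxelize to the exact Euclidean ball", {
  # radius 0: just the voxel itself
  expect_identical(
    stroke_to_voxels(stroke(c(2, 3, 4), radius = 0), c(10, 10, 10)), 432L)
  # unit ball on the integer grid: center + 6 face neighbors
  ids <- stroke_to_voxels(stroke(c(5, 5, 5), radius = 1), c(11, 11, 11))
  expect_length(ids, 7L)
  # clipped at the corner: center + 3 in-bounds face neighbors
  ids0 <- stroke_to_voxels(stroke(c(0, 0, 0), radius = 1), c(11, 11, 11))
  expect_identical(ids0,
                   sort(as.integer(oracle_stroke_voxels(
                     matrix(c(0, 0, 0), 1), 1, c(11, 11, 11)))))
  expect_length(ids0, 4L)
  expect_error(stroke(matrix(numeric(0), 0, 3)), "point")
})

test_that("stroke voxelization matches the brute-force distance oracle", {
  dims <- c(12, 14, 9)
  set.seed(42)
  for (i in 1:4) {
    npts <- sample(1:4, 1)
    pts <- cbind(runif(npts, 0, dims[1] - 1), runif(npts, 0, dims[2] - 1),
                 runif(npts, 0, dims[3] - 1))
    r <- runif(1, 0.5, 2.5)
    got <- stroke_to_voxels(stroke(pts, radius = r), dims)
    want <- sort(oracle_stroke_voxels(pts, r, dims))
    expect_identical(got, as.integer(want))
  }
})

test_that("later iterations update tags and erasure keeps history", {
  ann <- annotation_set(c(10, 10, 10))
  ann <- add_tags(ann, c(1, 2, 3), "positive", 1)
  ann <- add_tags(ann, 2, "negative", 2)
  live <- live_tags(ann)
  expect_identical(live$label[match(c(1, 3), live$voxel_id)],
                   c("positive", "positive"))
  expect_identical(live$label[live$voxel_id == 2], "negative")

  # erase all, then re-tag at a later round: the newest event wins
  ann <- erase_tags(ann, c(1, 2, 3))
  expect_equal(nrow(live_tags(ann)), 0L)
  expect_gt(nrow(ann$events), 0L)  # history retained
  ann <- add_tags(ann, 2, "positive", 3)
  expect_identical(live_tags(ann)$label, "positive")
  expect_identical(live_tags(ann)$iteration, 3L)

  # erasing an untagged voxel is a no-op
  before <- live_tags(ann)
  expect_identical(live_tags(erase_tags(ann, 999)), before)

  # empty tag set leaves the annotation unchanged
  expect_identical(live_tags(add_tags(ann, integer(0), "positive")), before)
})

test_that("bounds, iteration ordering and same-round conflicts are rejected", {
  ann <- annotation_set(c(4, 4, 4))
  expect_error(add_tags(ann, 64, "positive", 1), "bounds")  # nx*ny*nz
  ann <- add_tags(ann, 1, "positive", 2)
  expect_error(add_tags(ann, 2, "negative", 1), "iteration")
  expect_error(add_tags(ann, 1, "negative", 2), "both labels")
})

test_that("event-log replay is deterministic", {
  build <- function() {
    ann <- annotation_set(c(8, 8, 8))
    ann <- add_tags(ann, c(1, 5, 9), "positive", 1)
    ann <- add_tags(ann, c(20, 30), "negative", 1)
    ann <- erase_tags(ann, c(5, 20))
    ann <- add_tags(ann, c(5, 40), "negative", 2)
    ann
  }
  expect_identical(live_tags(build()), live_tags(build()))
})

test_that("training_table joins live tags with features in voxel order", {
  set.seed(3)
  v <- array(runif(16^3, 0, 100), c(16, 16, 16))
  ann <- annotation_set(c(16, 16, 16))
  pos <- sample(0:4095, 4); neg <- setdiff(sample(0:4095, 10), pos)[1:6]
  ann <- add_tags(ann, pos, "positive", 1)
  ann <- add_tags(ann, neg, "negative", 1)
  fm <- compute_features_at(v, live_tags(ann)$voxel_id)
  tt <- training_table(ann, fm)
  expect_equal(nrow(tt$x), 10L)
  expect_equal(sum(tt$y), 4L)
  expect_identical(tt$voxel_id, sort(c(pos, neg)))

  # re-tagging the same voxel at a later round keeps one row per voxel
  ann2 <- add_tags(ann, pos[1], "negative", 2)
  fm2 <- compute_features_at(v, live_tags(ann2)$voxel_id)
  tt2 <- training_table(ann2, fm2)
  expect_equal(nrow(tt2$x), 10L)
  expect_equal(sum(tt2$y), 3L)

  # missing feature rows are a schema error
  expect_error(training_table(ann, fm[-1, ]), "missing feature rows")

  # all tags erased: empty table with schema preserved, training refuses
  ann3 <- erase_tags(ann, live_tags(ann)$voxel_id)
  fm3 <- compute_features_at(v, integer(0))
  tt3 <- training_table(ann3, fm3)
  expect_equal(nrow(tt3$x), 0L)
  expect_equal(ncol(tt3$x), 56L)
  expect_error(train_classifier(classifier_spec("rfc"), tt3$x, tt3$y),
               "each class")
})
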