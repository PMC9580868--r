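test_that("TIFF round-trip preserves integer volumes bit-identically", {
  set.seed(7)
  v <- volume_stack(array(sample(0:65535, 10 * 10 * 5, replace = TRUE),
                          c(10, 10, 5)))
  path <- withr::local_tempfile(fileext = ".tif")
  write_volume(v, path)
  v2 <- read_volume(path)
  expect_identical(dim(v2$data), c(10L, 10L, 5L))
  expect_identical(v2$data, v$data)
})

test_that("a volume of zeros reads back with the right dims and values", {
  path <- withr::local_tempfile(fileext = ".tif")
  write_volume(array(0, c(10, 10, 5)), path)
  v <- read_volume(path)
  expect_identical(dim(v$data), c(10L, 10L, 5L))
  expect_true(all(v$data == 0))
})

test_that("probability maps are stored as 32-bit reals within 1e-7", {
  set.seed(11)
  pm <- probability_map(array(runif(6 * 7 * 8), c(6, 7, 8)))
  path <- withr::local_tempfile(fileext = ".tif")
  write_volume(pm, path)
  v2 <- read_volume(path)
  expect_lt(max(abs(v2$data - pm$data)), 1e-7)
})

test_that("NIfTI round-trip preserves data and a text file errors", {
  set.seed(13)
  v <- volume_stack(array(rnorm(16^3), c(16, 16, 16)), spacing = c(1, 2, 3))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  v2 <- read_volume(path)
  expect_equal(v2$data, v$data, tolerance = 0)
  txt <- withr::local_tempfile(fileext = ".tif")
  writeLines("this is not an image", txt)
  expect_error(read_volume(txt), "readable")
  expect_error(read_volume("no_such_file.tif"), "not found")
  expect_error(write_volume(v, "x.xyz"), "format")
})

test_that("voxel (0,0,0) maps to the first pixel of the first slice", {
  v <- array(0, c(4, 3, 2))
  v[1, 1, 1] <- 7     # corner marker at voxel (0,0,0)
  v[4, 1, 1] <- 3     # x-extreme marker
  path <- withr::local_tempfile(fileext = ".tif")
  write_volume(v, path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  expect_equal(pages[[1]][1, 1], 7)  # first row, first column of page 1
  expect_equal(pages[[1]][1, 4], 3)  # x runs along TIFF columns
  expect_identical(read_volume(path)$data, v * 1)
})

test_that("transfer functions validate, interpolate, and round-trip", {
  tf <- transfer_function(c(0, 1), c(0, 1), rbind(c(0, 0, 0), c(1, 1, 1)))
  path <- withr::local_tempfile(fileext = ".json")
  save_transfer_function(tf, path)
  tf2 <- load_transfer_function(path)
  expect_identical(tf2$x, tf$x)
  expect_identical(tf2$opacity, tf$opacity)
  expect_identical(tf2$rgb, tf$rgb)
  # midpoint of a linear ramp
  e <- tf_eval(tf, 0.5)
  expect_equal(e$opacity, 0.5)
  expect_equal(as.numeric(e$rgb), c(0.5, 0.5, 0.5))
  # non-increasing intensities rejected
  expect_error(transfer_function(c(0, 0.6, 0.4, 1), c(0, 0, 0, 0),
                                 matrix(0, 4, 3)), "increasing")
  expect_error(transfer_function(c(0.1, 1), c(0, 1), matrix(0, 2, 3)),
               "start at 0")
  writeLines("{not json", path)
  expect_error(load_transfer_function(path), "malformed")
})

test_that("annotation JSON round-trips live tags and validates labels", {
  ann <- annotation_set(c(10, 10, 10), volume = "demo")
  ann <- add_tags(ann, c(1, 2, 3), "positive", 1)
  ann <- add_tags(ann, c(7, 9), "negative", 1)
  path <- withr::local_tempfile(fileext = ".json")
  save_annotations(ann, path)
  ann2 <- load_annotations(path)
  expect_identical(live_tags(ann2), live_tags(ann))
  expect_equal(nrow(live_tags(ann2)), 5L)

  # empty set round-trips as a valid empty file
  empty <- annotation_set(c(5, 5, 5))
  save_annotations(empty, path)
  expect_equal(nrow(live_tags(load_annotations(path))), 0L)

  # label outside {positive, negative} rejected
  jsonlite::write_json(list(volume = "x", dims = c(5, 5, 5),
                            tags = list(list(id = 1, label = "maybe",
                                             iteration = 1))),
                       path, auto_unbox = TRUE)
  expect_error(load_annotations(path), "positive")

  # conflicting duplicate IDs rejected
  jsonlite::write_json(list(volume = "x", dims = c(5, 5, 5),
                            tags = list(
                              list(id = 1, label = "positive", iteration = 1),
                              list(id = 1, label = "negative", iteration = 1))),
                       path, auto_unbox = TRUE)
  expect_error(load_annotations(path), "conflicting")
})

test_that("randomized IO round-trips hold across seeds", {
  for (seed in 1:3) {
    set.seed(seed)
    dims <- sample(4:12, 3, replace = TRUE)
    v <- array(sample(0:255, prod(dims), replace = TRUE), dims)
    path <- withr::local_tempfile(fileext = ".tif")
    write_volume(v, path)
    expect_identical(read_volume(path)$data, v * 1)
    npath <- withr::local_tempfile(fileext = ".nii.gz")
    write_volume(v, npath)
    expect_equal(read_volume(npath)$data, v * 1, tolerance = 0)
  }
})
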