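test_that("probability maps stay in [0, 1] and match the sparse path at tagged voxels", {
  run <- fixture_rfc_run("blob_clean")
  expect_true(all(run$pm$data >= 0 & run$pm$data <= 1))
  # dense inference agrees with predict_proba on the tagged voxels' rows
  p_sparse <- predict_proba(run$model, run$tt$x)
  p_dense <- run$pm$data[run$tt$voxel_id + 1L]
  expect_equal(p_dense, p_sparse, tolerance = 1e-12)
})

test_that("blockwise inference equals monolithic inference", {
  set.seed(30)
  d <- separable_clusters(20, 56, seed = 30, shift = 2)
  colnames(d$x) <- feature_bank_default()$name
  m <- train_classifier(classifier_spec("rfc", seed = 0), d$x, d$y)
  v <- array(runif(16^3, -2, 5), c(16, 16, 16))
  mono <- infer_volume(m, v)
  tiled <- infer_volume(m, v, block_shape = c(11, 11, 11))
  expect_lt(max(abs(mono$data - tiled$data)), 1e-6)
})

test_that("schema mismatch between model and bank is rejected", {
  d <- separable_clusters(10, 3, seed = 31)
  m <- train_classifier(classifier_spec("rfc", seed = 0), d$x, d$y)
  expect_error(infer_volume(m, array(0, c(16, 16, 16))), "schema")
})

test_that("log transform floors at log(1e-12) and preserves order", {
  pm <- probability_map(array(c(1, 0, 0.5, 0.25, 1e-15, 0.75, runif(58)),
                              c(4, 4, 4)))
  lt <- log_transform(pm)
  expect_equal(lt[1], 0)
  expect_equal(lt[2], log(1e-12))
  expect_equal(lt[5], log(1e-12))  # tiny p is floored too
  expect_equal(lt[3], log(0.5))
  ord <- order(pm$data)
  expect_true(all(diff(lt[ord]) >= 0))
})

test_that("the overlay compositor honors the channel contract", {
  dims <- c(6, 6, 6)
  raw <- volume_stack(array(seq(0, 100, length.out = prod(dims)), dims))
  pm <- probability_map(array(0, dims))

  # probability 0 under the default colormap is pure blue
  e <- tf_eval(tf_probability(), c(0, 1, 0.5))
  expect_equal(e$rgb[1, ], c(0, 0, 1))  # p = 0 -> blue
  expect_equal(e$rgb[2, ], c(1, 0, 0))  # p = 1 -> red
  expect_equal(e$rgb[3, 2], 0)          # no green on the path

  # a fully transparent probability layer leaves the raw channel untouched
  clear <- transfer_function(c(0, 1), c(0, 0), rbind(c(0, 0, 1), c(1, 0, 0)))
  ov1 <- overlay(list(list(vol = raw, tf = tf_grayscale())))
  ov2 <- overlay(list(list(vol = raw, tf = tf_grayscale()),
                      list(vol = pm, tf = clear)))
  expect_equal(unclass(ov1), unclass(ov2), tolerance = 1e-12)

  # a single raw channel with the identity TF is a grayscale rendering
  nv <- (raw$data - min(raw$data)) / diff(range(raw$data))
  expect_equal(ov1[, , , 1], nv, tolerance = 1e-12)
  expect_equal(ov1[, , , 1], ov1[, , , 2])
  expect_equal(ov1[, , , 2], ov1[, , , 3])
  expect_true(all(ov1[, , , 4] == 1))

  # channel limit and dims checks
  five <- rep(list(list(vol = raw, tf = tf_grayscale())), 5)
  expect_error(overlay(five), "4 channels")
  expect_error(overlay(list(list(vol = raw, tf = tf_grayscale()),
                            list(vol = probability_map(array(0, c(5, 6, 6))),
                                 tf = tf_probability()))),
               "dims")
  # overlay TIFF export round-trips shape
  path <- withr::local_tempfile(fileext = ".tif")
  write_overlay(ov1, path)
  # libtiff flags the alpha plane as an extra sample when re-reading
  pages <- suppressWarnings(tiff::readTIFF(path, all = TRUE))
  expect_length(pages, 6L)
  expect_identical(dim(pages[[1]]), c(6L, 6L, 4L))
})

test_that("an empty correction round reproduces the previous model", {
  run <- fixture_rfc_run("blob_clean")
  ph <- fixture_phantom("blob_clean")
  out <- iterate(classifier_spec("rfc", seed = 0), run$ann, ph$volume,
                 new_tags = NULL)
  expect_identical(predict_proba(out$model, run$tt$x),
                   predict_proba(run$model, run$tt$x))
  # wrong iteration number is a validation error
  bad <- tibble::tibble(voxel_id = 0L, label = "negative", iteration = 7L)
  expect_error(iterate(classifier_spec("rfc", seed = 0), run$ann, ph$volume,
                       new_tags = bad), "iteration")
})
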