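test_that("the default bank has 56 uniquely named features led by PIXEL_VALUE", {
  bank <- feature_bank_default()
  expect_equal(nrow(bank), 56L)
  expect_identical(bank$name[1], "PIXEL_VALUE")
  expect_identical(bank$index[1], 0L)
  expect_false(anyDuplicated(bank$name) > 0)
  expect_setequal(unique(bank$kernel_size[-1]), c(3L, 5L, 7L, 9L, 11L))
  # bank spec JSON round-trip
  path <- withr::local_tempfile(fileext = ".json")
  write_feature_bank(bank, path)
  bank2 <- read_feature_bank(path)
  expect_identical(bank2$name, bank$name)
})

test_that("constant volumes give constant smoothers and zero differentials", {
  v <- array(3.5, c(14, 14, 14))
  fv <- compute_features_full(v)
  flat <- c("GAUSSIAN", "MEAN", "MEDIAN", "MINIMUM", "MAXIMUM")
  zero <- c("RANGE", "STDDEV", "GRADIENT_MAGNITUDE", "LAPLACIAN_OF_GAUSSIAN",
            "DIFFERENCE_OF_GAUSSIANS", "HESSIAN_MAX_EIGEN")
  for (k in c(3, 5, 7, 9, 11)) {
    for (f in flat)
      expect_equal(max(abs(fv[[paste0(f, "_k", k)]] - 3.5)), 0,
                   tolerance = 1e-12)
    for (f in zero)  # stddev's sqrt amplifies cancellation error to ~1e-7
      expect_lt(max(abs(fv[[paste0(f, "_k", k)]])), 1e-6)
  }
  expect_identical(fv$PIXEL_VALUE, v)
})

test_that("every filter matches brute-force neighborhood enumeration", {
  set.seed(3)
  v <- array(runif(9^3, 0, 255), c(9, 9, 9))
  bank <- feature_bank_default()
  # interior voxel, a face voxel, and a corner voxel (mirror path)
  probes <- rbind(c(4, 4, 4), c(0, 4, 4), c(8, 8, 8), c(2, 7, 1))
  ids <- voxel_id(probes, dim(v))
  fm <- compute_features_at(v, ids)
  for (j in seq_len(nrow(bank))) {
    kind <- bank$filter_kind[j]
    k <- ifelse(is.na(bank$kernel_size[j]), 1L, bank$kernel_size[j])
    for (i in seq_len(nrow(probes))) {
      want <- oracle_filter_at(v, probes[i, 1], probes[i, 2], probes[i, 3],
                               kind, k)
      expect_equal(fm[[bank$name[j]]][i], want, tolerance = 1e-6,
                   label = sprintf("%s at probe %d", bank$name[j], i))
    }
  }
})

test_that("mean_k3 at the center of a 5^3 volume is the 27-voxel average", {
  set.seed(3)
  v <- array(runif(5^3), c(5, 5, 5))
  fm <- compute_features_at(v, voxel_id(c(2, 2, 2), dim(v)))
  expect_equal(fm$MEAN_k3[1], mean(v[2:4, 2:4, 2:4]), tolerance = 1e-12)
})

test_that("a bright voxel propagates to face neighbors under maximum_k3", {
  v <- array(0, c(7, 7, 7)); v[4, 4, 4] <- 9
  fm <- compute_features_at(v, voxel_id(c(4, 3, 3), dim(v)))
  expect_equal(fm$MAXIMUM_k3[1], 9)
})

test_that("blockwise dense features equal the monolithic computation", {
  set.seed(8)
  v <- array(runif(16^3, 0, 255), c(16, 16, 16))
  mono <- compute_features_full(v)
  tiled <- compute_features_full(v, block_shape = c(8, 8, 8) + 3L)
  worst <- max(mapply(function(a, b) max(abs(a - b)), mono, tiled))
  expect_lt(worst, 1e-6)
  # block smaller than the largest kernel is rejected
  expect_error(compute_features_full(v, block_shape = c(8, 8, 8)),
               "block_shape")
})

test_that("dense features sampled at random voxels equal the sparse path", {
  set.seed(21)
  v <- array(runif(12^3, 0, 50), c(12, 12, 12))
  fv <- compute_features_full(v)
  ids <- sample(0:(12^3 - 1), 10)
  dense_rows <- feature_volumes_matrix(fv, ids)
  sparse_rows <- as.matrix(compute_features_at(v, ids)[, -1])
  expect_equal(unname(dense_rows), unname(sparse_rows), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(fv$PIXEL_VALUE, v)
})

test_that("feature responses are translation-equivariant in the interior", {
  set.seed(9)
  core <- array(runif(6^3, 0, 10), c(6, 6, 6))
  pad <- array(0, c(20, 20, 20))
  a <- pad; a[8:13, 8:13, 8:13] <- core
  b <- pad; b[9:14, 8:13, 8:13] <- core  # shifted by (1, 0, 0)
  fa <- compute_features_at(a, voxel_id(c(10, 10, 10), dim(a)))
  fb <- compute_features_at(b, voxel_id(c(11, 10, 10), dim(b)))
  expect_equal(as.matrix(fa[, -1]), as.matrix(fb[, -1]), tolerance = 1e-9)
})

test_that("minimum shrinks and maximum grows with kernel size", {
  set.seed(10)
  v <- array(runif(13^3, 0, 100), c(13, 13, 13))
  ids <- sample(0:(13^3 - 1), 25)
  fm <- compute_features_at(v, ids)
  for (i in seq_along(ids)) {
    mins <- sapply(c(3, 5, 7, 9, 11), function(k) fm[[paste0("MINIMUM_k", k)]][i])
    maxs <- sapply(c(3, 5, 7, 9, 11), function(k) fm[[paste0("MAXIMUM_k", k)]][i])
    expect_true(all(diff(mins) <= 1e-12))
    expect_true(all(diff(maxs) >= -1e-12))
  }
})

test_that("out-of-bounds voxel ids and bad bank specs are rejected", {
  v <- array(0, c(8, 8, 8))
  expect_error(compute_features_at(v, 8^3), "bounds")
  expect_error(feature_bank("gaussian", 4), "odd")
  expect_error(feature_bank("whirlpool", 3), "unknown filter kind")
})
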