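test_that("all five classifier kinds separate well-separated clusters", {
  d <- separable_clusters(50, 5, seed = 0)
  for (kind in c("rfc", "mlp", "xgb", "svm", "nbc")) {
    m <- train_classifier(classifier_spec(kind, seed = 0), d$x, d$y)
    p <- predict_proba(m, d$x)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(mean((p >= 0.5) == (d$y == 1)), 1,
                 label = paste(kind, "training accuracy"))
    # probe identical to a positive training point
    expect_gt(predict_proba(m, d$x[51, , drop = FALSE]), 0.5)
  }
})

test_that("degenerate training inputs are rejected", {
  d <- separable_clusters(10, 3, seed = 1)
  expect_error(train_classifier(classifier_spec("rfc"), d$x,
                                rep(1, nrow(d$x))), "each class")
  bad <- d$x; bad[1, 1] <- NaN
  expect_error(train_classifier(classifier_spec("rfc"), bad, d$y), "NaN")
})

test_that("training is deterministic for a fixed seed", {
  d <- separable_clusters(30, 8, seed = 2, shift = 1.5)
  set.seed(99)
  probe <- matrix(rnorm(20 * 8), 20, dimnames = list(NULL, colnames(d$x)))
  for (kind in c("rfc", "mlp", "xgb", "svm", "nbc")) {
    m1 <- train_classifier(classifier_spec(kind, seed = 7), d$x, d$y)
    m2 <- train_classifier(classifier_spec(kind, seed = 7), d$x, d$y)
    expect_identical(predict_proba(m1, probe), predict_proba(m2, probe),
                     label = paste(kind, "determinism"))
  }
})

test_that("schema mismatches are caught at predict time", {
  d <- separable_clusters(20, 6, seed = 3)
  m <- train_classifier(classifier_spec("rfc", seed = 0), d$x, d$y)
  expect_error(predict_proba(m, d$x[, 1:4]), "schema")
  xwrong <- d$x
  attr(xwrong, "spec_hash") <- "someone-else"
  expect_error(predict_proba(m, xwrong), "schema")
})

test_that("the strong learner stacks 4 weak probability columns onto the features", {
  d <- separable_clusters(25, 56, seed = 4, shift = 1)
  colnames(d$x) <- feature_bank_default()$name
  sl <- train_strong(d$x, d$y, seed = 0)
  expect_length(sl$weak, 4L)
  expect_setequal(names(sl$weak), c("rfc", "mlp", "svm", "nbc"))
  expect_equal(length(sl$meta$feature_names), 56L + 4L)
  expect_identical(sl$meta$spec$kind, "xgb")
  p <- predict_proba(sl, d$x)
  expect_true(all(p >= 0 & p <= 1))
  # stacking never hurts training accuracy on a separable fixture
  acc <- function(m) mean((predict_proba(m, d$x) >= 0.5) == (d$y == 1))
  for (w in sl$weak) expect_gte(mean((predict_proba(sl, d$x) >= 0.5) ==
                                       (d$y == 1)), acc(w))
  # meta schema enforced at predict time
  expect_error(predict_proba(sl, d$x[, 1:10]), "schema")
})

test_that("models round-trip through the archive format exactly", {
  d <- separable_clusters(30, 6, seed = 5)
  set.seed(1)
  probe <- matrix(rnorm(100 * 6), 100, dimnames = list(NULL, colnames(d$x)))
  path <- withr::local_tempfile(fileext = ".vxl")
  for (kind in c("rfc", "xgb", "nbc")) {
    m <- train_classifier(classifier_spec(kind, seed = 0), d$x, d$y)
    save_model(m, path)
    m2 <- load_model(path)
    expect_identical(predict_proba(m2, probe), predict_proba(m, probe))
  }
  sl <- train_strong(d$x, d$y, seed = 0)
  save_model(sl, path)
  expect_identical(predict_proba(load_model(path), probe),
                   predict_proba(sl, probe))
  # truncated archives are rejected
  txt <- readLines(path, warn = FALSE)
  writeLines(substr(paste(txt, collapse = ""), 1, 500), path)
  expect_error(load_model(path), "archive|blob|version")
})

test_that("impurity importance is normalized and finds the informative feature", {
  set.seed(6)
  n <- 120
  x <- matrix(rnorm(n * 8), n, dimnames = list(NULL, paste0("F", 1:8)))
  y <- as.integer(x[, 3] > 0)   # only F3 carries signal
  for (kind in c("rfc", "xgb")) {
    m <- train_classifier(classifier_spec(kind, seed = 0), x, y)
    imp <- feature_importance(m)
    expect_equal(sum(imp$importance), 100, tolerance = 1e-6)
    expect_true(all(imp$importance >= 0))
    expect_identical(imp$feature[1], "F3")
  }
  msvm <- train_classifier(classifier_spec("svm", seed = 0), x, y)
  expect_error(feature_importance(msvm), "not defined")
})

test_that("tidy and glance summarize models", {
  d <- separable_clusters(20, 4, seed = 7)
  m <- train_classifier(classifier_spec("rfc", seed = 0), d$x, d$y)
  expect_named(glance(m),
               c("kind", "n_features", "n_train", "n_positive",
                 "n_negative", "iteration", "seed"))
  td <- tidy(m)
  expect_true(all(c("feature", "importance") %in% names(td)))
})
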