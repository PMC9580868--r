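#' Classifier specification
#'
#' The pipeline trains five base classifier kinds on tagged-voxel
#' features: random forest (`"rfc"`), multi-layer perceptron (`"mlp"`),
#' gradient boosting (`"xgb"`), support vector machine (`"svm"`) and
#' Gaussian naive Bayes (`"nbc"`). Defaults are set for rapid learning on
#' small tagged sets and can be overridden through `hyperparameters`:
#'
#' * `rfc`: 100 trees, unlimited depth (`ntree`, `nodesize`)
#' * `xgb`: 100 rounds, depth 3, learning rate 0.1 (`nrounds`,
#'   `max_depth`, `eta`)
#' * `mlp`: one hidden layer of 32 units, 200 epochs, weight decay 1e-4
#'   (`size`, `maxit`, `decay`); inputs are standardized internally
#' * `svm`: radial-basis kernel with probability outputs (`cost`,
#'   `gamma`)
#' * `nbc`: Gaussian class-conditional densities; per-feature standard
#'   deviations are floored at a small fraction of the feature scale so
#'   constant features stay well-defined
#'
#' @param kind One of `"rfc"`, `"mlp"`, `"xgb"`, `"svm"`, `"nbc"`.
#' @param hyperparameters Named list overriding the defaults above.
#' @param seed Integer seed; recorded in the model and used for every
#'   stochastic step of training.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("rfc", "mlp", "xgb", "svm", "nbc"),
                            hyperparameters = list(), seed = 0L) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    rfc = list(ntree = 100L, nodesize = 1L),
    xgb = list(nrounds = 100L, max_depth = 3L, eta = 0.1),
    mlp = list(size = 32L, maxit = 200L, decay = 1e-4),
    svm = list(cost = 1, gamma = NULL),
    nbc = list())
  structure(list(kind = kind,
                 hyperparameters = utils::modifyList(defaults, hyperparameters),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

check_training_input <- function(x, y) {
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x)))
    stop("features contain NaN/Inf values", call. = FALSE)
  y <- as.integer(y)
  if (nrow(x) != length(y)) stop("x and y sizes differ", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training needs at least one sample of each class", call. = FALSE)
  list(x = x, y = y)
}

#' Train a base classifier
#'
#' Fits the classifier described by `spec` on a tagged-voxel training
#' table. Training is deterministic for a fixed seed. The model stores the
#' feature-schema fingerprint and refuses to predict on features with a
#' different schema.
#'
#' @param spec A [classifier_spec()].
#' @param x Numeric feature matrix (rows = tagged voxels); typically the
#'   `x` element of [training_table()].
#' @param y Binary response (1 = positive tag).
#' @param iteration Tagging round recorded in the model metadata.
#' @return An object of class `voxel_model`.
#' @export
train_classifier <- function(spec, x, y, iteration = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  inp <- check_training_input(x, y)
  x <- inp$x; y <- inp$y
  fingerprint <- attr(x, "spec_hash")
  if (is.null(fingerprint)) fingerprint <- rlang::hash(colnames(x))
  hp <- spec$hyperparameters
  set.seed(spec$seed)
  fit <- switch(spec$kind,
    rfc = randomForest::randomForest(
      x, factor(y, levels = c(0, 1)),
      ntree = hp$ntree, nodesize = hp$nodesize),
    xgb = fit_xgb(x, y, hp, spec$seed),
    mlp = fit_mlp(x, y, hp),
    svm = fit_svm(x, y, hp),
    nbc = fit_nbc(x, y))
  structure(list(spec = spec, fingerprint = fingerprint,
                 feature_names = colnames(x), fit = fit,
                 meta = list(n = nrow(x),
                             n_positive = sum(y == 1L),
                             n_negative = sum(y == 0L),
                             iteration = as.integer(iteration))),
            class = "voxel_model")
}

fit_xgb <- function(x, y, hp, seed) {
  dm <- xgboost::xgb.DMatrix(x, label = y)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                  eta = hp$eta, nthread = 1L, seed = seed),
    data = dm, nrounds = hp$nrounds)
  # keep the raw booster bytes so models survive serialize()/JSON archives
  list(raw = xgboost::xgb.save.raw(booster),
       feature_names = colnames(x))
}

fit_mlp <- function(x, y, hp) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  net <- nnet::nnet(xs, y, size = hp$size, maxit = hp$maxit,
                    decay = hp$decay, entropy = TRUE, trace = FALSE,
                    MaxNWts = 100000L)
  list(net = net, center = center, scale = scale)
}

fit_svm <- function(x, y, hp) {
  args <- list(x = x, y = factor(y, levels = c(0, 1)), kernel = "radial",
               cost = hp$cost, probability = TRUE)
  if (!is.null(hp$gamma)) args$gamma <- hp$gamma
  # zero-variance columns trip e1071's internal scaling; scale the rest
  args$scale <- apply(x, 2, stats::sd) > 1e-12
  do.call(e1071::svm, args)
}

fit_nbc <- function(x, y) {
  nb <- e1071::naiveBayes(x, factor(y, levels = c(0, 1)))
  floor_sd <- 1e-6 * max(apply(x, 2, stats::sd), 1e-6)
  nb$tables <- lapply(nb$tables, function(tb) {
    tb[, 2] <- pmax(tb[, 2], floor_sd)
    tb
  })
  nb
}

#' @export
print.voxel_model <- function(x, ...) {
  cat(sprintf("<voxel_model> %s, %d features, trained on %d tags (%d+/%d-), iteration %d\n",
              toupper(x$spec$kind), length(x$feature_names), x$meta$n,
              x$meta$n_positive, x$meta$n_negative, x$meta$iteration))
  invisible(x)
}

check_schema <- function(model, x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  fp <- attr(x, "spec_hash")
  if (ncol(x) != length(model$feature_names))
    stop("feature schema mismatch: model expects ",
         length(model$feature_names), " features, got ", ncol(x),
         call. = FALSE)
  if (!is.null(fp) && !identical(fp, model$fingerprint))
    stop("feature schema mismatch: fingerprint differs", call. = FALSE)
  colnames(x) <- model$feature_names
  x
}

#' Predict positive-class probabilities
#'
#' @param model A [train_classifier()] or [train_strong()] model.
#' @param x Numeric feature matrix with the model's schema.
#' @return Numeric vector of probabilities in `[0, 1]`, one per row; the
#'   negative-class probability is the complement.
#' @export
predict_proba <- function(model, x) {
  UseMethod("predict_proba")
}

#' @export
predict_proba.voxel_model <- function(model, x) {
  x <- check_schema(model, x)
  p <- switch(model$spec$kind,
    rfc = predict(model$fit, x, type = "prob")[, "1"],
    xgb = predict(xgboost::xgb.load.raw(model$fit$raw),
                  xgboost::xgb.DMatrix(x)),
    mlp = {
      xs <- sweep(sweep(x, 2, model$fit$center), 2, model$fit$scale, "/")
      as.numeric(predict(model$fit$net, xs))
    },
    svm = {
      pr <- attr(predict(model$fit, x, probability = TRUE), "probabilities")
      pr[, "1"]
    },
    nbc = predict(model$fit, x, type = "raw")[, "1"])
  unname(pmin(pmax(as.numeric(p), 0), 1))
}

# ---- strong learner -----------------------------------------------------

.weak_kinds <- c("rfc", "mlp", "svm", "nbc")

#' Train the stacked strong learner
#'
#' Trains the four weak classifiers (random forest, multi-layer
#' perceptron, SVM, naive Bayes), appends their predicted positive-class
#' probabilities on the training voxels to the feature matrix, and fits a
#' gradient-boosting meta classifier on the augmented matrix (base
#' features + 4 probability columns).
#'
#' By default the appended probabilities are the weak learners' in-sample
#' predictions: the goal of one-shot annotation is to annotate the data
#' being explored, so the usual out-of-fold precautions matter less. Set
#' `out_of_fold = TRUE` for 5-fold out-of-fold stacking probabilities.
#'
#' @param x Numeric feature matrix.
#' @param y Binary response (1 = positive).
#' @param seed Integer seed; the weak learners train on seeds derived from
#'   it.
#' @param hyperparameters Named list of per-kind overrides, e.g.
#'   `list(rfc = list(ntree = 200))`; `meta` overrides the meta booster.
#' @param out_of_fold Use out-of-fold weak probabilities (default FALSE).
#' @param iteration Tagging round recorded in metadata.
#' @return An object of class `strong_learner`.
#' @export
train_strong <- function(x, y, seed = 0L, hyperparameters = list(),
                         out_of_fold = FALSE, iteration = 1L) {
  inp <- check_training_input(x, y)
  xm <- inp$x; y <- inp$y
  fingerprint <- attr(x, "spec_hash")
  if (is.null(fingerprint)) fingerprint <- rlang::hash(colnames(xm))
  attr(xm, "spec_hash") <- fingerprint
  weak <- list()
  probs <- matrix(0, nrow(xm), length(.weak_kinds),
                  dimnames = list(NULL, paste0("WEAK_", toupper(.weak_kinds))))
  for (i in seq_along(.weak_kinds)) {
    kind <- .weak_kinds[i]
    spec <- classifier_spec(kind, hyperparameters[[kind]] %||% list(),
                            seed = seed + i)
    weak[[kind]] <- train_classifier(spec, xm, y, iteration = iteration)
    probs[, i] <- if (out_of_fold) {
      oof_probs(spec, xm, y, seed = seed + i)
    } else {
      predict_proba(weak[[kind]], xm)
    }
  }
  meta_x <- cbind(xm, probs)
  attr(meta_x, "spec_hash") <- rlang::hash(c(fingerprint, colnames(probs)))
  meta_spec <- classifier_spec("xgb", hyperparameters[["meta"]] %||% list(),
                               seed = seed)
  meta <- train_classifier(meta_spec, meta_x, y, iteration = iteration)
  structure(list(weak = weak, meta = meta, fingerprint = fingerprint,
                 feature_names = colnames(xm), out_of_fold = out_of_fold,
                 metadata = list(n = nrow(xm), n_positive = sum(y == 1L),
                                 n_negative = sum(y == 0L),
                                 iteration = as.integer(iteration),
                                 seed = as.integer(seed))),
            class = "strong_learner")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

oof_probs <- function(spec, x, y, seed, folds = 5L) {
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), length(y)))
  p <- numeric(length(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L) {
      p[!tr] <- mean(y[tr])
      next
    }
    m <- train_classifier(spec, x[tr, , drop = FALSE], y[tr])
    p[!tr] <- predict_proba(m, x[!tr, , drop = FALSE])
  }
  p
}

#' @export
print.strong_learner <- function(x, ...) {
  cat(sprintf("<strong_learner> XGB meta over %d weak learners (%s), %d base features\n",
              length(x$weak), paste(toupper(names(x$weak)), collapse = ", "),
              length(x$feature_names)))
  invisible(x)
}

#' @export
predict_proba.strong_learner <- function(model, x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != length(model$feature_names))
    stop("feature schema mismatch: strong learner expects ",
         length(model$feature_names), " base features, got ", ncol(x),
         call. = FALSE)
  fp <- attr(x, "spec_hash")
  if (!is.null(fp) && !identical(fp, model$fingerprint))
    stop("feature schema mismatch: fingerprint differs", call. = FALSE)
  colnames(x) <- model$feature_names
  attr(x, "spec_hash") <- model$fingerprint
  probs <- vapply(model$weak, function(w) predict_proba(w, x),
                  numeric(nrow(x)))
  if (nrow(x) == 1L) probs <- matrix(probs, nrow = 1L)
  colnames(probs) <- paste0("WEAK_", toupper(names(model$weak)))
  meta_x <- cbind(x, probs)
  attr(meta_x, "spec_hash") <- model$meta$fingerprint
  predict_proba(model$meta, meta_x)
}

# ---- persistence --------------------------------------------------------

.model_format_version <- 1L

#' Save / load a trained model
#'
#' Models are persisted as a self-describing archive: a JSON document
#' holding the schema (format version, kind, feature names, fingerprint,
#' training metadata) plus the fitted parameters as a base64-encoded
#' serialized blob. Round-trips reproduce predictions exactly.
#'
#' @param model A `voxel_model` or `strong_learner`.
#' @param path File path (conventionally `.vxl`).
#' @return `load_model` returns the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "voxel_model") || inherits(model, "strong_learner"))
  kind <- if (inherits(model, "strong_learner")) "strong" else model$spec$kind
  payload <- list(
    format_version = .model_format_version,
    kind = kind,
    feature_names = model$feature_names,
    fingerprint = model$fingerprint,
    blob = jsonlite::base64_enc(serialize(model, NULL, version = 2L)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- tryCatch(jsonlite::fromJSON(path),
                      error = function(e)
                        stop("unreadable model archive: ", path, call. = FALSE))
  if (is.null(payload$format_version) ||
      payload$format_version != .model_format_version)
    stop("model archive schema version mismatch", call. = FALSE)
  model <- tryCatch(unserialize(jsonlite::base64_dec(payload$blob)),
                    error = function(e)
                      stop("corrupt model blob in ", path, call. = FALSE))
  if (!identical(model$fingerprint, payload$fingerprint))
    stop("model archive fingerprint mismatch", call. = FALSE)
  model
}

# ---- importance ---------------------------------------------------------

#' Impurity-based feature importance
#'
#' For tree-ensemble models (random forest, gradient boosting) the
#' importance of a feature is its share of the total reduction of the
#' Gini / gain criterion across all splits, expressed in percent. The
#' percentages are non-negative and sum to 100. Other kinds (SVM, naive
#' Bayes, MLP) do not define an impurity importance and raise an error.
#' For a strong learner the meta booster's importance over the augmented
#' schema (base features + 4 weak-probability columns) is reported.
#'
#' @param model A `voxel_model` (rfc or xgb) or `strong_learner`.
#' @return Tibble with columns `feature` and `importance` (percent),
#'   sorted descending.
#' @export
feature_importance <- function(model) {
  if (inherits(model, "strong_learner"))
    return(feature_importance(model$meta))
  stopifnot(inherits(model, "voxel_model"))
  kind <- model$spec$kind
  raw <- switch(kind,
    rfc = {
      imp <- randomForest::importance(model$fit, type = 2)
      setNames(imp[, 1], rownames(imp))
    },
    xgb = {
      booster <- xgboost::xgb.load.raw(model$fit$raw)
      gi <- xgboost::xgb.importance(model = booster)
      v <- setNames(rep(0, length(model$feature_names)), model$feature_names)
      v[gi$Feature] <- gi$Gain
      v
    },
    stop("impurity-based importance is not defined for kind '", kind, "'",
         call. = FALSE))
  total <- sum(raw)
  pct <- if (total > 0) 100 * raw / total else raw * 0
  out <- tibble::tibble(feature = names(pct), importance = unname(pct))
  out[order(-out$importance), ]
}

# ---- broom-style methods ------------------------------------------------

#' @export
tidy.voxel_model <- function(x, ...) {
  if (x$spec$kind %in% c("rfc", "xgb")) feature_importance(x)
  else tibble::tibble(feature = x$feature_names)
}

#' @export
glance.voxel_model <- function(x, ...) {
  tibble::tibble(kind = x$spec$kind, n_features = length(x$feature_names),
                 n_train = x$meta$n, n_positive = x$meta$n_positive,
                 n_negative = x$meta$n_negative,
                 iteration = x$meta$iteration, seed = x$spec$seed)
}

#' @export
tidy.strong_learner <- function(x, ...) feature_importance(x)

#' @export
glance.strong_learner <- function(x, ...) {
  tibble::tibble(kind = "strong", n_weak = length(x$weak),
                 n_features = length(x$feature_names),
                 n_meta_features = length(x$meta$feature_names),
                 n_train = x$metadata$n, iteration = x$metadata$iteration,
                 seed = x$metadata$seed)
}

#' Plot a feature-importance ranking
#'
#' @param importance Tibble from [feature_importance()].
#' @param top_n Number of leading features to show.
#' @return A ggplot object.
#' @export
plot_importance <- function(importance, top_n = 11L) {
  df <- head(importance, top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$importance,
    y = stats::reorder(.data$feature, .data$importance))) +
    ggplot2::geom_col(fill = "#31688e") +
    ggplot2::labs(x = "impurity-based importance (%)", y = NULL) +
    ggplot2::theme_minimal()
}
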