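#' Classify every voxel of a volume
#'
#' Computes the dense feature bank (optionally blockwise) and applies the
#' model to every voxel, producing a probability map. Blockwise tiling
#' uses a mirror-padded halo and yields the same result as the monolithic
#' computation.
#'
#' @param model A `voxel_model` or `strong_learner`.
#' @param vol A [volume_stack()] (or 3D array).
#' @param bank The `feature_bank` used at training time.
#' @param block_shape Optional tile shape passed to
#'   [compute_features_full()].
#' @param chunk_rows Number of voxel rows classified per prediction call
#'   (memory knob only; does not change results).
#' @return A [probability_map()].
#' @export
infer_volume <- function(model, vol, bank = feature_bank_default(),
                         block_shape = NULL, chunk_rows = 100000L) {
  v <- as_vol_array(vol)
  if (!identical(bank_fingerprint(bank), model$fingerprint))
    stop("feature schema mismatch: model was trained on a different bank",
         call. = FALSE)
  fv <- compute_features_full(v, bank, block_shape = block_shape)
  m <- feature_volumes_matrix(fv)
  n <- nrow(m)
  p <- numeric(n)
  fp <- attr(m, "spec_hash")
  for (start in seq(1L, n, by = chunk_rows)) {
    idx <- start:min(start + chunk_rows - 1L, n)
    xm <- m[idx, , drop = FALSE]
    attr(xm, "spec_hash") <- fp
    p[idx] <- predict_proba(model, xm)
  }
  probability_map(array(p, dim(v)),
                  model_fingerprint = model$fingerprint)
}

#' Fuse raw and probability channels into an RGBA overlay
#'
#' Each channel (a raw volume or a probability map) is normalized, mapped
#' through its transfer function to per-voxel RGBA, and the channels are
#' fused back-to-front with the alpha "over" operator: the first channel
#' is the backdrop, later channels ride on top. Raw volumes are
#' normalized by their own (min, max); probability maps use the fixed
#' `[0, 1]` scale so the default probability colormap maps 0 to blue and
#' 1 to red.
#'
#' @param channels List of up to four `list(vol = , tf = )` entries, all
#'   with matching dims. A bare volume/probability map may be given
#'   instead of a list, in which case [tf_grayscale()] or
#'   [tf_probability()] is chosen by type.
#' @return An object of class `overlay_volume`: 4D array
#'   `(nx, ny, nz, 4)` of RGBA in `[0, 1]`.
#' @export
overlay <- function(channels) {
  if (!is.list(channels)) stop("channels must be a list", call. = FALSE)
  if (length(channels) == 0L) stop("need at least one channel", call. = FALSE)
  if (length(channels) > 4L)
    stop("at most 4 channels can be fused (got ", length(channels), ")",
         call. = FALSE)
  channels <- lapply(channels, function(ch) {
    if (inherits(ch, "volume_stack"))
      ch <- list(vol = ch, tf = tf_grayscale())
    else if (inherits(ch, "probability_map"))
      ch <- list(vol = ch, tf = tf_probability())
    if (is.null(ch$tf))
      ch$tf <- if (inherits(ch$vol, "probability_map")) tf_probability()
               else tf_grayscale()
    ch
  })
  dims <- dim(as_vol_array(channels[[1]]$vol))
  out <- array(0, c(dims, 4L))
  rgba <- matrix(0, prod(dims), 4L)
  for (ch in channels) {
    v <- as_vol_array(ch$vol)
    if (!identical(dim(v), dims))
      stop("channel dims mismatch", call. = FALSE)
    if (inherits(ch$vol, "probability_map")) {
      nv <- as.numeric(v)
    } else {
      rng <- range(v)
      nv <- if (rng[2] > rng[1]) (as.numeric(v) - rng[1]) / (rng[2] - rng[1])
            else as.numeric(v) * 0
    }
    e <- tf_eval(ch$tf, nv)
    a <- e$opacity
    # standard "over" compositing against an initially transparent backdrop
    rgba[, 1] <- e$rgb[, 1] * a + rgba[, 1] * (1 - a)
    rgba[, 2] <- e$rgb[, 2] * a + rgba[, 2] * (1 - a)
    rgba[, 3] <- e$rgb[, 3] * a + rgba[, 3] * (1 - a)
    rgba[, 4] <- a + rgba[, 4] * (1 - a)
  }
  out[] <- rgba
  structure(out, class = "overlay_volume")
}

#' Write an RGBA overlay as a multi-page TIFF
#'
#' Each z-slice is written as a page with 4 samples per pixel (RGBA).
#'
#' @param ov An `overlay_volume`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(ov, path) {
  d <- dim(ov)
  pages <- lapply(seq_len(d[3]), function(z) {
    pg <- array(0, c(d[2], d[1], 4L))
    for (c4 in 1:4) pg[, , c4] <- t(ov[, , z, c4])
    pg
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Retrain a classifier after an additional tagging round
#'
#' Merges a new round of corrective tags into the annotation set and
#' retrains from scratch on the merged live tag set. The model metadata
#' records the new iteration number.
#'
#' @param model_spec A [classifier_spec()], or the string `"strong"` for
#'   the stacked strong learner.
#' @param ann The current [annotation_set()].
#' @param vol The annotated [volume_stack()].
#' @param bank The `feature_bank` in use.
#' @param new_tags Tibble/data.frame with columns `voxel_id`, `label` and
#'   `iteration`; all rows must carry `iteration` equal to the previous
#'   maximum + 1. May be empty (retrains on the unchanged tag set).
#' @param seed Seed for `model_spec = "strong"`.
#' @return List with the retrained `model` and the updated `ann`.
#' @export
iterate <- function(model_spec, ann, vol, bank = feature_bank_default(),
                    new_tags = NULL, seed = 0L) {
  it_prev <- max_iteration(ann)
  if (!is.null(new_tags) && nrow(new_tags) > 0L) {
    if (!all(c("voxel_id", "label", "iteration") %in% names(new_tags)))
      stop("new_tags needs voxel_id, label and iteration columns",
           call. = FALSE)
    if (any(new_tags$iteration != it_prev + 1L))
      stop("new tags must carry iteration = ", it_prev + 1L, call. = FALSE)
    for (lab in unique(new_tags$label))
      ann <- add_tags(ann, new_tags$voxel_id[new_tags$label == lab], lab,
                      iteration = it_prev + 1L)
  }
  live <- live_tags(ann)
  fm <- compute_features_at(vol, live$voxel_id, bank)
  tt <- training_table(ann, fm)
  it_now <- max(max_iteration(ann), 1L)
  model <- if (identical(model_spec, "strong")) {
    train_strong(tt$x, tt$y, seed = seed, iteration = it_now)
  } else {
    train_classifier(model_spec, tt$x, tt$y, iteration = it_now)
  }
  list(model = model, ann = ann)
}

#' Plot a probability-map slice
#'
#' Renders one z-slice with the blue-to-red probability colormap.
#'
#' @param object A [probability_map()].
#' @param z 1-based slice index (default: middle slice).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.probability_map <- function(object, z = NULL, ...) {
  d <- dim(object$data)
  if (is.null(z)) z <- (d[3] + 1L) %/% 2L
  sl <- object$data[, , z]
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$p <- as.numeric(sl)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "blue", high = "red",
                                 limits = c(0, 1), name = "p(positive)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("z = %d", z)) +
    ggplot2::theme_minimal()
}
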