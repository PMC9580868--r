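check_gt <- function(gt, dims = NULL) {
  g <- as_vol_array(gt)
  if (!is.null(dims) && !identical(dim(g), as.integer(dims)))
    stop("ground-truth dims mismatch", call. = FALSE)
  if (!all(g %in% c(0, 1)))
    stop("ground truth must be binary (0/1)", call. = FALSE)
  g
}

#' Dice coefficient
#'
#' Thresholds the prediction (ties, `p == threshold`, count as positive)
#' and computes `2 TP / (2 TP + FP + FN)` against a binary reference
#' segmentation. Two empty masks score 1 by convention.
#'
#' @param pred A [probability_map()], binary volume, or 3D array.
#' @param gt Binary reference volume with matching dims.
#' @param threshold Scalar threshold on the prediction (default 0.5).
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(pred, gt, threshold = 0.5) {
  p <- as_vol_array(pred)
  g <- check_gt(gt, dim(p))
  pm <- p >= threshold
  gm <- g == 1
  tp <- sum(pm & gm)
  denom <- 2 * tp + sum(pm & !gm) + sum(!pm & gm)
  if (denom == 0) return(1)
  2 * tp / denom
}

#' Root-mean-square error of a probability map
#'
#' `sqrt(mean((p - g)^2))` over all voxels of the volume, between the
#' inferred probabilities and the binary reference segmentation.
#'
#' @param pred A [probability_map()] or 3D array.
#' @param gt Binary reference volume with matching dims.
#' @return RMSE `>= 0` (at most 1 for probability inputs).
#' @export
rmse <- function(pred, gt) {
  p <- as_vol_array(pred)
  g <- check_gt(gt, dim(p))
  sqrt(mean((p - g)^2))
}

#' Evaluate a model on a volume with known ground truth
#'
#' Runs full-volume inference, thresholds the probability map, and scores
#' it with Dice and RMSE; also reports the voxel confusion counts and
#' informational wall-times per stage.
#'
#' @param model A `voxel_model` or `strong_learner`.
#' @param vol The [volume_stack()] to classify.
#' @param gt Binary reference segmentation, same dims.
#' @param bank The `feature_bank` used at training time.
#' @param threshold Probability threshold (default 0.5; ties positive).
#' @param block_shape Optional tile shape for inference.
#' @return An object of class `evaluation_report`: list with `dice`,
#'   `rmse`, `threshold`, counts `tp, fp, fn, tn`, the `probability` map
#'   and `timings` (seconds, informational).
#' @export
evaluate_run <- function(model, vol, gt, bank = feature_bank_default(),
                         threshold = 0.5, block_shape = NULL) {
  v <- as_vol_array(vol)
  g <- check_gt(gt, dim(v))
  t0 <- proc.time()[3]
  pm <- infer_volume(model, vol, bank, block_shape = block_shape)
  t_inf <- proc.time()[3] - t0
  t0 <- proc.time()[3]
  p <- pm$data
  pmask <- p >= threshold
  gmask <- g == 1
  tp <- sum(pmask & gmask); fp <- sum(pmask & !gmask)
  fn <- sum(!pmask & gmask); tn <- sum(!pmask & !gmask)
  d <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  r <- sqrt(mean((p - g)^2))
  t_eval <- proc.time()[3] - t0
  structure(list(dice = d, rmse = r, threshold = threshold,
                 tp = tp, fp = fp, fn = fn, tn = tn,
                 probability = pm,
                 timings = c(inference = unname(t_inf),
                             evaluation = unname(t_eval))),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> Dice %.4f, RMSE %.4f @ threshold %g (TP %d, FP %d, FN %d, TN %d)\n",
              x$dice, x$rmse, x$threshold, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' @export
tidy.evaluation_report <- function(x, ...) {
  tibble::tibble(metric = c("dice", "rmse"), value = c(x$dice, x$rmse))
}

#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(dice = x$dice, rmse = x$rmse, threshold = x$threshold,
                 tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn)
}

#' Write an evaluation report as JSON (and optionally CSV)
#'
#' @param report An `evaluation_report`.
#' @param path JSON destination.
#' @param csv Optional CSV destination for the per-run metric row.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, csv = NULL) {
  obj <- list(dice = report$dice, rmse = report$rmse,
              threshold = report$threshold,
              counts = list(tp = report$tp, fp = report$fp,
                            fn = report$fn, tn = report$tn),
              timings = as.list(report$timings))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv))
    utils::write.csv(glance(report), csv, row.names = FALSE)
  invisible(path)
}
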