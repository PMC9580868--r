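#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: the input volume (or a
#' phantom spec to simulate one), the annotations (or a stroke-simulation
#' request), the model kind, the seed, the evaluation threshold and the
#' optional tiling shape. The seed is recorded in the run log so every
#' run is reproducible from its logged configuration alone.
#'
#' @param volume A [volume_stack()], or `NULL` to simulate from
#'   `phantom`.
#' @param phantom A [phantom_spec()] used when `volume` is `NULL`; its
#'   ground truth also serves as the evaluation reference.
#' @param annotations An [annotation_set()], or `NULL` to simulate
#'   strokes from the phantom ground truth.
#' @param gt Optional binary reference segmentation for evaluation.
#' @param model `"rfc"`, `"mlp"`, `"xgb"`, `"svm"`, `"nbc"` or
#'   `"strong"`.
#' @param seed Integer seed for stroke simulation and training.
#' @param threshold Evaluation threshold.
#' @param block_shape Optional inference tile shape.
#' @param n_pos_strokes,n_neg_strokes,stroke_radius Stroke-simulation
#'   parameters.
#' @param bank Feature bank (default [feature_bank_default()]).
#' @param service Optional [voxel_service()]; when given, training runs
#'   through the job service instead of in-process (results are
#'   identical for identical seeds).
#' @param out_dir Optional directory for artifacts (probability map,
#'   overlay, report, run log).
#' @return An object of class `run_config`.
#' @export
run_config <- function(volume = NULL, phantom = NULL, annotations = NULL,
                       gt = NULL, model = "rfc", seed = 0L,
                       threshold = 0.5, block_shape = NULL,
                       n_pos_strokes = 2L, n_neg_strokes = 2L,
                       stroke_radius = 1,
                       bank = feature_bank_default(), service = NULL,
                       out_dir = NULL) {
  if (is.null(volume) && is.null(phantom))
    stop("need a volume or a phantom spec", call. = FALSE)
  structure(list(volume = volume, phantom = phantom,
                 annotations = annotations, gt = gt, model = model,
                 seed = as.integer(seed), threshold = threshold,
                 block_shape = block_shape,
                 n_pos_strokes = n_pos_strokes,
                 n_neg_strokes = n_neg_strokes,
                 stroke_radius = stroke_radius, bank = bank,
                 service = service, out_dir = out_dir),
            class = "run_config")
}

#' Run the full annotation pipeline
#'
#' Executes simulate/tag, feature extraction, training (in-process or
#' through a job service), full-volume inference, overlay compositing and
#' — when a reference segmentation is available — Dice/RMSE evaluation.
#' Artifacts and a machine-readable run log are written to
#' `config$out_dir` when set.
#'
#' @param config A [run_config()].
#' @return List with `model`, `probability` ([probability_map()]),
#'   `overlay`, `report` (an `evaluation_report` or `NULL`), `ann`, and
#'   `volume`. Stage failures abort with a stage-labeled message.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  gt <- config$gt
  vol <- config$volume
  if (is.null(vol)) {
    ph <- stage("simulate", generate_phantom(config$phantom))
    vol <- ph$volume
    if (is.null(gt)) gt <- ph$gt
  }
  ann <- config$annotations
  if (is.null(ann)) {
    if (is.null(gt))
      stop("[tag] no annotations given and no ground truth to simulate from",
           call. = FALSE)
    ann <- stage("tag", simulate_strokes(
      gt, config$n_pos_strokes, config$n_neg_strokes,
      radius = config$stroke_radius, seed = config$seed))
  }
  live <- live_tags(ann)
  fm <- stage("features", compute_features_at(vol, live$voxel_id, config$bank))
  tt <- stage("features", training_table(ann, fm))
  model <- stage("train", {
    if (!is.null(config$service)) {
      svc_train_remote(config$service, tt$x, tt$y, model = config$model,
                       seed = config$seed)
    } else if (identical(config$model, "strong")) {
      train_strong(tt$x, tt$y, seed = config$seed)
    } else {
      train_classifier(classifier_spec(config$model, seed = config$seed),
                       tt$x, tt$y)
    }
  })
  pm <- stage("infer", infer_volume(model, vol, config$bank,
                                    block_shape = config$block_shape))
  ov <- stage("overlay", overlay(list(
    list(vol = vol, tf = tf_grayscale()),
    list(vol = pm, tf = tf_probability()))))
  report <- NULL
  if (!is.null(gt)) {
    report <- stage("evaluate", {
      g <- check_gt(gt, dim(pm$data))
      pmask <- pm$data >= config$threshold
      gmask <- g == 1
      tp <- sum(pmask & gmask); fp <- sum(pmask & !gmask)
      fn <- sum(!pmask & gmask); tn <- sum(!pmask & !gmask)
      structure(list(
        dice = if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn),
        rmse = sqrt(mean((pm$data - g)^2)),
        threshold = config$threshold, tp = tp, fp = fp, fn = fn, tn = tn,
        probability = pm, timings = c()), class = "evaluation_report")
    })
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_volume(pm, file.path(config$out_dir, "probability.tif"))
    write_overlay(ov, file.path(config$out_dir, "overlay.tif"))
    save_model(model, file.path(config$out_dir, "model.vxl"))
    save_annotations(ann, file.path(config$out_dir, "annotations.json"),
                     volume_name = vol$name)
    if (!is.null(report))
      write_report(report, file.path(config$out_dir, "report.json"))
    log <- list(seed = config$seed, model = config$model,
                threshold = config$threshold,
                dims = dim(vol$data),
                n_tags = nrow(live),
                remote = !is.null(config$service))
    jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(model = model, probability = pm, overlay = ov, report = report,
       ann = ann, volume = vol)
}
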