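#' Read a 3D volume from TIFF or NIfTI
#'
#' Multi-page TIFF stacks are read one page per z-slice; NIfTI-1 volumes
#' are read with their native data. The in-memory convention is
#' `data[x, y, z]` with voxel `(0, 0, 0)` at the first pixel (first
#' column of the first row) of the first slice. Integer TIFF data are
#' returned in native integer units; 32-bit float TIFF and NIfTI data are
#' returned as-is.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tiff"` or `"nifti"`.
#' @param channel For multi-channel (RGB or multi-sample) TIFF pages, the
#'   1-based channel to extract. With more than one channel present and
#'   `channel = NULL`, a channel-selection error is raised: the learning
#'   pipeline operates on a single intensity channel.
#' @return A [volume_stack()].
#' @export
read_volume <- function(path, format = c("auto", "tiff", "nifti"),
                        channel = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- guess_format(path)
  if (format == "tiff") {
    pages <- tryCatch({
      meta <- tiff::readTIFF(path, payload = FALSE)
      # 32-bit samples are floats and come back in native units already;
      # integer depths are read unscaled (as.is) to keep them bit-exact
      tiff::readTIFF(path, all = TRUE, as.is = meta$bits.per.sample[1] != 32)
    }, error = function(e)
      stop("not a readable TIFF file: ", path, " (",
           conditionMessage(e), ")", call. = FALSE))
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(pg) {
      if (length(dim(pg)) == 3L) {
        nch <- dim(pg)[3]
        if (is.null(channel)) {
          if (nch > 1L)
            stop("volume has ", nch,
                 " channels; select one with `channel=`", call. = FALSE)
          channel <- 1L
        }
        if (channel > nch) stop("channel ", channel, " not present",
                                call. = FALSE)
        pg <- pg[, , channel]
      }
      pg
    })
    d <- dim(pages[[1]])
    # TIFF pages are [row, col] = [y, x]; transpose to data[x, y]
    data <- array(0, c(d[2], d[1], length(pages)))
    for (z in seq_along(pages)) data[, , z] <- t(pages[[z]])
    volume_stack(data, name = basename(path))
  } else {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e)
                      stop("not a readable NIfTI file: ", path, " (",
                           conditionMessage(e), ")", call. = FALSE))
    a <- as.array(img)
    a <- array(as.numeric(a), dim(a))  # drop RNifti's internal attributes
    if (length(dim(a)) == 4L) {
      if (dim(a)[4] == 1L) {
        a <- a[, , , 1L]
      } else if (!is.null(channel)) {
        a <- a[, , , channel]
      } else {
        stop("volume has ", dim(a)[4],
             " channels; select one with `channel=`", call. = FALSE)
      }
    }
    sp <- tryCatch(RNifti::pixdim(img)[1:3], error = function(e) c(1, 1, 1))
    if (any(!is.finite(sp)) || any(sp <= 0)) sp <- c(1, 1, 1)
    volume_stack(a, spacing = sp, name = basename(path))
  }
}

guess_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.(tif|tiff)$", lp)) return("tiff")
  if (grepl("\\.(nii|nii\\.gz|hdr|img)$", lp)) return("nifti")
  stop("cannot guess volume format from extension: ", path, call. = FALSE)
}

#' Write a 3D volume to TIFF or NIfTI
#'
#' Integer-valued volumes in `[0, 65535]` are stored as 16-bit TIFF and
#' round-trip bit-identically; anything else (probability maps included)
#' is stored as 32-bit float voxels. NIfTI output always stores the data
#' verbatim.
#'
#' @param vol A [volume_stack()], [probability_map()] or 3D array.
#' @param path Destination path.
#' @param format `"auto"` (by extension), `"tiff"` or `"nifti"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = c("auto", "tiff", "nifti")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  v <- as_vol_array(vol)
  if (format == "tiff") {
    d <- dim(v)
    # probability maps always go to 32-bit float, whatever their values
    integerish <- !inherits(vol, "probability_map") &&
      all(v == round(v)) && min(v) >= 0 && max(v) <= 65535
    pages <- lapply(seq_len(d[3]), function(z) t(v[, , z]))
    ok <- tryCatch({
      if (integerish) {
        tiff::writeTIFF(lapply(pages, function(p) p / 65535),
                        path, bits.per.sample = 16L)
      } else {
        tiff::writeTIFF(pages, path, bits.per.sample = 32L)
      }
      TRUE
    }, error = function(e)
      stop("cannot write TIFF to ", path, " (", conditionMessage(e), ")",
           call. = FALSE))
  } else {
    sp <- if (inherits(vol, "volume_stack")) vol$spacing else c(1, 1, 1)
    img <- RNifti::asNifti(v, datatype = "double")
    tryCatch(RNifti::writeNifti(img, path),
             error = function(e)
               stop("cannot write NIfTI to ", path, " (",
                    conditionMessage(e), ")", call. = FALSE))
  }
  invisible(path)
}

# ---- transfer functions -------------------------------------------------

#' Construct a transfer function
#'
#' A transfer function maps normalized intensity in `[0, 1]` to opacity in
#' `[0, 1]` and RGB color, by monotone piecewise-linear interpolation
#' between control points. Control-point intensities must be strictly
#' increasing, with the first at 0 and the last at 1.
#'
#' @param x Numeric vector of control-point intensities.
#' @param opacity Numeric vector of opacities in `[0, 1]`.
#' @param rgb Matrix with one row per control point, columns R, G, B in
#'   `[0, 1]`.
#' @return An object of class `transfer_function`.
#' @export
transfer_function <- function(x, opacity, rgb) {
  x <- as.numeric(x); opacity <- as.numeric(opacity)
  rgb <- matrix(as.numeric(rgb), ncol = 3)
  if (length(x) < 2L) stop("need at least 2 control points", call. = FALSE)
  if (any(diff(x) <= 0))
    stop("control-point intensities must be strictly increasing",
         call. = FALSE)
  if (abs(x[1]) > 1e-12 || abs(x[length(x)] - 1) > 1e-12)
    stop("control points must start at 0 and end at 1", call. = FALSE)
  if (length(opacity) != length(x) || nrow(rgb) != length(x))
    stop("opacity and rgb must match the number of control points",
         call. = FALSE)
  if (any(opacity < 0 | opacity > 1) || any(rgb < 0 | rgb > 1))
    stop("opacity and rgb must lie in [0, 1]", call. = FALSE)
  structure(list(x = x, opacity = opacity, rgb = rgb),
            class = "transfer_function")
}

#' Evaluate a transfer function
#'
#' @param tf A [transfer_function()].
#' @param v Numeric vector of normalized intensities; values outside
#'   `[0, 1]` are clamped.
#' @return A list with `opacity` (vector) and `rgb` (matrix).
#' @export
tf_eval <- function(tf, v) {
  v <- pmin(pmax(as.numeric(v), 0), 1)
  interp <- function(y) stats::approx(tf$x, y, xout = v, rule = 2)$y
  list(opacity = interp(tf$opacity),
       rgb = cbind(interp(tf$rgb[, 1]), interp(tf$rgb[, 2]),
                   interp(tf$rgb[, 3])))
}

#' Built-in transfer functions
#'
#' `tf_grayscale()` renders normalized intensity as opaque gray.
#' `tf_probability()` is the default probability colormap: 0 maps to blue
#' and 1 to red with a linearly interpolated hue passing through magenta
#' (no green), and opacity rising linearly from 0 to 1 so that low
#' probabilities fade out of the fused view.
#'
#' @return A [transfer_function()].
#' @export
tf_grayscale <- function() {
  transfer_function(c(0, 1), c(1, 1), rbind(c(0, 0, 0), c(1, 1, 1)))
}

#' @rdname tf_grayscale
#' @export
tf_probability <- function() {
  transfer_function(c(0, 1), c(0, 1), rbind(c(0, 0, 1), c(1, 0, 0)))
}

#' Save / load a transfer function as JSON
#'
#' The on-disk dialect is
#' `{"points": [{"x": 0.0, "opacity": 0.0, "rgb": [0, 0, 0]}, ...]}`.
#' Round-trips preserve control points exactly.
#'
#' @param tf A [transfer_function()].
#' @param path File path.
#' @return `load_transfer_function` returns a [transfer_function()].
#' @export
save_transfer_function <- function(tf, path) {
  pts <- lapply(seq_along(tf$x), function(i)
    list(x = tf$x[i], opacity = tf$opacity[i], rgb = as.numeric(tf$rgb[i, ])))
  jsonlite::write_json(list(points = pts), path, auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname save_transfer_function
#' @export
load_transfer_function <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
                  error = function(e)
                    stop("malformed transfer-function JSON: ", path,
                         call. = FALSE))
  if (is.null(obj$points) || length(obj$points) < 2L)
    stop("transfer-function JSON must contain >= 2 points", call. = FALSE)
  x <- vapply(obj$points, function(p) as.numeric(p$x), 0)
  op <- vapply(obj$points, function(p) as.numeric(p$opacity), 0)
  rgb <- t(vapply(obj$points, function(p) as.numeric(p$rgb), numeric(3)))
  transfer_function(x, op, rgb)
}

# ---- annotations on disk ------------------------------------------------

#' Save / load an annotation set as JSON
#'
#' The on-disk dialect is
#' `{"volume": "<name>", "dims": [nx, ny, nz],
#'   "tags": [{"id": 432, "label": "positive", "iteration": 1}, ...]}`.
#' Only live tags are serialized (the erase history is an in-memory audit
#' log); round-trips preserve every live `(voxel ID, label, iteration)`
#' record.
#'
#' @param ann An [annotation_set()].
#' @param path File path.
#' @param volume_name Volume name recorded in the file.
#' @return `load_annotations` returns an [annotation_set()].
#' @export
save_annotations <- function(ann, path, volume_name = ann$volume) {
  live <- live_tags(ann)
  tags <- lapply(seq_len(nrow(live)), function(i)
    list(id = live$voxel_id[i], label = live$label[i],
         iteration = live$iteration[i]))
  jsonlite::write_json(list(volume = volume_name, dims = as.integer(ann$dims),
                            tags = tags),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_annotations
#' @export
load_annotations <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
                  error = function(e)
                    stop("malformed annotation JSON: ", path, call. = FALSE))
  if (is.null(obj$dims) || length(obj$dims) != 3L)
    stop("annotation JSON must carry dims [nx, ny, nz]", call. = FALSE)
  ann <- annotation_set(as.integer(obj$dims),
                        volume = if (is.null(obj$volume)) "" else obj$volume)
  tags <- obj$tags
  if (is.null(tags) || (is.data.frame(tags) && nrow(tags) == 0L) ||
      length(tags) == 0L)
    return(ann)
  if (!is.data.frame(tags))
    stop("annotation JSON tags must be an array of records", call. = FALSE)
  if (!all(c("id", "label", "iteration") %in% names(tags)))
    stop("annotation tags need id, label and iteration fields", call. = FALSE)
  if (!all(tags$label %in% c("positive", "negative")))
    stop("annotation labels must be 'positive' or 'negative'", call. = FALSE)
  key <- paste(tags$id)
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    conf <- tapply(tags$label, key, function(l) length(unique(l)) > 1L)
    if (any(conf))
      stop("duplicate voxel ID with conflicting labels in annotation file",
           call. = FALSE)
    tags <- tags[!duplicated(key), , drop = FALSE]
  }
  for (it in sort(unique(tags$iteration)))
    for (lab in unique(tags$label[tags$iteration == it]))
      ann <- add_tags(ann, tags$id[tags$iteration == it & tags$label == lab],
                      lab, iteration = it)
  ann
}
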