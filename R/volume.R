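#' Construct a volume stack
#'
#' A `volume_stack` wraps a 3D scalar intensity grid together with its
#' per-axis voxel spacing and a free-text name. It is the unit every stage
#' of the pipeline consumes: feature extraction, inference, overlay and
#' evaluation all take volume stacks.
#'
#' @param data 3D numeric array of intensities (dims `nx, ny, nz`). A 2D
#'   matrix is promoted to a single-slice volume.
#' @param spacing Positive numeric vector of length 3: voxel size per axis
#'   (unitless, default 1).
#' @param name Free-text volume name, stored in annotation files.
#' @return An object of class `volume_stack`.
#' @export
volume_stack <- function(data, spacing = c(1, 1, 1), name = "volume") {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (any(dim(data) < 1L)) stop("all dims must be >= 1", call. = FALSE)
  storage.mode(data) <- "double"
  if (any(!is.finite(data)))
    stop("intensities must be finite", call. = FALSE)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be strictly positive", call. = FALSE)
  structure(list(data = data, spacing = spacing, name = as.character(name)[1]),
            class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_stack> '%s'  %d x %d x %d voxels, intensity [%g, %g]\n",
              x$name, d[1], d[2], d[3], min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume_stack <- function(x) dim(x$data)

# coerce volume_stack / probability_map / bare array to a 3D array
as_vol_array <- function(x) {
  if (inherits(x, "volume_stack") || inherits(x, "probability_map")) return(x$data)
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (is.array(x) && length(dim(x)) == 3L) {
    storage.mode(x) <- "double"
    return(x)
  }
  stop("expected a volume_stack, probability_map, or 3D array", call. = FALSE)
}

#' Linear voxel IDs from 0-based coordinates
#'
#' Voxels are addressed by a 0-based linear index with x fastest:
#' `id = x + nx * (y + ny * z)`. This single documented linearization keeps
#' annotation files portable between tools.
#'
#' @param coords Matrix (or vector of length 3) of 0-based `(x, y, z)`
#'   voxel coordinates, one row per voxel.
#' @param dims Integer vector `(nx, ny, nz)`.
#' @return Integer vector of voxel IDs.
#' @export
voxel_id <- function(coords, dims) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3)
  dims <- as.integer(dims)
  stopifnot(ncol(coords) == 3, length(dims) == 3)
  if (any(coords < 0) || any(coords[, 1] > dims[1] - 1) ||
      any(coords[, 2] > dims[2] - 1) || any(coords[, 3] > dims[3] - 1))
    stop("coordinates out of bounds", call. = FALSE)
  as.integer(coords[, 1] + dims[1] * (coords[, 2] + dims[2] * coords[, 3]))
}

#' 0-based coordinates from linear voxel IDs
#'
#' Inverse of [voxel_id()].
#'
#' @param ids Integer vector of voxel IDs.
#' @param dims Integer vector `(nx, ny, nz)`.
#' @return Integer matrix with columns `x, y, z` (0-based).
#' @export
voxel_coords <- function(ids, dims) {
  dims <- as.integer(dims)
  ids <- as.integer(ids)
  n <- prod(dims)
  if (any(ids < 0L) || any(ids >= n))
    stop("voxel id out of bounds", call. = FALSE)
  x <- ids %% dims[1]
  y <- (ids %/% dims[1]) %% dims[2]
  z <- ids %/% (dims[1] * dims[2])
  cbind(x = x, y = y, z = z)
}

#' Construct a probability map
#'
#' Per-voxel probability of the positive class, the pipeline's primary
#' output. Values live in `[0, 1]` and dims match the source volume.
#'
#' @param data 3D numeric array of probabilities in `[0, 1]`.
#' @param model_fingerprint Fingerprint of the model that produced the map.
#' @param class_label Name of the positive class.
#' @return An object of class `probability_map`.
#' @export
probability_map <- function(data, model_fingerprint = "", class_label = "positive") {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  stopifnot(is.array(data), length(dim(data)) == 3L)
  storage.mode(data) <- "double"
  if (any(!is.finite(data)) || any(data < 0) || any(data > 1))
    stop("probabilities must be finite and in [0, 1]", call. = FALSE)
  structure(list(data = data, model_fingerprint = model_fingerprint,
                 class_label = class_label),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<probability_map> %d x %d x %d, mean p = %.3f\n",
              d[1], d[2], d[3], mean(x$data)))
  invisible(x)
}

#' @export
dim.probability_map <- function(x) dim(x$data)

#' Log-transform a probability map
#'
#' Natural log of the per-voxel probability with a floor at `log(1e-12)`
#' so that zero probabilities stay finite. Monotone in the input, which is
#' all a transfer function needs.
#'
#' @param pm A [probability_map()] (or 3D array of probabilities).
#' @return 3D array of log-probabilities.
#' @export
log_transform <- function(pm) {
  p <- as_vol_array(pm)
  log(pmax(p, 1e-12))
}
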