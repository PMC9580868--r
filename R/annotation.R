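#' Construct an empty annotation set
#'
#' An annotation set is the headless stand-in for the VR tagging store: a
#' sparse event log of `(voxel_id, label, iteration)` records over a
#' volume of known dimensions. Later iterations win (tags can be updated),
#' and erasures are recorded as events so the audit trail of iterative
#' retraining is preserved in memory.
#'
#' @param dims Integer vector `(nx, ny, nz)`.
#' @param volume Free-text name of the annotated volume.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(dims, volume = "") {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L))
  structure(list(
    dims = dims, volume = as.character(volume)[1],
    events = tibble::tibble(seq = integer(), voxel_id = integer(),
                            label = character(), iteration = integer())
  ), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  live <- live_tags(x)
  cat(sprintf(
    "<annotation_set> dims %s, %d live tags (%d positive, %d negative), %d events\n",
    paste(x$dims, collapse = "x"), nrow(live),
    sum(live$label == "positive"), sum(live$label == "negative"),
    nrow(x$events)))
  invisible(x)
}

max_iteration <- function(ann) {
  if (nrow(ann$events) == 0L) 0L else max(ann$events$iteration)
}

#' Live tags of an annotation set
#'
#' Replays the event log: for each voxel the most recent event decides its
#' label; erased voxels carry no live label.
#'
#' @param ann An [annotation_set()].
#' @return Tibble with columns `voxel_id`, `label`, `iteration`, sorted by
#'   `voxel_id`.
#' @export
live_tags <- function(ann) {
  ev <- ann$events
  if (nrow(ev) == 0L)
    return(tibble::tibble(voxel_id = integer(), label = character(),
                          iteration = integer()))
  ev <- ev[order(ev$voxel_id, ev$seq), ]
  last <- ev[!duplicated(ev$voxel_id, fromLast = TRUE), ]
  last <- last[last$label != "erased", c("voxel_id", "label", "iteration")]
  last[order(last$voxel_id), ]
}

#' Add tags to an annotation set
#'
#' Voxels acquire the given label at the given iteration. A voxel
#' re-tagged at a later iteration takes the newest label. Tagging the same
#' voxel with both labels within one iteration is rejected — the VR
#' interface makes this impossible, so the headless API treats it as a
#' validation error.
#'
#' @param ann An [annotation_set()].
#' @param voxel_ids Integer vector of linear voxel IDs (0-based).
#' @param label `"positive"` or `"negative"`.
#' @param iteration Tagging round, `>=` the current maximum iteration.
#' @return The updated [annotation_set()].
#' @export
add_tags <- function(ann, voxel_ids, label = c("positive", "negative"),
                     iteration = NULL) {
  label <- match.arg(label)
  voxel_ids <- unique(as.integer(voxel_ids))
  if (length(voxel_ids) == 0L) return(ann)
  n <- prod(ann$dims)
  if (any(voxel_ids < 0L) || any(voxel_ids >= n))
    stop("voxel_id out of bounds for dims ",
         paste(ann$dims, collapse = "x"), call. = FALSE)
  if (is.null(iteration)) iteration <- max(1L, max_iteration(ann))
  iteration <- as.integer(iteration)
  if (iteration < 1L || iteration < max_iteration(ann))
    stop("iteration must be >= the current maximum iteration (",
         max_iteration(ann), ")", call. = FALSE)
  ev <- ann$events
  clash <- ev$voxel_id %in% voxel_ids & ev$iteration == iteration &
    ev$label != "erased" & ev$label != label
  if (any(clash))
    stop("voxel tagged with both labels within iteration ", iteration,
         call. = FALSE)
  new <- tibble::tibble(seq = nrow(ev) + seq_along(voxel_ids),
                        voxel_id = voxel_ids, label = label,
                        iteration = iteration)
  ann$events <- dplyr::bind_rows(ev, new)
  ann
}

#' Erase tags
#'
#' Named voxels lose their live label; the history is retained as erase
#' events so corrections made during iterative retraining remain
#' auditable. Erasing an untagged voxel is a no-op.
#'
#' @param ann An [annotation_set()].
#' @param voxel_ids Integer vector of voxel IDs to erase.
#' @return The updated [annotation_set()].
#' @export
erase_tags <- function(ann, voxel_ids) {
  voxel_ids <- unique(as.integer(voxel_ids))
  live <- live_tags(ann)
  voxel_ids <- intersect(voxel_ids, live$voxel_id)
  if (length(voxel_ids) == 0L) return(ann)
  it <- max(1L, max_iteration(ann))
  new <- tibble::tibble(seq = nrow(ann$events) + seq_along(voxel_ids),
                        voxel_id = voxel_ids, label = "erased",
                        iteration = it)
  ann$events <- dplyr::bind_rows(ann$events, new)
  ann
}

#' Construct a stroke
#'
#' A stroke is the headless counterpart of a VR controller gesture: an
#' ordered 3D polyline in voxel coordinates with a brush radius and a
#' label.
#'
#' @param points Matrix of 3D points (one row per point, columns x, y, z,
#'   0-based voxel coordinates), or a numeric vector of length 3.
#' @param radius Brush radius in voxel units (`>= 0`, finite).
#' @param label `"positive"` or `"negative"`.
#' @return An object of class `stroke`.
#' @export
stroke <- function(points, radius = 1, label = c("positive", "negative")) {
  label <- match.arg(label)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- as.matrix(points)
  if (nrow(points) < 1L || ncol(points) != 3L)
    stop("a stroke needs >= 1 three-dimensional point", call. = FALSE)
  if (!is.finite(radius) || radius < 0)
    stop("radius must be finite and >= 0", call. = FALSE)
  structure(list(points = points, radius = as.numeric(radius), label = label),
            class = "stroke")
}

#' Voxels swept by a stroke
#'
#' Returns every voxel whose center (integer grid point) lies within
#' Euclidean distance `radius` of the stroke polyline, computed by exact
#' point-to-segment distance over per-segment bounding boxes. Voxels
#' outside the volume are clipped.
#'
#' @param strk A [stroke()].
#' @param dims Integer vector `(nx, ny, nz)`.
#' @return Sorted integer vector of voxel IDs.
#' @export
stroke_to_voxels <- function(strk, dims) {
  stopifnot(inherits(strk, "stroke"))
  dims <- as.integer(dims)
  pts <- strk$points
  r <- strk$radius
  ids <- integer(0)
  segs <- if (nrow(pts) == 1L) list(list(a = pts[1, ], b = pts[1, ]))
          else lapply(seq_len(nrow(pts) - 1L),
                      function(i) list(a = pts[i, ], b = pts[i + 1L, ]))
  for (sg in segs) {
    lo <- pmax(ceiling(pmin(sg$a, sg$b) - r - 1e-9), 0)
    hi <- pmin(floor(pmax(sg$a, sg$b) + r + 1e-9), dims - 1)
    if (any(hi < lo)) next
    g <- expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
    d2 <- point_segment_dist2(as.matrix(g), sg$a, sg$b)
    keep <- d2 <= r * r + 1e-12
    if (any(keep))
      ids <- c(ids, voxel_id(as.matrix(g)[keep, , drop = FALSE], dims))
  }
  sort(unique(ids))
}

# squared distance from points (rows of p) to segment [a, b]
point_segment_dist2 <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab * ab)
  ap <- sweep(p, 2, a)
  t <- if (len2 == 0) rep(0, nrow(p)) else
    pmin(pmax(as.numeric(ap %*% ab) / len2, 0), 1)
  d <- ap - outer(t, ab)
  rowSums(d * d)
}

#' Apply a stroke to an annotation set
#'
#' Convenience wrapper: voxelizes the stroke and adds the resulting tags.
#'
#' @param ann An [annotation_set()].
#' @param strk A [stroke()].
#' @param iteration Tagging round (default: current round, or 1).
#' @return The updated [annotation_set()].
#' @export
apply_stroke <- function(ann, strk, iteration = NULL) {
  ids <- stroke_to_voxels(strk, ann$dims)
  add_tags(ann, ids, strk$label, iteration)
}

#' Assemble the training table
#'
#' Joins the live tags of an annotation set with their feature rows,
#' producing the supervised design matrix. Rows are ordered by voxel ID;
#' the response is 1 for positive tags and 0 for negative ones.
#'
#' @param ann An [annotation_set()].
#' @param features A `feature_matrix` from [compute_features_at()]
#'   containing a row for every live-tagged voxel.
#' @return List with `x` (numeric matrix, attribute `spec_hash`), `y`
#'   (0/1 integer vector) and `voxel_id`.
#' @export
training_table <- function(ann, features) {
  live <- live_tags(ann)
  fm_ids <- features$voxel_id
  missing <- setdiff(live$voxel_id, fm_ids)
  if (length(missing))
    stop("missing feature rows for ", length(missing), " tagged voxel(s)",
         call. = FALSE)
  vals <- feature_matrix_values(features)
  idx <- match(live$voxel_id, fm_ids)
  x <- vals[idx, , drop = FALSE]
  attr(x, "spec_hash") <- attr(vals, "spec_hash")
  list(x = x, y = as.integer(live$label == "positive"),
       voxel_id = live$voxel_id)
}

#' @export
tidy.annotation_set <- function(x, ...) live_tags(x)

#' @export
glance.annotation_set <- function(x, ...) {
  live <- live_tags(x)
  tibble::tibble(n_live = nrow(live),
                 n_positive = sum(live$label == "positive"),
                 n_negative = sum(live$label == "negative"),
                 n_events = nrow(x$events),
                 max_iteration = max_iteration(x))
}
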