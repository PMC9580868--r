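#' Phantom specification
#'
#' Synthetic volumes emulate the two structure classes the pipeline is
#' aimed at: bulky high-intensity blobs (tumor-like ellipsoids) and thin
#' tubular networks (neurite-like random walks with momentum), embedded in
#' a noisy background.
#'
#' @param kind `"blob"` or `"tubes"`.
#' @param dims Integer vector `(nx, ny, nz)`, each `>= 16`.
#' @param object_mean Mean intensity inside objects (default 200).
#' @param background_mean Mean background intensity (default 10).
#' @param noise `"gaussian"` or `"poisson"`.
#' @param noise_sd Gaussian noise standard deviation (ignored for
#'   Poisson).
#' @param geometry Kind-specific list. Blob: `ellipsoids`, a list of
#'   `list(center =, radii =)` (defaults to one centered ellipsoid with
#'   radii ~ 28% of the dims). Tubes: `n_tubes`, `tube_radius`, `n_steps`,
#'   `persistence` (momentum of the random walk, default 0.9).
#' @param seed Integer seed; recorded and used for all randomness.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("blob", "tubes"), dims = c(32, 32, 32),
                         object_mean = 200, background_mean = 10,
                         noise = c("gaussian", "poisson"), noise_sd = 0,
                         geometry = list(), seed = 0L) {
  kind <- match.arg(kind)
  noise <- match.arg(noise)
  dims <- as.integer(rep_len(dims, 3L))
  if (any(dims < 16L)) stop("dims must be >= 16 per axis", call. = FALSE)
  if (object_mean < 0 || background_mean < 0)
    stop("intensities must be >= 0", call. = FALSE)
  defaults <- if (kind == "blob") {
    list(ellipsoids = list(list(center = (dims - 1) / 2,
                                radii = pmax(dims * 0.28, 4))))
  } else {
    list(n_tubes = 3L, tube_radius = 1.5, n_steps = 60L, persistence = 0.9)
  }
  structure(list(kind = kind, dims = dims, object_mean = object_mean,
                 background_mean = background_mean, noise = noise,
                 noise_sd = noise_sd,
                 geometry = {  # wholesale per-key override (values may be
                               # unnamed lists, which modifyList would skip)
                   g <- defaults
                   g[names(geometry)] <- geometry
                   g
                 },
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phantom volume and its ground truth
#'
#' The ground truth is the union of the noiseless geometry; the volume is
#' the ground-truth-dependent intensities plus noise. The same spec (same
#' seed) always produces bit-identical output.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` (a [volume_stack()]) and `gt` (binary 3D
#'   array).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$dims
  set.seed(spec$seed)
  gt <- if (spec$kind == "blob") blob_gt(spec) else tubes_gt(spec)
  if (!any(gt == 1)) stop("phantom geometry produced an empty object",
                          call. = FALSE)
  clean <- spec$background_mean + (spec$object_mean - spec$background_mean) * gt
  v <- if (spec$noise == "gaussian") {
    if (spec$noise_sd > 0) clean + rnorm(length(clean), 0, spec$noise_sd)
    else clean
  } else {
    array(rpois(length(clean), lambda = clean), dims)
  }
  v <- pmax(v, 0)
  list(volume = volume_stack(array(v, dims),
                             name = paste0(spec$kind, "_phantom")),
       gt = array(gt, dims))
}

blob_gt <- function(spec) {
  dims <- spec$dims
  gt <- array(0, dims)
  cc <- voxel_coords(0:(prod(dims) - 1L), dims)
  for (el in spec$geometry$ellipsoids) {
    if (any(el$center - el$radii < -0.5) ||
        any(el$center + el$radii > dims - 0.5))
      stop("ellipsoid larger than the volume", call. = FALSE)
    q <- ((cc[, 1] - el$center[1]) / el$radii[1])^2 +
         ((cc[, 2] - el$center[2]) / el$radii[2])^2 +
         ((cc[, 3] - el$center[3]) / el$radii[3])^2
    gt[q <= 1] <- 1
  }
  gt
}

tubes_gt <- function(spec) {
  dims <- spec$dims
  g <- spec$geometry
  gt <- array(0, dims)
  for (t in seq_len(g$n_tubes)) {
    # random walk with momentum ("persistence") produces dendrite-like
    # curvature without a morphology library
    pos <- runif(3, 0.2, 0.8) * (dims - 1)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    path <- matrix(0, g$n_steps + 1L, 3L)
    path[1, ] <- pos
    for (s in seq_len(g$n_steps)) {
      kick <- rnorm(3); kick <- kick / sqrt(sum(kick^2))
      dir <- g$persistence * dir + (1 - g$persistence) * kick
      dir <- dir / sqrt(sum(dir^2))
      pos <- pos + dir
      # reflect off the faces so tubes stay inside the volume
      for (a in 1:3) {
        if (pos[a] < 1) { pos[a] <- 2 - pos[a]; dir[a] <- -dir[a] }
        if (pos[a] > dims[a] - 2) {
          pos[a] <- 2 * (dims[a] - 2) - pos[a]; dir[a] <- -dir[a]
        }
      }
      path[s + 1L, ] <- pos
    }
    ids <- stroke_to_voxels(stroke(path, radius = g$tube_radius,
                                   label = "positive"), dims)
    gt[ids + 1L] <- 1
  }
  gt
}

#' Simulate annotation strokes on a known ground truth
#'
#' Emulates the sparse supervision a user would give: a few short
#' positive strokes wholly inside the object and a few larger negative
#' background streaks. Stroke polylines are random walks constrained to
#' the respective class, and every returned tag is label-consistent with
#' the ground truth (swept voxels of the other class are dropped).
#'
#' @param gt Binary 3D array with both classes present.
#' @param n_pos_strokes,n_neg_strokes Number of strokes per label.
#' @param radius Brush radius in voxels (default 1).
#' @param seed Integer seed.
#' @param pos_len Number of random-walk steps per positive stroke.
#' @return An [annotation_set()] with all tags at iteration 1.
#' @export
simulate_strokes <- function(gt, n_pos_strokes = 2L, n_neg_strokes = 2L,
                             radius = 1, seed = 0L, pos_len = 10L) {
  g <- check_gt(gt)
  dims <- dim(g)
  if (!any(g == 1) || !any(g == 0))
    stop("ground truth must contain both classes", call. = FALSE)
  set.seed(seed)
  ann <- annotation_set(dims, volume = "simulated")
  ids_all <- 0:(prod(dims) - 1L)
  pos_ids <- ids_all[g == 1]
  neg_ids <- ids_all[g == 0]
  walk <- function(start_id, inside, len) {
    cc <- voxel_coords(start_id, dims)[1, ]
    path <- matrix(cc, 1L, 3L)
    pos <- cc
    for (s in seq_len(len)) {
      nb <- t(pos + t(rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                            c(0,0,1), c(0,0,-1))))
      ok <- nb[, 1] >= 0 & nb[, 2] >= 0 & nb[, 3] >= 0 &
            nb[, 1] < dims[1] & nb[, 2] < dims[2] & nb[, 3] < dims[3]
      nb <- nb[ok, , drop = FALSE]
      keep <- g[cbind(nb[, 1] + 1L, nb[, 2] + 1L, nb[, 3] + 1L)]
      nb <- nb[if (inside) keep == 1 else keep == 0, , drop = FALSE]
      if (nrow(nb) == 0L) break
      pos <- nb[sample.int(nrow(nb), 1L), ]
      path <- rbind(path, pos)
    }
    path
  }
  pos_stroke <- function() {
    # short scribble wholly inside the structure of interest
    for (attempt in 1:20) {
      start <- pos_ids[sample.int(length(pos_ids), 1L)]
      path <- walk(start, TRUE, pos_len)
      ids <- stroke_to_voxels(stroke(path, radius = radius,
                                     label = "positive"), dims)
      ids <- ids[g[ids + 1L] == 1]  # label-consistent only
      if (length(ids) > 0L) return(ids)
    }
    stop("could not place a positive stroke", call. = FALSE)
  }
  neg_stroke <- function() {
    # a large background streak swept across the scene, brushing past the
    # object so background right up to its frontier gets tagged
    for (attempt in 1:20) {
      anchor <- voxel_coords(pos_ids[sample.int(length(pos_ids), 1L)],
                             dims)[1, ]
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      span <- sqrt(sum(dims^2))
      a <- pmin(pmax(anchor - span * dir, 0), dims - 1)
      b <- pmin(pmax(anchor + span * dir, 0), dims - 1)
      ids <- stroke_to_voxels(stroke(rbind(a, b), radius = radius,
                                     label = "negative"), dims)
      ids <- ids[g[ids + 1L] == 0]  # clip the streak to the background
      if (length(ids) > 0L) return(ids)
    }
    stop("could not place a negative stroke", call. = FALSE)
  }
  for (i in seq_len(n_pos_strokes))
    ann <- add_tags(ann, pos_stroke(), "positive", 1L)
  for (i in seq_len(n_neg_strokes))
    ann <- add_tags(ann, neg_stroke(), "negative", 1L)
  ann
}

#' The standard phantom fixture suite
#'
#' Three fixed phantoms used throughout the tests and the acceptance
#' checks, with published seeds and specs:
#'
#' * `blob_clean`: 32^3, one centered ellipsoid, no noise.
#' * `blob_noisy`: same geometry, Gaussian noise with sd = 20% of the
#'   object/background contrast.
#' * `tubes_noisy`: 48^3, 3 tubes of radius 1.5, same relative noise.
#'
#' @return Named list of [phantom_spec()]s.
#' @export
standard_fixtures <- function() {
  contrast <- 200 - 10
  list(
    blob_clean = phantom_spec("blob", dims = c(32, 32, 32),
                              noise_sd = 0, seed = 101L),
    blob_noisy = phantom_spec("blob", dims = c(32, 32, 32),
                              noise_sd = 0.2 * contrast, seed = 102L),
    tubes_noisy = phantom_spec("tubes", dims = c(48, 48, 48),
                               noise_sd = 0.2 * contrast, seed = 103L)
  )
}
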