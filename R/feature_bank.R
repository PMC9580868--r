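# filter kind -> integer code shared with src/filters.cpp
.filter_codes <- c(
  pixel_value = 0L, gaussian = 1L, mean = 2L, median = 3L,
  minimum = 4L, maximum = 5L, range = 6L, stddev = 7L,
  gradient_magnitude = 8L, laplacian_of_gaussian = 9L,
  difference_of_gaussians = 10L, hessian_max_eigen = 11L
)

.bank_kernel_sizes <- c(3L, 5L, 7L, 9L, 11L)

#' The default 56-feature multi-scale filter bank
#'
#' Per-voxel features are the responses of a fixed, ordered bank of 3D
#' spatial filters computed at multiple kernel sizes, plus the raw voxel
#' intensity itself (`PIXEL_VALUE`, feature index 0). The default bank is
#' 11 filter kinds x 5 kernel sizes (3, 5, 7, 9, 11 voxels) + PIXEL_VALUE
#' = 56 features, spanning smoothing (Gaussian, mean, median), order
#' statistics (minimum, maximum, range), local texture (standard
#' deviation) and differential geometry (gradient magnitude, Laplacian of
#' Gaussian, difference of Gaussians, largest Hessian eigenvalue — the
#' latter responds strongly to thin tubular structures).
#'
#' Gaussian-derived filters use `sigma = kernel_size / 6` so that +/- 3
#' sigma spans the kernel; the difference of Gaussians subtracts the
#' response at `2 * sigma`, both truncated to the kernel.
#'
#' @return A tibble of class `feature_bank` with columns `index` (0-based),
#'   `filter_kind`, `kernel_size` (`NA` for `PIXEL_VALUE`) and canonical
#'   `name` (`"KIND_k<size>"`).
#' @export
feature_bank_default <- function() {
  kinds <- setdiff(names(.filter_codes), "pixel_value")
  grid <- expand.grid(kernel_size = .bank_kernel_sizes, filter_kind = kinds,
                      stringsAsFactors = FALSE)[, 2:1]
  bank <- tibble::tibble(
    filter_kind = c("pixel_value", grid$filter_kind),
    kernel_size = c(NA_integer_, grid$kernel_size),
    name = c("PIXEL_VALUE",
             paste0(toupper(grid$filter_kind), "_k", grid$kernel_size))
  )
  bank <- tibble::add_column(bank, index = seq_len(nrow(bank)) - 1L,
                             .before = 1L)
  class(bank) <- c("feature_bank", class(bank))
  bank
}

#' Build a custom feature bank
#'
#' @param filter_kind Character vector of filter kinds (see
#'   [feature_bank_default()] for the available kinds).
#' @param kernel_size Integer vector of odd kernel sizes in voxels
#'   (`NA` for `pixel_value`), recycled against `filter_kind`.
#' @return A `feature_bank` tibble.
#' @export
feature_bank <- function(filter_kind, kernel_size = NA_integer_) {
  filter_kind <- as.character(filter_kind)
  kernel_size <- suppressWarnings(as.integer(rep_len(kernel_size, length(filter_kind))))
  bad <- setdiff(filter_kind, names(.filter_codes))
  if (length(bad)) stop("unknown filter kind(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  ks <- kernel_size[filter_kind != "pixel_value"]
  if (any(is.na(ks)) || any(ks < 3L) || any(ks %% 2L == 0L))
    stop("kernel_size must be an odd integer >= 3 for every non-pixel_value filter",
         call. = FALSE)
  name <- ifelse(filter_kind == "pixel_value", "PIXEL_VALUE",
                 paste0(toupper(filter_kind), "_k", kernel_size))
  if (anyDuplicated(name)) stop("feature names must be unique", call. = FALSE)
  bank <- tibble::tibble(index = seq_along(name) - 1L,
                         filter_kind = filter_kind,
                         kernel_size = ifelse(filter_kind == "pixel_value",
                                              NA_integer_, kernel_size),
                         name = name)
  class(bank) <- c("feature_bank", class(bank))
  bank
}

# schema fingerprint: hash of the ordered feature names
bank_fingerprint <- function(bank) rlang::hash(bank$name)

bank_codes <- function(bank) {
  list(kinds = unname(.filter_codes[bank$filter_kind]),
       ks = ifelse(is.na(bank$kernel_size), 1L, bank$kernel_size))
}

# halo (in voxels) needed so a tile reproduces the monolithic result:
# kernel radius, +2 for the finite-difference stencils chained after the
# Gaussian smoothing stage
bank_halo <- function(bank) {
  ks <- bank$kernel_size[!is.na(bank$kernel_size)]
  if (!length(ks)) return(0L)
  as.integer(max(ks) %/% 2L + 2L)
}

#' Serialize / read a feature bank specification as JSON
#'
#' @param bank A `feature_bank` tibble.
#' @param path File path.
#' @return `read_feature_bank` returns a `feature_bank` tibble.
#' @export
write_feature_bank <- function(bank, path) {
  jsonlite::write_json(
    list(features = bank[, c("filter_kind", "kernel_size", "name")]),
    path, auto_unbox = TRUE, digits = I(17), na = "null")
  invisible(path)
}

#' @rdname write_feature_bank
#' @export
read_feature_bank <- function(path) {
  obj <- jsonlite::fromJSON(path)
  feature_bank(obj$features$filter_kind, obj$features$kernel_size)
}

#' Compute features at selected voxels
#'
#' Evaluates every filter of the bank centered at each requested voxel.
#' Borders are handled by mirror padding. The per-voxel evaluation is
#' exactly consistent with the dense full-volume path of
#' [compute_features_full()].
#'
#' @param vol A [volume_stack()] (or 3D array).
#' @param voxel_ids Integer vector of linear voxel IDs (0-based, x fastest).
#' @param bank A `feature_bank`; defaults to [feature_bank_default()].
#' @return A tibble of class `feature_matrix`: column `voxel_id` followed by
#'   one column per feature, rows ordered as `voxel_ids`. The bank
#'   fingerprint is stored in attribute `spec_hash`.
#' @export
compute_features_at <- function(vol, voxel_ids, bank = feature_bank_default()) {
  v <- as_vol_array(vol)
  dims <- dim(v)
  voxel_ids <- as.integer(voxel_ids)
  if (any(voxel_ids < 0L) || any(voxel_ids >= prod(dims)))
    stop("voxel id out of bounds", call. = FALSE)
  cd <- bank_codes(bank)
  m <- cpp_features_at(as.numeric(v), as.integer(dims), voxel_ids,
                       as.integer(cd$kinds), as.integer(cd$ks))
  colnames(m) <- bank$name
  fm <- tibble::as_tibble(m)
  fm <- tibble::add_column(fm, voxel_id = voxel_ids, .before = 1L)
  attr(fm, "spec_hash") <- bank_fingerprint(bank)
  class(fm) <- c("feature_matrix", class(fm))
  fm
}

#' Compute dense features for every voxel
#'
#' Produces one scalar response volume per feature descriptor. Large
#' volumes are processed blockwise with a mirror-padded halo so that the
#' tiled result is identical to the monolithic computation.
#'
#' @param vol A [volume_stack()] (or 3D array).
#' @param bank A `feature_bank`.
#' @param block_shape Optional integer vector of length 3: tile shape in
#'   voxels. `NULL` computes the volume in one piece. Every entry must be
#'   at least the largest kernel size in the bank.
#' @return A named list of class `feature_volumes`, one 3D array per
#'   feature, in bank order; attributes `spec_hash` and `dims`.
#' @export
compute_features_full <- function(vol, bank = feature_bank_default(),
                                  block_shape = NULL) {
  v <- as_vol_array(vol)
  dims <- dim(v)
  cd <- bank_codes(bank)
  out <- vector("list", nrow(bank))
  names(out) <- bank$name
  if (is.null(block_shape)) {
    for (j in seq_len(nrow(bank)))
      out[[j]] <- cpp_filter_dense(as.numeric(v), as.integer(dims),
                                   cd$kinds[j], cd$ks[j])
  } else {
    block_shape <- rep_len(as.integer(block_shape), 3L)
    kmax <- max(bank$kernel_size, 1L, na.rm = TRUE)
    if (any(block_shape < kmax))
      stop("block_shape must be >= the largest kernel size (", kmax, ")",
           call. = FALSE)
    halo <- bank_halo(bank)
    for (j in seq_len(nrow(bank))) out[[j]] <- array(0, dims)
    starts <- lapply(seq_len(3L), function(a) seq(1L, dims[a], by = block_shape[a]))
    for (sz in starts[[3]]) for (sy in starts[[2]]) for (sx in starts[[1]]) {
      lo <- c(sx, sy, sz)
      hi <- pmin(lo + block_shape - 1L, dims)
      # mirror-extended index ranges (matches the C++ boundary rule)
      idx <- lapply(seq_len(3L), function(a)
        mirror_index(seq(lo[a] - halo, hi[a] + halo), dims[a]))
      tile <- v[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
      tdims <- dim(tile)
      keep <- lapply(seq_len(3L), function(a) seq(halo + 1L, halo + hi[a] - lo[a] + 1L))
      for (j in seq_len(nrow(bank))) {
        f <- cpp_filter_dense(as.numeric(tile), as.integer(tdims),
                              cd$kinds[j], cd$ks[j])
        out[[j]][lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
          f[keep[[1]], keep[[2]], keep[[3]]]
      }
    }
  }
  structure(out, spec_hash = bank_fingerprint(bank), dims = dims,
            class = "feature_volumes")
}

# symmetric (edge-included) mirror of 1-based indices into [1, n]
mirror_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j < 0L, j + 2L * n, j)
  as.integer(ifelse(j < n, j, 2L * n - 1L - j) + 1L)
}

#' Flatten dense feature volumes into a feature matrix
#'
#' @param fv A `feature_volumes` list from [compute_features_full()].
#' @param voxel_ids Optional voxel IDs to extract (default: all voxels in
#'   ID order).
#' @return Numeric matrix, one row per voxel, one column per feature.
#' @export
feature_volumes_matrix <- function(fv, voxel_ids = NULL) {
  dims <- attr(fv, "dims")
  if (is.null(voxel_ids)) {
    m <- vapply(fv, as.numeric, numeric(prod(dims)))
  } else {
    idx <- as.integer(voxel_ids) + 1L
    m <- vapply(fv, function(a) a[idx], numeric(length(idx)))
    if (length(idx) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(fv)))
  }
  attr(m, "spec_hash") <- attr(fv, "spec_hash")
  m
}

# feature_matrix tibble -> plain numeric matrix (drops voxel_id)
feature_matrix_values <- function(fm) {
  m <- as.matrix(fm[, setdiff(names(fm), "voxel_id"), drop = FALSE])
  attr(m, "spec_hash") <- attr(fm, "spec_hash")
  m
}
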