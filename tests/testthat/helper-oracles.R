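# Independent brute-force oracles for the filter bank and stroke
# voxelization, written as plain nested-loop R so they share no code path
# with the package internals.

# symmetric (edge-included) mirror of a 0-based index into [0, n-1]
oracle_mirror <- function(i, n) {
  if (n == 1) return(0L)
  p <- 2L * n
  i <- i %% p
  if (i < 0) i <- i + p
  if (i < n) i else p - 1L - i
}

# k^3 neighborhood values (mirror-padded) around 0-based (x, y, z)
oracle_window <- function(v, x, y, z, k) {
  r <- k %/% 2
  d <- dim(v)
  out <- numeric(k^3)
  m <- 1L
  for (dz in -r:r) for (dy in -r:r) for (dx in -r:r) {
    out[m] <- v[oracle_mirror(x + dx, d[1]) + 1L,
                oracle_mirror(y + dy, d[2]) + 1L,
                oracle_mirror(z + dz, d[3]) + 1L]
    m <- m + 1L
  }
  out
}

oracle_gauss_weights <- function(k, sigma) {
  r <- k %/% 2
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w / sum(w)
}

# Gaussian-smoothed value at one voxel by direct 3D weighted sum
oracle_gauss_at <- function(v, x, y, z, k, sigma = k / 6) {
  w1 <- oracle_gauss_weights(k, sigma)
  w3 <- as.numeric(outer(outer(w1, w1), w1))  # dx fastest, matches window
  sum(w3 * oracle_window(v, x, y, z, k))
}

# one filter response at one voxel, every kind by direct enumeration
oracle_filter_at <- function(v, x, y, z, kind, k) {
  win <- function() oracle_window(v, x, y, z, k)
  smoothed <- function(dx = 0, dy = 0, dz = 0) {
    d <- dim(v)
    oracle_gauss_at(v, oracle_mirror(x + dx, d[1]),
                    oracle_mirror(y + dy, d[2]),
                    oracle_mirror(z + dz, d[3]), k)
  }
  switch(kind,
    pixel_value = v[x + 1, y + 1, z + 1],
    gaussian = oracle_gauss_at(v, x, y, z, k),
    mean = mean(win()),
    median = median(win()),
    minimum = min(win()),
    maximum = max(win()),
    range = max(win()) - min(win()),
    stddev = {
      w <- win()
      sqrt(max(mean(w^2) - mean(w)^2, 0))
    },
    gradient_magnitude = {
      gx <- (smoothed(1, 0, 0) - smoothed(-1, 0, 0)) / 2
      gy <- (smoothed(0, 1, 0) - smoothed(0, -1, 0)) / 2
      gz <- (smoothed(0, 0, 1) - smoothed(0, 0, -1)) / 2
      sqrt(gx^2 + gy^2 + gz^2)
    },
    laplacian_of_gaussian = {
      smoothed(1, 0, 0) + smoothed(-1, 0, 0) + smoothed(0, 1, 0) +
        smoothed(0, -1, 0) + smoothed(0, 0, 1) + smoothed(0, 0, -1) -
        6 * smoothed()
    },
    difference_of_gaussians =
      oracle_gauss_at(v, x, y, z, k, k / 6) -
        oracle_gauss_at(v, x, y, z, k, k / 3),
    hessian_max_eigen = {
      s <- function(dx, dy, dz) smoothed(dx, dy, dz)
      dxx <- s(1, 0, 0) - 2 * s(0, 0, 0) + s(-1, 0, 0)
      dyy <- s(0, 1, 0) - 2 * s(0, 0, 0) + s(0, -1, 0)
      dzz <- s(0, 0, 1) - 2 * s(0, 0, 0) + s(0, 0, -1)
      dxy <- (s(1, 1, 0) - s(1, -1, 0) - s(-1, 1, 0) + s(-1, -1, 0)) / 4
      dxz <- (s(1, 0, 1) - s(1, 0, -1) - s(-1, 0, 1) + s(-1, 0, -1)) / 4
      dyz <- (s(0, 1, 1) - s(0, 1, -1) - s(0, -1, 1) + s(0, -1, -1)) / 4
      H <- matrix(c(dxx, dxy, dxz, dxy, dyy, dyz, dxz, dyz, dzz), 3, 3)
      max(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
    },
    stop("oracle: unknown kind ", kind))
}

# all voxels within `radius` of a polyline, by exhaustive scan
oracle_stroke_voxels <- function(points, radius, dims) {
  seg_dist <- function(p, a, b) {
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) 0 else min(max(sum((p - a) * ab) / len2, 0), 1)
    sqrt(sum((p - a - t * ab)^2))
  }
  ids <- integer(0)
  for (z in 0:(dims[3] - 1)) for (y in 0:(dims[2] - 1))
    for (x in 0:(dims[1] - 1)) {
      p <- c(x, y, z)
      d <- Inf
      if (nrow(points) == 1L) {
        d <- sqrt(sum((p - points[1, ])^2))
      } else {
        for (i in seq_len(nrow(points) - 1L))
          d <- min(d, seg_dist(p, points[i, ], points[i + 1L, ]))
      }
      if (d <= radius)
        ids <- c(ids, x + dims[1] * (y + dims[2] * z))
    }
  ids
}
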