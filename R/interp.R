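# Trilinear interpolation of 3-D volumes at world-coordinate points.

# Precompute the 8 corner linear indices and weights for world points
# (n x 3). Points outside the voxel-center hull get ok = FALSE.
trilinear_weights <- function(vol, pts) {
  d <- dim(vol$data)
  cc <- world_to_voxel(pts, vol)             # continuous 0-based coords
  ok <- cc[, 1] >= 0 & cc[, 1] <= d[1] - 1 &
        cc[, 2] >= 0 & cc[, 2] <= d[2] - 1 &
        cc[, 3] >= 0 & cc[, 3] <= d[3] - 1
  cc[!ok, ] <- 0
  i0 <- pmin(floor(cc), rep(d - 2, each = nrow(cc)))
  i0 <- pmax(i0, 0)
  fr <- cc - i0
  n <- nrow(cc)
  idx <- matrix(0L, n, 8L)
  w <- matrix(0, n, 8L)
  corner <- 0L
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    corner <- corner + 1L
    ii <- i0[, 1] + dx; jj <- i0[, 2] + dy; kk <- i0[, 3] + dz
    idx[, corner] <- as.integer(1 + ii + d[1] * (jj + d[2] * kk))
    w[, corner] <-
      (if (dx == 1) fr[, 1] else 1 - fr[, 1]) *
      (if (dy == 1) fr[, 2] else 1 - fr[, 2]) *
      (if (dz == 1) fr[, 3] else 1 - fr[, 3])
  }
  list(idx = idx, w = w, ok = ok)
}

# Trilinear interpolation; returns NA outside the voxel-center hull.
trilinear <- function(vol, pts, weights = NULL) {
  vol <- as_volume3d(vol)
  tw <- weights %||% trilinear_weights(vol, pts)
  v <- as.numeric(vol$data)
  out <- rowSums(matrix(v[tw$idx], ncol = 8L) * tw$w)
  out[!tw$ok] <- NA_real_
  out
}

# Nearest-neighbour lookup (for masks / labels).
nearest_lookup <- function(vol, pts) {
  vol <- as_volume3d(vol)
  d <- dim(vol$data)
  cc <- round(world_to_voxel(pts, vol)) + 1
  ok <- cc[, 1] >= 1 & cc[, 1] <= d[1] &
        cc[, 2] >= 1 & cc[, 2] <= d[2] &
        cc[, 3] >= 1 & cc[, 3] <= d[3]
  out <- rep(NA, nrow(cc))
  lin <- cc[ok, 1] + d[1] * (cc[ok, 2] - 1 + d[2] * (cc[ok, 3] - 1))
  out[ok] <- vol$data[lin]
  out
}
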