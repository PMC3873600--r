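# Exact Euclidean distance transform with feature (nearest-point)
# propagation, via the separable lower-envelope-of-parabolas algorithm
# applied along each axis in turn. Distances are measured in mm between
# voxel centers and support anisotropic spacing.

# 1-D squared-distance transform of sampled function f at positions x.
# Returns d (squared distances) and arg (index of the winning parabola).
dt1d <- function(f, x) {
  n <- length(f)
  fin <- which(is.finite(f))
  if (length(fin) == 0L) return(list(d = f, arg = rep(NA_integer_, n)))
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- fin[1L]; z[1L] <- -Inf; z[2L] <- Inf
  if (length(fin) > 1L) for (q in fin[-1L]) {
    repeat {
      vk <- v[k]
      s <- ((f[q] + x[q]^2) - (f[vk] + x[vk]^2)) / (2 * (x[q] - x[vk]))
      if (s <= z[k]) { k <- k - 1L } else break
    }
    k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  d <- numeric(n); arg <- integer(n)
  j <- 1L
  for (q in seq_len(n)) {
    while (z[j + 1L] < x[q]) j <- j + 1L
    vq <- v[j]
    d[q] <- (x[q] - x[vq])^2 + f[vq]
    arg[q] <- vq
  }
  list(d = d, arg = arg)
}

#' Euclidean distance transform of a binary mask
#'
#' For every voxel of `mask` computes the exact Euclidean distance (mm)
#' from its center to the nearest background (`FALSE`) voxel center,
#' together with the 1-based grid index of that nearest background
#' voxel (the feature transform).
#'
#' @param mask logical [volume3d] (or 3-D logical array with unit
#'   spacing).
#' @return list with `dist` (3-D array, mm; 0 on background), and `feat`
#'   (integer array `dims x 3` of nearest-background voxel indices).
#' @export
distance_transform <- function(mask) {
  if (inherits(mask, "volume3d")) {
    sp <- mask$spacing; m <- mask$data
  } else { sp <- c(1, 1, 1); m <- mask }
  d <- dim(m)
  f <- array(ifelse(m, Inf, 0), d)
  fx <- array(NA_integer_, d); fy <- array(NA_integer_, d); fz <- array(NA_integer_, d)
  x1 <- (seq_len(d[1]) - 1) * sp[1]
  x2 <- (seq_len(d[2]) - 1) * sp[2]
  x3 <- (seq_len(d[3]) - 1) * sp[3]
  # pass 1: along x; feature x-index per line
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) {
    r <- dt1d(f[, j, k], x1)
    f[, j, k] <- r$d
    fx[, j, k] <- r$arg
  }
  # pass 2: along y; compose features (read from copies, lines alias)
  for (k in seq_len(d[3])) for (i in seq_len(d[1])) {
    r <- dt1d(f[i, , k], x2)
    f[i, , k] <- r$d
    ok <- !is.na(r$arg)
    old_fx <- fx[i, , k]
    fy[i, ok, k] <- r$arg[ok]
    fx[i, ok, k] <- old_fx[r$arg[ok]]
  }
  # pass 3: along z; compose features
  for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    r <- dt1d(f[i, j, ], x3)
    f[i, j, ] <- r$d
    ok <- !is.na(r$arg)
    old_fx <- fx[i, j, ]; old_fy <- fy[i, j, ]
    fz[i, j, ok] <- r$arg[ok]
    fx[i, j, ok] <- old_fx[r$arg[ok]]
    fy[i, j, ok] <- old_fy[r$arg[ok]]
  }
  feat <- array(NA_integer_, c(d, 3L))
  feat[, , , 1] <- fx; feat[, , , 2] <- fy; feat[, , , 3] <- fz
  list(dist = array(sqrt(pmax(f, 0)), d), feat = feat)
}
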