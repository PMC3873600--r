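# Fractional anisotropy from diffusion-tensor eigenvalues, FA volumes
# from tensor fields, and maximum-FA projection along model spokes onto
# the skeleton surface.

#' Fractional anisotropy from tensor eigenvalues
#'
#' Computes FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||,
#' clamped to `[0, 1]`. Vectorized over voxels. An all-zero eigenvalue
#' triple yields 0 with a warning (FA is undefined there).
#'
#' @param l1,l2,l3 numeric vectors of eigenvalues (any order).
#' @return numeric vector of FA values in `[0, 1]`. Attribute
#'   `n_negative` counts inputs with a negative eigenvalue (physically
#'   invalid but numerically possible).
#' @export
fa_from_eigenvalues <- function(l1, l2, l3) {
  n <- max(length(l1), length(l2), length(l3))
  l1 <- rep_len(as.numeric(l1), n)
  l2 <- rep_len(as.numeric(l2), n)
  l3 <- rep_len(as.numeric(l3), n)
  ssq <- l1^2 + l2^2 + l3^2
  zero <- ssq == 0
  if (any(zero))
    warning("fa_from_eigenvalues: ", sum(zero),
            " all-zero eigenvalue triple(s); FA set to 0")
  lbar <- (l1 + l2 + l3) / 3
  dev <- (l1 - lbar)^2 + (l2 - lbar)^2 + (l3 - lbar)^2
  fa <- sqrt(1.5) * sqrt(dev) / sqrt(ifelse(zero, 1, ssq))
  fa[zero] <- 0
  out <- pmin(pmax(fa, 0), 1)
  attr(out, "n_negative") <- sum(l1 < 0 | l2 < 0 | l3 < 0)
  out
}

# eigenvalues of symmetric 3x3 tensors, vectorized (trigonometric
# closed form); components in order xx, xy, xz, yy, yz, zz
symm3_eigenvalues <- function(xx, xy, xz, yy, yz, zz) {
  q <- (xx + yy + zz) / 3
  a <- xx - q; b <- yy - q; c <- zz - q
  p2 <- (a^2 + b^2 + c^2 + 2 * (xy^2 + xz^2 + yz^2)) / 6
  p <- sqrt(pmax(p2, 0))
  # det of (A - qI) / p
  safe_p <- ifelse(p > 0, p, 1)
  da <- a / safe_p; db <- b / safe_p; dc <- c / safe_p
  dxy <- xy / safe_p; dxz <- xz / safe_p; dyz <- yz / safe_p
  detB <- da * (db * dc - dyz^2) - dxy * (dxy * dc - dyz * dxz) +
    dxz * (dxy * dyz - db * dxz)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  iso <- p == 0
  e1[iso] <- q[iso]; e2[iso] <- q[iso]; e3[iso] <- q[iso]
  cbind(e1, e2, e3)
}

#' FA volume from a diffusion-tensor field
#'
#' Applies [fa_from_eigenvalues()] voxelwise to a symmetric tensor
#' field. Background voxels (all six components zero) map to FA 0
#' without a warning.
#'
#' @param tensors 4-D numeric array `X x Y x Z x 6` with unique tensor
#'   components in the order `xx, xy, xz, yy, yz, zz`, or a list with
#'   fields `data` (that array), `spacing`, `origin`.
#' @param spacing,origin world geometry (mm), used when `tensors` is a
#'   bare array.
#' @return an FA [volume3d] with values in `[0, 1]`; attribute
#'   `n_negative` counts voxels with a negative eigenvalue.
#' @export
fa_volume <- function(tensors, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.list(tensors)) {
    spacing <- tensors$spacing %||% spacing
    origin <- tensors$origin %||% origin
    tensors <- tensors$data
  }
  d <- dim(tensors)
  if (length(d) != 4L || d[4] != 6L)
    abort("fa_volume: expected an X x Y x Z x 6 tensor array")
  cmp <- lapply(1:6, function(j) as.numeric(tensors[, , , j]))
  bg <- Reduce(`&`, lapply(cmp, function(x) x == 0))
  ev <- symm3_eigenvalues(cmp[[1]], cmp[[2]], cmp[[3]], cmp[[4]], cmp[[5]], cmp[[6]])
  fa <- suppressWarnings(fa_from_eigenvalues(ev[, 1], ev[, 2], ev[, 3]))
  nneg <- attr(fa, "n_negative")
  fa[bg] <- 0
  out <- volume3d(array(as.numeric(fa), d[1:3]), spacing = spacing, origin = origin)
  attr(out, "n_negative") <- nneg
  out
}

# sample-point table for max projection: per vertex and side,
# fractions (0:n)/n with n a power of two chosen so the along-spoke
# step is <= step_fraction * voxel; power-of-two counts make sample
# sets nested under step refinement (monotone max)
projection_samples <- function(model, step_fraction) {
  step_mm <- step_fraction * min(model$spacing)
  nvert <- nrow(model$vertices)
  pts <- list(); vid <- list(); m <- 0L
  for (s in 1:2) {
    len <- model$spoke_lengths[, s]
    nsteps <- 2^ceiling(log2(pmax(len / step_mm, 1)))
    for (i in seq_len(nvert)) {
      fr <- (0:nsteps[i]) / nsteps[i]
      m <- m + 1L
      pts[[m]] <- model$vertices[rep(i, length(fr)), , drop = FALSE] +
        outer(fr, model$spokes[i, , s])
      vid[[m]] <- rep(i, length(fr))
    }
  }
  list(pts = do.call(rbind, pts), vid = unlist(vid))
}

#' Precompute a projection cache
#'
#' Computes spoke sample points and trilinear interpolation weights for
#' a model and a volume geometry once, so that [project_max_fa()] can be
#' applied cheaply to many subjects sharing the same grid.
#'
#' @param model a `tract_model`.
#' @param geometry a [volume3d] supplying grid dims, spacing, origin
#'   (its data values are ignored).
#' @param step_fraction along-spoke sampling step as a fraction of the
#'   voxel size.
#' @return an opaque cache object for `project_max_fa(..., cache = )`.
#' @export
projection_cache <- function(model, geometry, step_fraction = 0.25) {
  stopifnot(inherits(model, "tract_model"))
  geometry <- as_volume3d(geometry)
  smp <- projection_samples(model, step_fraction)
  tw <- trilinear_weights(geometry, smp$pts)
  nvert <- nrow(model$vertices)
  ord <- order(smp$vid)
  structure(list(idx = tw$idx[ord, , drop = FALSE],
                 w = tw$w[ord, , drop = FALSE],
                 ok = tw$ok[ord], vid = smp$vid[ord],
                 nvert = nvert, dims = dim(geometry$data),
                 step_fraction = step_fraction),
            class = "projection_cache")
}

#' Project maximum FA along spokes onto the skeleton
#'
#' For every model vertex, samples the FA volume by trilinear
#' interpolation at evenly spaced depth fractions along both spokes
#' (skeleton to boundary on each side) and takes the maximum, the
#' tract-specific data-reduction step that projects one FA value per
#' skeleton point.
#'
#' @param fa an FA [volume3d] in the model's world frame.
#' @param model a `tract_model`.
#' @param step_fraction along-spoke sampling step as a fraction of the
#'   voxel size (default 0.25 voxel).
#' @param cache optional [projection_cache()] for repeated projection of
#'   subjects on one grid.
#' @param name,subject labels stored on the result.
#' @return a `vertex_scalar_map`: list with `values` (one scalar per
#'   vertex), `name`, `subject`.
#' @export
project_max_fa <- function(fa, model, step_fraction = 0.25, cache = NULL,
                           name = "FA_max", subject = NA_character_) {
  fa <- as_volume3d(fa)
  if (is.null(cache)) {
    cache <- projection_cache(model, fa, step_fraction)
  } else {
    stopifnot(inherits(cache, "projection_cache"))
    if (!identical(cache$dims, dim(fa$data)))
      abort("project_max_fa: cache grid does not match the FA volume")
  }
  v <- as.numeric(fa$data)
  vals <- rowSums(matrix(v[cache$idx], ncol = 8L) * cache$w)
  vals[!cache$ok] <- -Inf
  mx <- rep(-Inf, cache$nvert)
  # segment maxima: vid is sorted, so each vertex is one contiguous run
  brk <- c(which(diff(cache$vid) != 0L), length(cache$vid))
  st <- c(1L, head(brk, -1L) + 1L)
  seg_max <- vapply(seq_along(brk),
                    function(g) max(vals[st[g]:brk[g]]), numeric(1))
  mx[cache$vid[st]] <- seg_max
  if (any(!is.finite(mx))) {
    bad <- which(!is.finite(mx))[1]
    abort("project_max_fa: all spoke samples outside the volume at vertex ", bad)
  }
  structure(list(values = mx, name = name, subject = subject),
            class = "vertex_scalar_map")
}
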