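# Synthetic tract phantoms: tube, bent tube, and sheet masks standing in
# for tractography-defined white-matter tracts.

#' Specify a tract phantom
#'
#' Describes a binary tract-shaped volume: a straight tube, a bent tube
#' following spline-interpolated control points, or an axis-aligned
#' sheet (slab). All geometric parameters are in mm; the default voxel
#' size (2.2 mm isotropic) matches a typical clinical diffusion
#' acquisition.
#'
#' @param shape_kind one of `"tube"`, `"bent_tube"`, `"sheet"`.
#' @param grid_dims integer length-3, grid size in voxels.
#' @param voxel_size_mm isotropic voxel edge length (mm).
#' @param radius_mm tube radius (tube/bent_tube).
#' @param half_thickness_mm sheet half-thickness (sheet).
#' @param control_points_mm numeric matrix (k x 3) of centerline control
#'   points in mm (bent_tube; ignored otherwise). For `"tube"` the
#'   centerline is the grid's central x-axis.
#' @param extent_mm for sheets, in-plane half-extents (length 2, mm);
#'   `NULL` fills the grid up to the margin.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape_kind = c("tube", "bent_tube", "sheet"),
                         grid_dims = c(36L, 18L, 18L),
                         voxel_size_mm = 2.2,
                         radius_mm = 4.4,
                         half_thickness_mm = 4.4,
                         control_points_mm = NULL,
                         extent_mm = NULL) {
  shape_kind <- match.arg(shape_kind)
  grid_dims <- as.integer(rep_len(grid_dims, 3L))
  if (any(grid_dims < 8L)) abort("phantom_spec: grid_dims must be >= 8 voxels")
  if (!is.finite(voxel_size_mm) || voxel_size_mm <= 0)
    abort("phantom_spec: voxel_size_mm must be positive")
  if (shape_kind == "bent_tube") {
    if (is.null(control_points_mm))
      abort("phantom_spec: bent_tube requires control_points_mm")
    control_points_mm <- matrix(as.numeric(control_points_mm), ncol = 3L)
    if (nrow(control_points_mm) < 2L)
      abort("phantom_spec: need at least 2 control points")
  }
  structure(list(shape_kind = shape_kind, grid_dims = grid_dims,
                 voxel_size_mm = voxel_size_mm, radius_mm = radius_mm,
                 half_thickness_mm = half_thickness_mm,
                 control_points_mm = control_points_mm,
                 extent_mm = extent_mm),
            class = "phantom_spec")
}

# dense centerline polyline (n x 3, mm) for a phantom spec
phantom_centerline <- function(spec, step_mm = spec$voxel_size_mm / 4) {
  vs <- spec$voxel_size_mm
  ctr <- (spec$grid_dims - 1) / 2 * vs
  if (spec$shape_kind == "tube") {
    margin <- 2.5 * vs + spec$radius_mm
    x <- seq(margin, (spec$grid_dims[1] - 1) * vs - margin, by = step_mm)
    return(cbind(x, ctr[2], ctr[3]))
  }
  cp <- spec$control_points_mm
  # natural cubic spline through control points, chord-length parameterized
  s <- c(0, cumsum(sqrt(rowSums(diff(cp)^2))))
  if (any(diff(s) <= 0)) abort("phantom_centerline: coincident control points")
  ss <- seq(0, max(s), by = step_mm)
  sapply(1:3, function(j) stats::spline(s, cp[, j], xout = ss, method = "natural")$y)
}

#' Generate a binary tract phantom
#'
#' Rasterizes the phantom described by a [phantom_spec()] onto its voxel
#' grid. The resulting mask is guaranteed to be a single 6-connected
#' component that keeps a margin of at least 2 voxels from every grid
#' boundary face; geometry that would violate the margin is rejected.
#'
#' @param spec a [phantom_spec].
#' @return a logical [volume3d] mask (origin at 0, spacing from the spec).
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) abort("make_phantom: not a phantom_spec")
  d <- spec$grid_dims
  vs <- spec$voxel_size_mm
  ctr <- (d - 1) / 2 * vs
  ax <- lapply(1:3, function(j) ((1:d[j]) - 1) * vs)
  if (spec$shape_kind == "sheet") {
    h <- spec$half_thickness_mm
    ext <- spec$extent_mm %||% ((d[1:2] - 1) / 2 * vs - 2.5 * vs)
    inx <- abs(ax[[1]] - ctr[1]) <= ext[1]
    iny <- abs(ax[[2]] - ctr[2]) <= ext[2]
    inz <- abs(ax[[3]] - ctr[3]) <= h
    mask <- array(FALSE, d)
    mask[inx, iny, inz] <- TRUE
  } else {
    cl <- phantom_centerline(spec)
    r <- spec$radius_mm
    # distance from each voxel center to the polyline, chunked over z-slices
    mask <- array(FALSE, d)
    xy <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]]))
    for (k in seq_len(d[3])) {
      p <- cbind(xy, ax[[3]][k])
      # squared distance to nearest centerline sample
      d2 <- matrix(Inf, nrow(p), 1)
      for (start in seq(1, nrow(cl), by = 256)) {
        blk <- cl[start:min(start + 255, nrow(cl)), , drop = FALSE]
        cross <- p %*% t(blk)
        dd <- outer(rowSums(p^2), rowSums(blk^2), "+") - 2 * cross
        d2 <- pmin(d2, matrixStats_rowMins(dd))
      }
      mask[, , k] <- d2 <= r^2
    }
  }
  if (!any(mask)) abort("make_phantom: geometry produced an empty mask")
  # margin check: >= 2 voxels clear of every boundary face
  idx <- which(mask, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  faces <- c("x-min", "y-min", "z-min")[lo <= 2]
  faces <- c(faces, c("x-max", "y-max", "z-max")[hi >= d - 1])
  if (length(faces))
    abort("make_phantom: mask violates the 2-voxel margin at face(s): ",
          paste(faces, collapse = ", "))
  nc <- n_components6(mask)
  if (nc != 1L)
    abort("make_phantom: mask has ", nc, " 6-connected components; expected 1")
  volume3d(mask, spacing = rep(vs, 3), origin = c(0, 0, 0))
}

# rowMins without extra dependencies
matrixStats_rowMins <- function(m) {
  do.call(pmin, as.data.frame(m))
}
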