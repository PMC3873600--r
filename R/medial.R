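# Discrete medial model of a binary tract volume: a skeleton surface
# mesh with per-vertex spokes to the nearest boundary point on each
# side, spoke lengths, normals, and surface-area elements.
#
# The construction is a discrete stand-in for a continuous deformable
# medial ("skeleton + boundary") model: medial voxels are detected where
# the Euclidean feature transform jumps across the voxel (two distant
# nearest-boundary points), the largest 26-connected medial sheet is
# kept and pruned, regularized to one-voxel thickness by binning onto
# its principal tangent plane, and triangulated as a height field over
# that plane. Near-tubular shapes whose medial set degenerates toward a
# curve are thickened to a thin ribbon so a surface strip with nonzero
# area is always returned.

# edge list between 26-adjacent TRUE voxels (1-based linear indices)
grid_edges26 <- function(mask) {
  d <- dim(mask)
  lin <- array(seq_len(prod(d)), d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[offs[, 1] > 0 |
               (offs[, 1] == 0 & offs[, 2] > 0) |
               (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), , drop = FALSE]
  out <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    ia <- lapply(1:3, function(ax) {
      if (o[ax] >= 0) seq_len(d[ax] - o[ax]) else (1 - o[ax]):d[ax]
    })
    ib <- lapply(1:3, function(ax) ia[[ax]] + o[ax])
    a <- lin[ia[[1]], ia[[2]], ia[[3]]]
    b <- lin[ib[[1]], ib[[2]], ib[[3]]]
    keep <- mask[a] & mask[b]
    out[[r]] <- cbind(a[keep], b[keep])
  }
  m <- do.call(rbind, out)
  storage.mode(m) <- "integer"
  m
}

largest_component26 <- function(set) {
  idx <- which(set)
  if (length(idx) == 0L) return(set)
  lab <- cpp_label_components(prod(dim(set)), grid_edges26(set), as.vector(set))
  tab <- tabulate(lab[idx])
  keep <- which.max(tab)
  out <- array(FALSE, dim(set))
  out[idx[lab[idx] == keep]] <- TRUE
  out
}

# remove voxels with <= 1 26-neighbours in the set, `iter` times
prune_spurs <- function(set, iter = 3L) {
  for (it in seq_len(iter)) {
    cnt <- array(0L, dim(set))
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      s <- set
      if (dx != 0) s <- shift3d(s, 1, dx, FALSE)
      if (dy != 0) s <- shift3d(s, 2, dy, FALSE)
      if (dz != 0) s <- shift3d(s, 3, dz, FALSE)
      cnt <- cnt + s
    }
    drop <- set & cnt <= 1L
    if (!any(drop)) break
    set <- set & !drop
  }
  set
}

validate_tract_mask <- function(vol) {
  m <- vol$data
  d <- dim(m)
  if (!any(m)) abort("build_medial_model: empty mask")
  idx <- which(m, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  if (any(lo <= 2L) || any(hi >= d - 1L))
    abort("build_medial_model: mask must keep a 2-voxel margin from the grid boundary")
  nc <- n_components6(m)
  if (nc != 1L)
    abort("build_medial_model: mask has ", nc,
          " 6-connected components; expected a single component")
  # cavities: background components that never touch the grid border
  bg <- label_components6(!m)
  labs <- setdiff(unique(as.vector(bg)), 0L)
  if (length(labs) > 1L) {
    border <- unique(c(bg[1, , ], bg[d[1], , ], bg[, 1, ], bg[, d[2], ],
                       bg[, , 1], bg[, , d[3]]))
    cav <- setdiff(labs, border)
    if (length(cav))
      abort("build_medial_model: mask has ", length(cav),
            " internal cavit", if (length(cav) == 1) "y" else "ies",
            "; fill holes before modeling")
  }
  invisible(TRUE)
}

#' Build a discrete medial model from a binary tract mask
#'
#' Constructs a skeleton surface mesh approximating the ridge of the
#' Euclidean distance transform of `mask`, with two spokes per vertex
#' (one per side of the skeleton) reaching the nearest boundary point,
#' spoke lengths, outward per-vertex normals, and per-vertex surface
#' area elements. All model output is in world mm.
#'
#' @param mask logical [volume3d]; must be one 6-connected component
#'   with a 2-voxel margin and no internal cavities.
#' @param medial_angle_deg minimum angle (degrees) between the
#'   nearest-boundary directions of a voxel's two neighbours along some
#'   axis for the voxel to be classed as medial. An ideal medial sheet
#'   separates boundary points in opposite directions (180 degrees); the
#'   default 160 keeps central sheets and thin tube axes while dropping
#'   the oblique edge wings of the exact medial axis.
#' @param min_depth_voxels minimum distance-transform value (in voxels)
#'   for a medial voxel; suppresses spurious boundary-adjacent ridges.
#' @param prune_iter iterations of spur pruning (each removes skeleton
#'   voxels with at most one 26-neighbour, i.e. branches shorter than
#'   `prune_iter` voxels).
#' @param mesh_resolution bin size for skeleton meshing as a multiple of
#'   the voxel size (1 = one vertex per voxel cell).
#' @param spoke_cone_deg half-angle (degrees) of the search cone around
#'   the vertex normal within which each spoke's nearest boundary point
#'   is sought; keeps spokes near-orthogonal to the boundary at skeleton
#'   rim vertices where an oblique boundary point can be closer.
#' @return an object of class `tract_model`: `vertices` (n x 3 mm),
#'   `triangles` (m x 3 indices), `edges`, `normals`, `spokes`
#'   (n x 3 x 2 array, sides `+`/`-`), `spoke_lengths` (n x 2 mm),
#'   `vertex_area` (mm^2), `vertex_depth` (distance-transform value at
#'   each vertex, mm), plus grid geometry and parameters.
#' @export
build_medial_model <- function(mask, medial_angle_deg = 160,
                               min_depth_voxels = 1.2,
                               prune_iter = 3L,
                               mesh_resolution = 1,
                               spoke_cone_deg = 70) {
  mask <- as_volume3d(mask)
  if (!is.logical(mask$data)) mask$data <- mask$data > 0.5
  validate_tract_mask(mask)
  m <- mask$data
  d <- dim(m)
  sp <- mask$spacing
  dt <- distance_transform(mask)
  dist <- dt$dist

  medial <- medial_voxels(mask, dt, medial_angle_deg, min_depth_voxels)
  if (!any(medial))
    abort("build_medial_model: no medial voxels detected; mask too thin?")
  medial <- largest_component26(medial)
  medial <- prune_spurs(medial, prune_iter)
  if (!any(medial)) abort("build_medial_model: skeleton vanished during pruning")

  cell <- mesh_resolution * min(sp)
  mesh <- mesh_skeleton(medial, mask, dist, cell)
  # thin (near-tubular) skeleton: thicken to a ribbon and re-mesh
  thick <- 0L
  while (is.null(mesh) && thick < 2L) {
    medial <- dilate6(medial) & m
    mesh <- mesh_skeleton(medial, mask, dist, cell)
    thick <- thick + 1L
  }
  if (is.null(mesh))
    abort("build_medial_model: could not mesh the skeleton (degenerate shape)")

  model <- structure(list(
    vertices = mesh$vertices, triangles = mesh$triangles,
    edges = triangle_edges(mesh$triangles),
    vertex_depth = mesh$depth,
    spacing = sp, origin = mask$origin, grid_dims = d,
    params = list(medial_angle_deg = medial_angle_deg,
                  min_depth_voxels = min_depth_voxels,
                  prune_iter = prune_iter, mesh_resolution = mesh_resolution,
                  thickened = thick)
  ), class = "tract_model")
  model$normals <- vertex_normals(model)
  sk <- compute_spokes(model, mask, spoke_cone_deg)
  model$spokes <- sk$spokes
  model$spoke_lengths <- sk$lengths
  model$vertex_area <- vertex_areas(model)
  model
}

# Medial (maximal-ball) voxel detection: a voxel is medial when the
# nearest boundary point in the direction cone opposing its nearest
# boundary point (angular separation > medial_angle_deg) is at most one
# voxel farther away than the nearest itself - i.e. the voxel's maximal
# inscribed ball touches the boundary on two well-separated sides. This
# is tie-break-free, keeps slab midplanes and thin tube axes, and drops
# the 45-degree edge wings of the exact medial axis (separation 90 deg).
medial_voxels <- function(mask, dt, medial_angle_deg, min_depth_voxels,
                          spread_tol_voxels = 1.6) {
  m <- mask$data
  sp <- mask$spacing
  dist <- dt$dist
  floor_mm <- min_depth_voxels * min(sp)
  tol_mm <- spread_tol_voxels * max(sp)
  cos_med <- cos(medial_angle_deg * pi / 180)
  tie_mm <- 0.1 * max(sp)           # exact-tie band for anchor points
  cand <- which(m & dist > floor_mm)
  out <- array(FALSE, dim(m))
  if (length(cand) == 0L) return(out)
  bnd <- dilate6(m) & !m
  bw <- voxel_to_world(which(bnd, arr.ind = TRUE), mask)
  vw <- voxel_to_world(arrayInd(cand, dim(m)), mask)
  bb2 <- rowSums(bw^2)
  keep <- logical(length(cand))
  chunk <- 256L
  for (start in seq(1L, length(cand), by = chunk)) {
    ix <- start:min(start + chunk - 1L, length(cand))
    V <- vw[ix, , drop = FALSE]
    D2 <- bb2 - 2 * (bw %*% t(V)) +
      matrix(rowSums(V^2), nrow(bw), length(ix), byrow = TRUE)
    for (c in seq_along(ix)) {
      dd <- sqrt(pmax(D2[, c], .Machine$double.eps))
      d1 <- min(dd)
      # any near-nearest anchor with an opposing boundary point at most
      # tol farther away makes the voxel medial; trying every anchor in
      # the tie band keeps the test independent of nearest-point ties
      anchors <- which(dd <= d1 + tie_mm)
      if (length(anchors) > 8L) anchors <- anchors[order(dd[anchors])[1:8]]
      near <- which(dd <= d1 + tol_mm)
      dvec <- bw[near, , drop = FALSE] - matrix(V[c, ], length(near), 3L,
                                                byrow = TRUE)
      dnrm <- dvec / dd[near]
      for (a in anchors) {
        ca <- dnrm %*% (dvec[match(a, near), ] / dd[a])
        if (any(ca < cos_med)) { keep[ix[c]] <- TRUE; break }
      }
    }
  }
  out[cand[keep]] <- TRUE
  out
}

# Bin medial voxels onto their principal tangent plane and triangulate
# the occupied cells. Returns NULL when the footprint is too thin to
# carry triangles (caller thickens and retries).
mesh_skeleton <- function(medial, mask, dist, cell) {
  idxm <- which(medial, arr.ind = TRUE)
  if (nrow(idxm) < 3L) return(NULL)
  w <- voxel_to_world(idxm, mask)
  ctr <- colMeans(w)
  pc <- prcomp(w, center = TRUE, scale. = FALSE)
  rot <- pc$rotation                       # columns: t1, t2, t3
  proj <- sweep(w, 2, ctr) %*% rot
  # anchor bins at the first point so lattice-aligned projections land
  # mid-bin; plain round() at half-integer bin edges is numerically
  # unstable (and banker's rounding merges/skips alternate bins)
  c1 <- as.integer(floor((proj[, 1] - proj[1, 1]) / cell + 0.5))
  c2 <- as.integer(floor((proj[, 2] - proj[1, 2]) / cell + 0.5))
  # a meshable sheet needs a footprint of at least 3 x 3 bin cells;
  # thinner sets (tube-like axes) are thickened by the caller first
  if (length(unique(c1)) < 3L || length(unique(c2)) < 3L) return(NULL)
  key <- paste(c1, c2)
  uk <- unique(key)
  id <- match(key, uk)
  nv <- length(uk)
  vx <- rowsum(w, id) / as.vector(table(id)[as.character(seq_len(nv))])
  dep <- rowsum(dist[medial], id)[, 1] / as.vector(table(id)[as.character(seq_len(nv))])
  cc <- do.call(rbind, strsplit(uk, " "))
  ci <- as.integer(cc[, 1]); cj <- as.integer(cc[, 2])
  lut <- new.env(hash = TRUE)
  for (v in seq_len(nv)) assign(paste(ci[v], cj[v]), v, envir = lut)
  getv <- function(i, j) {
    k <- paste(i, j)
    if (exists(k, envir = lut, inherits = FALSE)) get(k, envir = lut) else NA_integer_
  }
  tris <- vector("list", 4L * nv); nt <- 0L
  for (v in seq_len(nv)) {
    i <- ci[v]; j <- cj[v]
    a <- v
    b <- getv(i + 1L, j); cth <- getv(i, j + 1L); dg <- getv(i + 1L, j + 1L)
    if (!is.na(b) && !is.na(cth)) {
      nt <- nt + 1L; tris[[nt]] <- c(a, b, cth)
      if (!is.na(dg)) { nt <- nt + 1L; tris[[nt]] <- c(b, dg, cth) }
    } else if (!is.na(b) && !is.na(dg)) {
      nt <- nt + 1L; tris[[nt]] <- c(a, b, dg)
    } else if (!is.na(cth) && !is.na(dg)) {
      nt <- nt + 1L; tris[[nt]] <- c(a, dg, cth)
    }
  }
  if (nt == 0L) return(NULL)
  tri <- do.call(rbind, tris[seq_len(nt)])
  # keep the largest mesh component; drop unreferenced vertices
  ed <- triangle_edges(tri)
  lab <- cpp_label_components(nv, ed, rep(TRUE, nv))
  keep_lab <- which.max(tabulate(lab))
  keepv <- which(lab == keep_lab)
  if (length(keepv) < 3L) return(NULL)
  remap <- rep(NA_integer_, nv); remap[keepv] <- seq_along(keepv)
  tri <- tri[rowSums(matrix(tri %in% keepv, ncol = 3L)) == 3L, , drop = FALSE]
  if (nrow(tri) == 0L) return(NULL)
  tri <- matrix(remap[tri], ncol = 3L)
  used <- sort(unique(as.vector(tri)))
  if (length(used) < length(keepv)) {
    remap2 <- rep(NA_integer_, length(keepv)); remap2[used] <- seq_along(used)
    tri <- matrix(remap2[tri], ncol = 3L)
    keepv <- keepv[used]
  }
  vx <- vx[keepv, , drop = FALSE]
  dimnames(vx) <- NULL
  list(vertices = vx, triangles = tri,
       depth = unname(dep[keepv]), rotation = rot)
}

triangle_edges <- function(tri) {
  e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  storage.mode(e) <- "integer"
  e
}

# area-weighted per-vertex normals, consistently oriented by majority
vertex_normals <- function(model) {
  v <- model$vertices; tri <- model$triangles
  a <- v[tri[, 2], , drop = FALSE] - v[tri[, 1], , drop = FALSE]
  b <- v[tri[, 3], , drop = FALSE] - v[tri[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  # orient all triangle normals into a common half-space (dominant normal)
  pcn <- prcomp(v, center = TRUE, scale. = FALSE)$rotation[, 3]
  flip <- as.vector(n %*% pcn) < 0
  n[flip, ] <- -n[flip, , drop = FALSE]
  out <- matrix(0, nrow(v), 3L)
  for (c in 1:3) {
    out[, 1] <- out[, 1] + tabulate2(tri[, c], n[, 1], nrow(v))
    out[, 2] <- out[, 2] + tabulate2(tri[, c], n[, 2], nrow(v))
    out[, 3] <- out[, 3] + tabulate2(tri[, c], n[, 3], nrow(v))
  }
  len <- sqrt(rowSums(out^2))
  len[len == 0] <- 1
  out / len
}

tabulate2 <- function(idx, w, n) {
  out <- numeric(n)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# spokes: vector to nearest boundary voxel center in each half-space
# defined by the vertex normal; boundary = background voxels 6-adjacent
# to the mask
compute_spokes <- function(model, mask, spoke_cone_deg = 70) {
  cos_cone <- cos(spoke_cone_deg * pi / 180)
  m <- mask$data
  bnd <- dilate6(m) & !m
  bidx <- which(bnd, arr.ind = TRUE)
  bw <- voxel_to_world(bidx, mask)
  v <- model$vertices
  n <- model$normals
  nv <- nrow(v)
  spokes <- array(NA_real_, c(nv, 3L, 2L),
                  dimnames = list(NULL, NULL, c("plus", "minus")))
  lengths <- matrix(NA_real_, nv, 2L, dimnames = list(NULL, c("plus", "minus")))
  bb2 <- rowSums(bw^2)
  chunk <- 256L
  for (start in seq(1L, nv, by = chunk)) {
    ix <- start:min(start + chunk - 1L, nv)
    V <- v[ix, , drop = FALSE]
    G <- bw %*% t(V)                                  # nb x k
    D2 <- bb2 - 2 * G + matrix(rowSums(V^2), nrow(bw), length(ix), byrow = TRUE)
    S <- (bw %*% t(n[ix, , drop = FALSE])) -
      matrix(rowSums(V * n[ix, , drop = FALSE]), nrow(bw), length(ix), byrow = TRUE)
    for (c in seq_along(ix)) {
      i <- ix[c]
      dd <- pmax(D2[, c], .Machine$double.eps)
      cosang <- S[, c] / sqrt(dd)
      for (s in 1:2) {
        sgn <- if (s == 1L) 1 else -1
        d2s <- dd
        d2s[sgn * cosang < cos_cone] <- Inf        # outside the normal cone
        if (!any(is.finite(d2s))) {                # relax to the half-space
          d2s <- dd
          d2s[sgn * S[, c] < 0] <- Inf
        }
        if (!any(is.finite(d2s))) d2s <- dd        # degenerate: global nearest
        # among (near-)ties, prefer the most normal-aligned candidate
        j <- which.min(d2s * (1 + 1e-6 * (1 - sgn * cosang)))
        spokes[i, , s] <- bw[j, ] - v[i, ]
        lengths[i, s] <- sqrt(dd[j])
      }
    }
  }
  list(spokes = spokes, lengths = lengths)
}

#' Vertices on the open boundary of the skeleton mesh
#'
#' A vertex is on the mesh boundary when it touches an edge incident to
#' exactly one triangle. Spokes at boundary (rim) vertices sit at the
#' open edge of the discrete medial sheet — or of the thin ribbon that
#' stands in for a degenerate tubular medial axis — and are not held to
#' the interior orthogonality contract.
#'
#' @param model a `tract_model`.
#' @return sorted integer vector of boundary vertex indices.
#' @export
mesh_boundary_vertices <- function(model) {
  tri <- model$triangles
  e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- paste(e[, 1], e[, 2])
  cnt <- table(key)
  be <- e[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
  sort(unique(as.vector(be)))
}

#' Per-vertex surface area elements
#'
#' Assigns each vertex one-third of the summed areas of its incident
#' triangles, so that the vertex areas add up exactly to the total mesh
#' area. Degenerate (zero-area) triangles are excluded with a warning.
#'
#' @param model a `tract_model` (or any list with `vertices` and
#'   `triangles`).
#' @return numeric vector of per-vertex areas in mm^2.
#' @export
vertex_areas <- function(model) {
  v <- model$vertices; tri <- model$triangles
  a <- v[tri[, 2], , drop = FALSE] - v[tri[, 1], , drop = FALSE]
  b <- v[tri[, 3], , drop = FALSE] - v[tri[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  ta <- 0.5 * sqrt(rowSums(cr^2))
  degen <- ta <= .Machine$double.eps * 100
  if (any(degen)) {
    warning(sum(degen), " degenerate (zero-area) triangle(s) excluded from vertex areas")
    ta[degen] <- 0
  }
  out <- numeric(nrow(v))
  for (c in 1:3) out <- out + tabulate2(tri[, c], ta / 3, nrow(v))
  out
}

#' Sample a volume along a spoke (depth coordinate)
#'
#' Evaluates `volume` by trilinear interpolation at the point
#' `vertex + fraction * spoke(side)`: fraction 0 is the skeleton vertex,
#' fraction 1 the boundary end of the spoke.
#'
#' @param model a `tract_model`.
#' @param volume a [volume3d] sharing the model's world frame.
#' @param vertex vertex index (scalar or vector).
#' @param side `"plus"` or `"minus"` (recycled).
#' @param fraction depth fraction in `[0, 1]` (recycled).
#' @return numeric vector of interpolated values.
#' @export
sample_along_spoke <- function(model, volume, vertex, side = "plus",
                               fraction = 0) {
  stopifnot(inherits(model, "tract_model"))
  volume <- as_volume3d(volume)
  k <- max(length(vertex), length(side), length(fraction))
  vertex <- rep_len(as.integer(vertex), k)
  side <- rep_len(side, k)
  fraction <- rep_len(as.numeric(fraction), k)
  if (any(vertex < 1L | vertex > nrow(model$vertices)))
    abort("sample_along_spoke: vertex index out of range")
  if (any(fraction < 0 | fraction > 1))
    abort("sample_along_spoke: fraction must lie in [0, 1]")
  si <- match(side, c("plus", "minus"))
  if (anyNA(si)) abort("sample_along_spoke: side must be 'plus' or 'minus'")
  pts <- model$vertices[vertex, , drop = FALSE] +
    fraction * t(vapply(seq_len(k),
                        function(i) model$spokes[vertex[i], , si[i]],
                        numeric(3)))
  vals <- trilinear(volume, pts)
  if (anyNA(vals)) {
    bad <- vertex[which(is.na(vals))[1]]
    abort("sample_along_spoke: sample outside volume bounds at vertex ", bad)
  }
  vals
}

#' @export
print.tract_model <- function(x, ...) {
  cat(sprintf("<tract_model: %d vertices, %d triangles, area %.1f mm^2>\n",
              nrow(x$vertices), nrow(x$triangles), sum(x$vertex_area)))
  invisible(x)
}
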