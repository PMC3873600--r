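# helper: a small detached block in a free region above the slab
shift3d_test <- function(a) {
  out <- array(FALSE, dim(a))
  out[4:5, 4:5, dim(a)[3] - 2] <- TRUE
  out
}

test_that("slab skeleton is the mid-plane with face-normal spokes of length h", {
  m <- slab_mask()            # half-thickness 4.4 mm, 4 voxel layers
  mod <- slab_model()
  zmid <- (dim(m$data)[3] - 1) / 2 * m$spacing[3]
  expect_true(all(abs(mod$vertices[, 3] - zmid) < 1e-6))
  # spoke lengths equal the half-thickness within one voxel
  expect_true(all(abs(mod$spoke_lengths - 4.4) <= m$spacing[3] + 1e-9))
  # spokes perpendicular to the slab faces (< 5 degrees)
  for (s in 1:2) {
    cosz <- abs(mod$spokes[, 3, s]) / mod$spoke_lengths[, s]
    expect_true(all(acos(pmin(cosz, 1)) * 180 / pi < 5))
  }
  # the two sides point opposite ways
  expect_true(all(mod$spokes[, 3, 1] * mod$spokes[, 3, 2] < 0))
})

test_that("tube skeleton degenerates to a thin strip near the centerline", {
  m <- tube_mask()
  mod <- tube_model()
  ctr <- (dim(m$data)[2:3] - 1) / 2 * m$spacing[2:3]
  axdist <- sqrt((mod$vertices[, 2] - ctr[1])^2 + (mod$vertices[, 3] - ctr[2])^2)
  expect_lt(max(axdist), 2 * min(m$spacing))   # ribbon hugs the axis
  expect_gt(nrow(mod$triangles), 0)            # but is still a surface strip
  expect_gt(sum(mod$vertex_area), 0)
})

test_that("spoke lengths equal the distance transform within one voxel diagonal", {
  for (fx in list(list(m = slab_mask(), mod = slab_model()),
                  list(m = tube_mask(), mod = tube_model()),
                  list(m = blob_mask(), mod = blob_model()))) {
    dv <- brute_boundary_distance(fx$mod$vertices, fx$m)   # independent oracle
    tol <- sqrt(3) * max(fx$m$spacing)
    expect_true(all(abs(fx$mod$spoke_lengths - dv) <= tol + 1e-9))
  }
})

test_that("interior spokes are orthogonal to the local boundary", {
  # slab: all vertices, < 5 degrees (tested above); tube: interior
  # vertices of the ribbon vs the analytic radial normal, < 15 degrees.
  # Rim vertices of the ribbon that substitutes a degenerate tubular
  # medial axis sit at the open mesh edge and are exempt (documented).
  m <- tube_mask(); mod <- tube_model()
  ctr <- (dim(m$data)[2:3] - 1) / 2 * m$spacing[2:3]
  interior <- setdiff(seq_len(nrow(mod$vertices)), mesh_boundary_vertices(mod))
  expect_gt(length(interior), 10)
  for (s in 1:2) {
    bp <- mod$vertices + mod$spokes[, , s]
    rad <- cbind(0, bp[, 2] - ctr[1], bp[, 3] - ctr[2])
    rad <- rad / sqrt(rowSums(rad^2))
    sdir <- mod$spokes[, , s] / mod$spoke_lengths[, s]
    ang <- acos(pmin(1, rowSums(sdir * rad))) * 180 / pi
    expect_true(all(ang[interior] < 15))
  }
})

test_that("no transversal spoke intersections over 10,000 sampled pairs", {
  expect_equal(count_spoke_crossings(slab_model(), 10000L, seed = 1), 0L)
  expect_equal(count_spoke_crossings(blob_model(), 10000L, seed = 2), 0L)
})

test_that("skeleton mesh is one connected component with conserved area", {
  for (mod in list(slab_model(), tube_model(), blob_model())) {
    comp <- bfs_components(rep(TRUE, nrow(mod$vertices)), mod$edges)
    expect_equal(length(unique(comp)), 1L)
    expect_true(all(mod$vertex_area > 0))
    v <- mod$vertices; tri <- mod$triangles
    a <- v[tri[, 2], ] - v[tri[, 1], ]; b <- v[tri[, 3], ] - v[tri[, 1], ]
    tot <- sum(0.5 * sqrt(rowSums(cbind(
      a[, 2] * b[, 3] - a[, 3] * b[, 2],
      a[, 3] * b[, 1] - a[, 1] * b[, 3],
      a[, 1] * b[, 2] - a[, 2] * b[, 1])^2)))
    expect_equal(sum(mod$vertex_area), tot, tolerance = 1e-10)
  }
})

test_that("every vertex lies strictly inside the mask", {
  for (fx in list(list(m = slab_mask(), mod = slab_model()),
                  list(m = blob_mask(), mod = blob_model()))) {
    inside <- tractfa:::nearest_lookup(fx$m, fx$mod$vertices)
    expect_true(all(inside == 1))
  }
})

test_that("vertex areas follow the one-third incident-triangle rule", {
  s <- 3
  tri_model <- list(vertices = rbind(c(0, 0, 0), c(s, 0, 0),
                                     c(s / 2, s * sqrt(3) / 2, 0)),
                    triangles = matrix(1:3, 1))
  va <- vertex_areas(tri_model)
  expect_equal(va, rep(sqrt(3) / 4 * s^2 / 3, 3))
  sq <- list(vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
             triangles = rbind(c(1, 2, 3), c(1, 3, 4)))
  expect_equal(sum(vertex_areas(sq)), 1.0)
  degen <- list(vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                triangles = matrix(1:3, 1))
  expect_warning(va2 <- vertex_areas(degen), "degenerate")
  expect_equal(sum(va2), 0)
})

test_that("sample_along_spoke interpolates the depth coordinate", {
  mod <- slab_model()
  m <- slab_mask()
  const <- volume3d(array(0.37, dim(m$data)), m$spacing, m$origin)
  expect_equal(sample_along_spoke(mod, const, 1:5, "plus", 0.5), rep(0.37, 5))
  # linear field recovered exactly under trilinear interpolation
  d <- dim(m$data)
  xw <- array(rep((0:(d[1] - 1)) * m$spacing[1], times = d[2] * d[3]), d)
  lin <- volume3d(0.01 * xw, m$spacing, m$origin)
  for (fr in c(0, 0.5, 1)) {
    pts <- mod$vertices + fr * mod$spokes[, , 2]
    expect_equal(sample_along_spoke(mod, lin, seq_len(nrow(mod$vertices)),
                                    "minus", fr),
                 unname(0.01 * pts[, 1]), tolerance = 1e-10)
  }
  expect_error(sample_along_spoke(mod, const, 1, "plus", 1.5), "fraction")
  expect_error(sample_along_spoke(mod, const, 10000, "plus", 0), "vertex")
})

test_that("defective masks are rejected with informative errors", {
  m <- slab_mask()
  two <- m
  two$data <- m$data | shift3d_test(m$data)
  expect_error(build_medial_model(two), "2 .*components|components")
  hole <- m
  ctr <- round(dim(m$data) / 2)
  hole$data[ctr[1], ctr[2], ctr[3]] <- FALSE
  expect_error(build_medial_model(hole), "cavit")
  tight <- volume3d(array(TRUE, c(8, 8, 8)), c(1, 1, 1))
  expect_error(build_medial_model(tight), "margin")
})

test_that("dilating the mask changes the median spoke length by about one voxel", {
  m <- blob_mask()
  mod <- blob_model()
  big <- volume3d(tractfa:::dilate6(m$data), m$spacing, m$origin)
  mod2 <- build_medial_model(big)
  delta <- median(mod2$spoke_lengths) - median(mod$spoke_lengths)
  expect_lt(abs(delta - min(m$spacing)), 0.75 * min(m$spacing))
})
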