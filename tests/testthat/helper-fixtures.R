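# Shared fixtures: phantom masks and medial models are built once per
# test run and memoized here; all fixtures are generated in code.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env, inherits = FALSE))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

slab_mask <- function() memo("slab_mask",
  make_phantom(phantom_spec("sheet", grid_dims = c(24, 16, 12),
                            half_thickness_mm = 4.4)))

slab_model <- function() memo("slab_model", build_medial_model(slab_mask()))

tube_mask <- function() memo("tube_mask",
  make_phantom(phantom_spec("tube", grid_dims = c(48, 20, 20),
                            voxel_size_mm = 1.1, radius_mm = 4.4)))

tube_model <- function() memo("tube_model", build_medial_model(tube_mask()))

# smooth flattened-ellipsoid blob with a gentle sinusoidal radius bump;
# single component, no cavities, by construction
blob_mask <- function() memo("blob_mask", {
  d <- c(26, 20, 12)
  vs <- 2.0
  ctr <- (d - 1) / 2 * vs
  ax <- lapply(1:3, function(j) ((1:d[j]) - 1) * vs - ctr[j])
  semi <- c(16, 11, 5.5)  # semi-axes mm
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  bump <- 1 + 0.12 * sin(g$x / 6) * cos(g$y / 7)
  r2 <- (g$x / semi[1])^2 + (g$y / semi[2])^2 + (g$z / semi[3])^2
  volume3d(array(r2 <= bump, d), spacing = rep(vs, 3), origin = c(0, 0, 0))
})

blob_model <- function() memo("blob_model", build_medial_model(blob_mask()))

# small slab for statistics tests (fast to project onto)
stat_mask <- function() memo("stat_mask",
  make_phantom(phantom_spec("sheet", grid_dims = c(20, 12, 10),
                            half_thickness_mm = 4.4)))

stat_model <- function() memo("stat_model", build_medial_model(stat_mask()))

# brute-force oracle: distance from points (n x 3, mm) to the nearest
# background voxel center of `mask` (independent of the package's EDT)
brute_boundary_distance <- function(pts, mask) {
  out_idx <- which(!mask$data, arr.ind = TRUE)
  bw <- sweep(sweep(out_idx - 1, 2, mask$spacing, "*"), 2, mask$origin, "+")
  apply(pts, 1, function(p) sqrt(min(colSums((t(bw) - p)^2))))
}

# minimum distance between segment pairs (p1->q1 vs p2->q2), with the
# closest-point parameters; vectorized over rows (Eberly's clamped
# quadratic minimization)
segment_pair_distance <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- rowSums(d1 * d1); e <- rowSums(d2 * d2)
  b <- rowSums(d1 * d2); c <- rowSums(d1 * r); f <- rowSums(d2 * r)
  den <- a * e - b * b
  s <- ifelse(den > 1e-12, (b * f - c * e) / den, 0)
  s <- pmin(pmax(s, 0), 1)
  t <- ifelse(e > 1e-12, (b * s + f) / e, 0)
  t2 <- pmin(pmax(t, 0), 1)
  # re-clamp s for clamped t
  s2 <- ifelse(a > 1e-12, (b * t2 - c) / a, 0)
  s2 <- pmin(pmax(s2, 0), 1)
  cp1 <- p1 + d1 * s2
  cp2 <- p2 + d2 * t2
  list(dist = sqrt(rowSums((cp1 - cp2)^2)), s = s2, t = t2)
}

# count transversal spoke intersections over n random spoke pairs:
# proper crossings (tiny separation at interior parameters), excluding
# pairs that merely share a skeleton/boundary endpoint region
count_spoke_crossings <- function(model, n_pairs = 10000L, seed = 1L,
                                  tol_mm = 0.05 * min(model$spacing)) {
  nv <- nrow(model$vertices)
  set.seed(seed)
  i <- sample.int(nv, n_pairs, replace = TRUE)
  j <- sample.int(nv, n_pairs, replace = TRUE)
  si <- sample(1:2, n_pairs, replace = TRUE)
  sj <- sample(1:2, n_pairs, replace = TRUE)
  keep <- i != j
  i <- i[keep]; j <- j[keep]; si <- si[keep]; sj <- sj[keep]
  p1 <- model$vertices[i, , drop = FALSE]
  q1 <- p1 + t(vapply(seq_along(i), function(k) model$spokes[i[k], , si[k]],
                      numeric(3)))
  p2 <- model$vertices[j, , drop = FALSE]
  q2 <- p2 + t(vapply(seq_along(j), function(k) model$spokes[j[k], , sj[k]],
                      numeric(3)))
  sp <- segment_pair_distance(p1, q1, p2, q2)
  interior <- sp$s > 0.02 & sp$s < 0.98 & sp$t > 0.02 & sp$t < 0.98
  sum(sp$dist < tol_mm & interior)
}

# tiny breadth-first connected components on a vertex subset (oracle,
# independent of the package's union-find)
bfs_components <- function(active, edges) {
  nv <- length(active)
  adj <- vector("list", nv)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    if (active[a] && active[b]) {
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  comp <- rep(NA_integer_, nv)
  cur <- 0L
  for (v in which(active)) {
    if (!is.na(comp[v])) next
    cur <- cur + 1L
    queue <- v
    while (length(queue)) {
      x <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[x])) next
      comp[x] <- cur
      queue <- c(queue, adj[[x]][is.na(comp[adj[[x]]])])
    }
  }
  comp
}
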