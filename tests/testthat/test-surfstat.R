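test_that("pointwise pooled t matches the hand-computed value", {
  a <- matrix(c(1, 2, 3), 3, 2)
  b <- matrix(c(4, 5, 6), 3, 2)
  sm <- pointwise_ttest(a, b)
  expect_equal(sm$t, rep(-3 / sqrt(2 / 3), 2), tolerance = 1e-12)  # -3.674235
  expect_equal(sm$df, 4L)
  # antisymmetry in argument order
  sw <- pointwise_ttest(b, a)
  expect_equal(sw$t, -sm$t)
  # identical groups -> t = 0
  expect_equal(pointwise_ttest(a, a)$t, c(0, 0))
  expect_error(pointwise_ttest(a, matrix(0, 3, 3)), "vertex counts")
})

test_that("zero-variance vertices yield t = 0 and are counted", {
  a <- cbind(rep(1, 4), rnorm(4))
  b <- cbind(rep(1, 4), rnorm(4))
  sm <- pointwise_ttest(a, b)
  expect_equal(sm$t[1], 0)
  expect_equal(sm$n_zero_var, 1L)
})

test_that("binary-covariate regression t^2 equals the two-sample t^2", {
  set.seed(10)
  X <- matrix(rnorm(12 * 30, 0.45, 0.05), 12)
  g <- rep(c(0, 1), each = 6)
  tt <- pointwise_ttest(X[g == 1, ], X[g == 0, ])
  rg <- pointwise_regression(X, g)
  expect_equal(rg$t^2, tt$t^2, tolerance = 1e-9)
})

test_that("regression handles exact fits and rejects constant scores", {
  z <- c(-2, -1, 0, 1, 2)
  X <- cbind(0.4 + 0.05 * z, rnorm(5))
  sm <- pointwise_regression(X, z)
  expect_gte(sm$t[1], 1e5)           # capped deterministic fit
  expect_equal(sm$n_degenerate, 1L)
  expect_error(pointwise_regression(X, rep(1, 5)), "constant")
  expect_error(pointwise_regression(X[1:2, ], z[1:2]), "n >= 3")
})

test_that("height thresholds match an independent t-quantile oracle", {
  # oracle: invert the numerically integrated t density
  t_quantile_oracle <- function(p, df) {
    dens <- function(x) stats::dt(x, df)
    cdf <- function(q) 0.5 + stats::integrate(dens, 0, q)$value
    stats::uniroot(function(q) cdf(q) - p, c(0, 50), tol = 1e-10)$root
  }
  expect_equal(height_threshold(22, 0.005, "greater"),
               t_quantile_oracle(0.995, 22), tolerance = 1e-8)
  expect_equal(height_threshold(45, 0.01, "two_sided"),
               t_quantile_oracle(0.995, 45), tolerance = 1e-8)
  # normal limit: one-sided 0.005 -> 2.576
  expect_equal(height_threshold(1e7, 0.005, "greater"), qnorm(0.995),
               tolerance = 1e-3)
  expect_equal(height_threshold(30, 0.5, "greater"), 0, tolerance = 1e-12)
  expect_error(height_threshold(0, 0.01), "df")
})

test_that("cluster formation matches a breadth-first oracle", {
  mod <- stat_model()
  nv <- nrow(mod$vertices)
  set.seed(6)
  t_vals <- rnorm(nv, 0, 0.3)
  # paint two well-separated supra-threshold patches
  ctr1 <- mod$vertices[1, ]; ctr2 <- mod$vertices[nv, ]
  d1 <- sqrt(colSums((t(mod$vertices) - ctr1)^2))
  d2 <- sqrt(colSums((t(mod$vertices) - ctr2)^2))
  t_vals[d1 < 5] <- 4
  t_vals[d2 < 5] <- 5
  sm <- tractfa:::new_stat_map(t_vals, 43, "test", "greater")
  cl <- form_clusters(sm, 3, mod)
  supra <- t_vals > 3
  comp <- bfs_components(supra, mod$edges)
  expect_equal(length(cl), length(unique(na.omit(comp[supra]))))
  expect_equal(length(cl), 2L)
  # areas equal summed vertex areas of the oracle components
  oracle_areas <- sort(tapply(mod$vertex_area[supra], comp[supra], sum),
                       decreasing = TRUE)
  expect_equal(vapply(cl, `[[`, numeric(1), "area_mm2"),
               as.numeric(oracle_areas))
  # no supra vertices -> empty; everything supra -> one total-area cluster
  expect_equal(form_clusters(tractfa:::new_stat_map(rep(0, nv), 43, "t", "greater"),
                             3, mod), list())
  all_cl <- form_clusters(tractfa:::new_stat_map(rep(9, nv), 43, "t", "greater"),
                          3, mod)
  expect_equal(length(all_cl), 1L)
  expect_equal(all_cl[[1]]$area_mm2, sum(mod$vertex_area))
})

test_that("raising the threshold never grows a cluster", {
  mod <- stat_model()
  set.seed(41)
  sm <- tractfa:::new_stat_map(rnorm(nrow(mod$vertices), 1, 1.5), 43,
                               "t", "greater")
  lo <- form_clusters(sm, 1.5, mod)
  hi <- form_clusters(sm, 2.5, mod)
  expect_lte(if (length(hi)) hi[[1]]$area_mm2 else 0,
             if (length(lo)) lo[[1]]$area_mm2 else 0)
  expect_lte(sum(vapply(hi, `[[`, numeric(1), "area_mm2")),
             sum(vapply(lo, `[[`, numeric(1), "area_mm2")))
})

test_that("exhaustive 3v3 permutation matches full enumeration exactly", {
  mod <- stat_model()
  nv <- nrow(mod$vertices)
  set.seed(2)
  X <- matrix(rnorm(6 * nv, 0.45, 0.03), 6)
  X[1:3, 1:8] <- X[1:3, 1:8] + 0.08    # planted effect in group A
  cfg <- perm_config(n_perm = 5000, height_p = 0.05, seed = 9)
  res <- suppressMessages(permutation_fwe(
    X, list(type = "contrast", labels = rep(c("a", "b"), each = 3),
            group_a = "a", group_b = "b"), cfg, mod, "greater"))
  expect_true(res$exhaustive)
  expect_equal(res$n_perm_used, choose(6, 3))
  ps <- vapply(res$clusters, `[[`, numeric(1), "fwe_p")
  expect_true(all(abs(ps * 21 - round(ps * 21)) < 1e-9))
  # oracle: enumerate all 20 relabelings by hand
  t_crit <- height_threshold(4, 0.05, "greater")
  combos <- combn(6, 3)
  max_area <- apply(combos, 2, function(ga) {
    st <- pointwise_ttest(X[ga, , drop = FALSE], X[-ga, , drop = FALSE],
                          "greater")
    supra <- st$t > t_crit
    if (!any(supra)) return(0)
    comp <- bfs_components(supra, mod$edges)
    max(tapply(mod$vertex_area[supra], comp[supra], sum))
  })
  for (cl in res$clusters) {
    expect_equal(cl$fwe_p, (1 + sum(max_area >= cl$area_mm2)) / 21)
  }
})

test_that("permutation p-values are deterministic given the seed", {
  mod <- stat_model()
  nv <- nrow(mod$vertices)
  set.seed(19)
  X <- matrix(rnorm(20 * nv, 0.45, 0.03), 20)
  X[1:8, 1:10] <- X[1:8, 1:10] - 0.05
  labs <- rep(c("p", "c"), c(8, 12))
  design <- list(type = "contrast", labels = labs, group_a = "p", group_b = "c")
  cfg <- perm_config(n_perm = 300, height_p = 0.01, seed = 123)
  r1 <- permutation_fwe(X, design, cfg, mod, "less")
  r2 <- permutation_fwe(X, design, cfg, mod, "less")
  expect_identical(vapply(r1$clusters, `[[`, numeric(1), "fwe_p"),
                   vapply(r2$clusters, `[[`, numeric(1), "fwe_p"))
  expect_identical(r1$null_max_area, r2$null_max_area)
  r3 <- permutation_fwe(X, design, perm_config(n_perm = 300, height_p = 0.01,
                                               seed = 124), mod, "less")
  expect_false(identical(r1$null_max_area, r3$null_max_area))
})

test_that("score-shuffle regression permutation recovers a planted coupling", {
  mod <- stat_model()
  nv <- nrow(mod$vertices)
  set.seed(3)
  n <- 13
  z <- rnorm(n, -13.2, 3.4)
  X <- matrix(rnorm(n * nv, 0.45, 0.02), n)
  X[, 1:12] <- X[, 1:12] + 0.008 * z    # coupling in a patch
  cfg <- perm_config(n_perm = 500, height_p = 0.01, seed = 5)
  res <- permutation_fwe(X, list(type = "regression", scores = z), cfg, mod,
                         "greater")
  expect_gt(length(res$clusters), 0)
  expect_true(res$clusters[[1]]$significant)
  expect_true(all(res$clusters[[1]]$members %in% 1:12))
  expect_gte(res$clusters[[1]]$n_vertices, 6)
})

test_that("report_clusters mirrors the cluster list", {
  mod <- stat_model()
  f <- tempfile(fileext = ".csv")
  df0 <- report_clusters(list(), "L_UNC", f)
  expect_equal(nrow(df0), 0L)
  expect_equal(nrow(utils::read.csv(f)), 0L)
  cl <- list(list(id = 1, members = 1:3, area_mm2 = 12, peak_t = -4,
                  fwe_p = 0.01, n_vertices = 3, significant = TRUE),
             list(id = 2, members = 7:8, area_mm2 = 30, peak_t = -3.2,
                  fwe_p = 0.2, n_vertices = 2, significant = FALSE))
  df <- report_clusters(cl, "L_UNC", f)
  expect_equal(df$area_mm2, c(30, 12))     # sorted by area
  expect_equal(utils::read.csv(f)$area_mm2, c(30, 12))
  expect_equal(names(df), c("tract", "cluster_id", "area_mm2", "fwe_p",
                            "peak_t", "n_vertices", "significant"))
})

test_that("perm_config validates its fields", {
  expect_error(perm_config(n_perm = 0), "n_perm")
  expect_error(perm_config(height_p = 0), "height_p")
  expect_error(perm_config(cluster_alpha = 1), "cluster_alpha")
})
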