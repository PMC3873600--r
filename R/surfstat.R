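# Pointwise statistics on the skeleton surface and non-parametric
# cluster-based permutation inference with familywise-error (FWE)
# correction via the maximum-cluster-area null distribution.

#' Permutation configuration
#'
#' @param n_perm number of random relabelings (default 10,000).
#' @param height_p height threshold as an uncorrected pointwise p-value;
#'   conventionally 0.005 for group contrasts and 0.01 for score
#'   regressions.
#' @param cluster_alpha FWE-corrected cluster significance level.
#' @param seed integer RNG seed for the permutation stream.
#' @param exhaustive enumerate all distinct relabelings exactly; `NA`
#'   auto-enables when the number of distinct relabelings does not
#'   exceed `n_perm`.
#' @return an object of class `perm_config`.
#' @export
perm_config <- function(n_perm = 10000L, height_p = 0.005,
                        cluster_alpha = 0.05, seed = 1L, exhaustive = NA) {
  if (n_perm < 1L) abort("perm_config: n_perm must be >= 1")
  if (!(height_p > 0 && height_p < 1))
    abort("perm_config: height_p must lie in (0, 1)")
  if (!(cluster_alpha > 0 && cluster_alpha < 1))
    abort("perm_config: cluster_alpha must lie in (0, 1)")
  structure(list(n_perm = as.integer(n_perm), height_p = height_p,
                 cluster_alpha = cluster_alpha, seed = as.integer(seed),
                 exhaustive = exhaustive),
            class = "perm_config")
}

new_stat_map <- function(t, df, design, direction, n_zero_var = 0L) {
  structure(list(t = t, df = df, design = design, direction = direction,
                 n_zero_var = n_zero_var),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map: %d vertices, df = %s, %s, direction = %s>\n",
              length(x$t), format(x$df), x$design, x$direction))
  invisible(x)
}

#' Pointwise two-sample t-test on the skeleton surface
#'
#' Pooled-variance (Student) two-sample t statistic per vertex for
#' group A minus group B; df = nA + nB - 2. Vertices with zero pooled
#' variance get t = 0 and are counted in the `n_zero_var` field.
#'
#' @param fa_a,fa_b numeric matrices, subjects x vertices.
#' @param direction alternative for downstream thresholding:
#'   `"greater"` (A > B), `"less"`, or `"two_sided"`.
#' @return a `stat_map`.
#' @export
pointwise_ttest <- function(fa_a, fa_b,
                            direction = c("two_sided", "greater", "less")) {
  direction <- match.arg(direction)
  fa_a <- as.matrix(fa_a); fa_b <- as.matrix(fa_b)
  if (ncol(fa_a) != ncol(fa_b))
    abort("pointwise_ttest: vertex counts differ (",
          ncol(fa_a), " vs ", ncol(fa_b), ")")
  na <- nrow(fa_a); nb <- nrow(fa_b)
  if (na < 2L || nb < 2L) abort("pointwise_ttest: need >= 2 subjects per group")
  ma <- colMeans(fa_a); mb <- colMeans(fa_b)
  ssa <- colSums(fa_a^2) - na * ma^2
  ssb <- colSums(fa_b^2) - nb * mb^2
  df <- na + nb - 2L
  sp2 <- (ssa + ssb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (ma - mb) / se
  zero <- !is.finite(t)
  t[zero] <- 0
  new_stat_map(t, df, sprintf("contrast A(n=%d) vs B(n=%d)", na, nb),
               direction, sum(zero))
}

#' Pointwise simple-regression t-test on the skeleton surface
#'
#' Per vertex, the t statistic of the slope of FA on `scores` under
#' simple linear regression; df = n - 2. Vertices with an exact
#' deterministic fit (zero residual) are capped at a large finite t and
#' counted in `n_degenerate`.
#'
#' @param fa_matrix numeric matrix, subjects x vertices.
#' @param scores numeric vector, one score per subject; must not be
#'   constant.
#' @param direction alternative for downstream thresholding.
#' @return a `stat_map` (field `n_degenerate` counts capped vertices).
#' @export
pointwise_regression <- function(fa_matrix, scores,
                                 direction = c("two_sided", "greater", "less")) {
  direction <- match.arg(direction)
  fa_matrix <- as.matrix(fa_matrix)
  n <- nrow(fa_matrix)
  if (n < 3L) abort("pointwise_regression: need n >= 3 subjects")
  if (length(scores) != n)
    abort("pointwise_regression: scores length != subject count")
  if (any(!is.finite(scores))) abort("pointwise_regression: scores must be finite")
  if (stats::sd(scores) == 0)
    abort("pointwise_regression: constant score vector; slope test undefined")
  sc <- scores - mean(scores)
  ssx <- sum(sc^2)
  xc <- sweep(fa_matrix, 2, colMeans(fa_matrix))
  ssy <- colSums(xc^2)
  num <- as.vector(sc %*% xc)
  r2den <- ssx * ssy
  r <- ifelse(r2den > 0, num / sqrt(r2den), 0)
  df <- n - 2L
  cap <- 1e6
  one <- abs(r) >= 1 - 1e-12
  t <- numeric(length(r))
  t[!one] <- r[!one] * sqrt(df) / sqrt(1 - r[!one]^2)
  t[one] <- sign(r[one]) * cap
  sm <- new_stat_map(t, df, "regression of FA on score", direction,
                     sum(ssy == 0))
  sm$n_degenerate <- sum(one & ssy > 0)
  sm
}

#' Height threshold for cluster formation
#'
#' The t-distribution quantile corresponding to an uncorrected
#' pointwise p-value: one-sided thresholds use the `1 - height_p`
#' quantile, two-sided the `1 - height_p / 2` quantile.
#'
#' @param df degrees of freedom (>= 1); `Inf` gives the normal limit.
#' @param height_p pointwise p-value in (0, 1).
#' @param direction `"greater"`, `"less"`, or `"two_sided"`.
#' @return positive critical t value.
#' @export
height_threshold <- function(df, height_p = 0.005,
                             direction = c("two_sided", "greater", "less")) {
  direction <- match.arg(direction)
  if (df < 1) abort("height_threshold: df must be >= 1")
  p <- if (direction == "two_sided") height_p / 2 else height_p
  stats::qt(1 - p, df)
}

#' Form supra-threshold clusters on the skeleton mesh
#'
#' Connected components (mesh edge adjacency) of vertices whose
#' statistic exceeds the height threshold in the stated direction.
#' Cluster area is the sum of member vertex area elements; clusters are
#' returned sorted by area, largest first.
#'
#' @param stat a `stat_map`.
#' @param t_crit positive critical t value, e.g. [height_threshold()].
#' @param model a `tract_model` supplying mesh `edges` and
#'   `vertex_area`.
#' @return list of clusters, each a list with `id`, `members`,
#'   `area_mm2`, `peak_t`, `fwe_p` (NA until permutation), and
#'   `n_vertices`. May be empty.
#' @export
form_clusters <- function(stat, t_crit, model) {
  stopifnot(inherits(stat, "stat_map"))
  if (!is.finite(t_crit)) abort("form_clusters: t_crit must be finite")
  nv <- length(stat$t)
  supra <- switch(stat$direction,
                  greater = stat$t > t_crit,
                  less = stat$t < -t_crit,
                  two_sided = abs(stat$t) > t_crit)
  if (!any(supra)) return(list())
  lab <- cpp_label_components(nv, model$edges, supra)
  ids <- sort(unique(lab[supra]))
  out <- lapply(ids, function(l) {
    members <- which(!is.na(lab) & lab == l)
    pk <- members[which.max(abs(stat$t[members]))]
    list(id = l, members = members,
         area_mm2 = sum(model$vertex_area[members]),
         peak_t = stat$t[pk], fwe_p = NA_real_,
         n_vertices = length(members))
  })
  out <- out[order(vapply(out, `[[`, numeric(1), "area_mm2"), decreasing = TRUE)]
  for (i in seq_along(out)) out[[i]]$id <- i
  out
}

# all distinct group-A index sets of size na out of n (columns)
all_relabelings <- function(n, na) utils::combn(n, na)

# random permutation matrix helpers -----------------------------------------

contrast_t_matrix <- function(X, amat, na, nb) {
  # X: n x V data; amat: m x n 0/1 indicator of membership in group A
  tot <- colSums(X); tot2 <- colSums(X^2)
  SA <- amat %*% X
  SA2 <- amat %*% (X^2)
  SB <- matrix(tot, nrow(SA), ncol(SA), byrow = TRUE) - SA
  SB2 <- matrix(tot2, nrow(SA), ncol(SA), byrow = TRUE) - SA2
  df <- na + nb - 2
  sp2 <- ((SA2 - SA^2 / na) + (SB2 - SB^2 / nb)) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (SA / na - SB / nb) / se
  t[!is.finite(t)] <- 0
  t
}

regression_t_matrix <- function(Xc, ssy, smat) {
  # Xc: centered n x V; smat: m x n rows of centered permuted scores
  ssx <- sum(smat[1, ]^2)
  num <- smat %*% Xc
  den <- sqrt(ssx * matrix(ssy, nrow(num), ncol(num), byrow = TRUE))
  r <- ifelse(den > 0, num / den, 0)
  r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  n <- ncol(smat)
  r * sqrt(n - 2) / sqrt(1 - r^2)
}

#' Cluster-based permutation test with FWE correction
#'
#' Runs the observed pointwise test (group contrast or score
#' regression), forms supra-threshold clusters at the height threshold
#' implied by `config$height_p`, and assigns each cluster a
#' familywise-error-corrected p-value against the permutation null
#' distribution of the maximum supra-threshold cluster area (group
#' labels shuffled for contrasts, scores shuffled for regressions).
#' `fwe_p = (1 + #\{null max >= observed area\}) / (n_perm + 1)`; ties
#' count against the cluster (conservative). When the number of
#' distinct relabelings does not exceed `n_perm` the null is enumerated
#' exactly instead of sampled, with a message.
#'
#' @param fa_matrix numeric matrix, subjects x vertices.
#' @param design list describing the test: for a contrast,
#'   `list(type = "contrast", labels = <character/factor>, group_a =,
#'   group_b =)`; for a regression, `list(type = "regression",
#'   scores = <numeric>)`.
#' @param config a [perm_config()].
#' @param model a `tract_model`.
#' @param direction test direction (see [pointwise_ttest()]).
#' @return list with `clusters` (as [form_clusters()], with `fwe_p` and
#'   `significant` filled in), `stat` (the observed `stat_map`),
#'   `t_crit`, `null_max_area`, `n_perm_used`, `exhaustive`, `config`.
#' @export
permutation_fwe <- function(fa_matrix, design, config, model,
                            direction = c("two_sided", "greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(inherits(config, "perm_config"))
  X <- as.matrix(fa_matrix)
  nv <- ncol(X)
  if (nv != nrow(model$vertices))
    abort("permutation_fwe: data vertex count does not match the model")

  if (identical(design$type, "contrast")) {
    labs <- as.character(design$labels)
    sel_a <- labs == design$group_a
    sel_b <- labs == design$group_b
    if (sum(sel_a) < 2L || sum(sel_b) < 2L)
      abort("permutation_fwe: need >= 2 subjects in each group")
    X <- X[sel_a | sel_b, , drop = FALSE]
    ga <- sel_a[sel_a | sel_b]
    na <- sum(ga); nb <- sum(!ga)
    n <- na + nb
    stat <- pointwise_ttest(X[ga, , drop = FALSE], X[!ga, , drop = FALSE],
                            direction)
    n_distinct <- choose(n, na)
    exhaustive <- isTRUE(config$exhaustive)
    if (!exhaustive && n_distinct <= config$n_perm) {
      message("permutation_fwe: ", n_distinct,
              " distinct relabelings <= n_perm; enumerating exhaustively")
      exhaustive <- TRUE
    }
    if (exhaustive && n_distinct > 1e6)
      abort("permutation_fwe: exhaustive enumeration infeasible (",
            n_distinct, " relabelings)")
    if (exhaustive) {
      sets <- all_relabelings(n, na)
      amat <- matrix(0, ncol(sets), n)
      amat[cbind(rep(seq_len(ncol(sets)), each = na), as.vector(sets))] <- 1
    } else {
      amat <- with_seed(config$seed, {
        m <- matrix(0, config$n_perm, n)
        for (r in seq_len(config$n_perm))
          m[r, sample.int(n, na)] <- 1
        m
      })
    }
    tfun <- function(rows) contrast_t_matrix(X, amat[rows, , drop = FALSE], na, nb)
    m <- nrow(amat)
  } else if (identical(design$type, "regression")) {
    scores <- as.numeric(design$scores)
    if (length(scores) != nrow(X))
      abort("permutation_fwe: scores length does not match subjects")
    stat <- pointwise_regression(X, scores, direction)
    n <- nrow(X)
    sc <- scores - mean(scores)
    Xc <- sweep(X, 2, colMeans(X))
    ssy <- colSums(Xc^2)
    exhaustive <- isTRUE(config$exhaustive) ||
      (!isFALSE(config$exhaustive) && n <= 9 && factorial(n) <= config$n_perm)
    if (exhaustive && n > 9)
      abort("permutation_fwe: exhaustive score permutation infeasible for n > 9")
    if (exhaustive) {
      perms <- permutations_of(n)
      smat <- matrix(sc[perms], nrow = nrow(perms))
    } else {
      smat <- with_seed(config$seed, {
        m <- matrix(0, config$n_perm, n)
        for (r in seq_len(config$n_perm)) m[r, ] <- sc[sample.int(n)]
        m
      })
    }
    tfun <- function(rows) regression_t_matrix(Xc, ssy, smat[rows, , drop = FALSE])
    m <- nrow(smat)
  } else {
    abort("permutation_fwe: design$type must be 'contrast' or 'regression'")
  }

  t_crit <- height_threshold(stat$df, config$height_p, direction)
  clusters <- form_clusters(stat, t_crit, model)
  dir_code <- switch(direction, greater = 1L, less = -1L, two_sided = 0L)
  null_max <- numeric(m)
  block <- 2000L
  for (start in seq(1L, m, by = block)) {
    rows <- start:min(start + block - 1L, m)
    tmat <- tfun(rows)
    null_max[rows] <- cpp_null_max_area(tmat, t_crit, dir_code,
                                        model$edges, model$vertex_area)
  }
  for (i in seq_along(clusters)) {
    # >= with a hair of tolerance: the observed labeling appears in the
    # exhaustive null and must count as a tie despite floating-point
    # summation-order differences
    b <- sum(null_max >= clusters[[i]]$area_mm2 - 1e-8)
    clusters[[i]]$fwe_p <- (1 + b) / (1 + m)
    clusters[[i]]$significant <- clusters[[i]]$fwe_p < config$cluster_alpha
  }
  list(clusters = clusters, stat = stat, t_crit = t_crit,
       null_max_area = null_max, n_perm_used = m,
       exhaustive = exhaustive, config = config, direction = direction)
}

# all permutations of 1..n (n! rows); recursion is fine for the tiny n
# exhaustive mode allows
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (i in seq_len(n)) {
    rows <- (r + 1L):(r + nrow(sub))
    out[rows, 1L] <- i
    out[rows, -1L] <- matrix(setdiff(seq_len(n), i)[sub], nrow(sub))
    r <- r + nrow(sub)
  }
  out
}

#' Tabulate cluster results
#'
#' Flattens a [permutation_fwe()] result (or a bare cluster list) into
#' a data frame with one row per cluster, mirroring the standard
#' reporting layout: tract, cluster area in mm^2, FWE-corrected
#' p-value, plus peak statistic and vertex count. Optionally writes
#' RFC-4180 CSV.
#'
#' @param results a [permutation_fwe()] result or list of clusters.
#' @param tract_name label for the tract column.
#' @param file optional CSV output path.
#' @return data.frame with columns `tract`, `cluster_id`, `area_mm2`,
#'   `fwe_p`, `peak_t`, `n_vertices`, `significant` (empty when there
#'   are no clusters).
#' @export
report_clusters <- function(results, tract_name = "tract", file = NULL) {
  clusters <- if (!is.null(results$clusters)) results$clusters else results
  if (length(clusters) == 0L) {
    df <- data.frame(tract = character(), cluster_id = integer(),
                     area_mm2 = numeric(), fwe_p = numeric(),
                     peak_t = numeric(), n_vertices = integer(),
                     significant = logical())
  } else {
    df <- data.frame(
      tract = tract_name,
      cluster_id = vapply(clusters, `[[`, numeric(1), "id"),
      area_mm2 = vapply(clusters, `[[`, numeric(1), "area_mm2"),
      fwe_p = vapply(clusters, `[[`, numeric(1), "fwe_p"),
      peak_t = vapply(clusters, `[[`, numeric(1), "peak_t"),
      n_vertices = vapply(clusters, `[[`, numeric(1), "n_vertices"),
      significant = vapply(clusters, function(cl)
        isTRUE(cl$significant), logical(1))
    )
    df <- df[order(df$area_mm2, decreasing = TRUE), , drop = FALSE]
    rownames(df) <- NULL
  }
  if (!is.null(file)) utils::write.csv(df, file, row.names = FALSE)
  df
}
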