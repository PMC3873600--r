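# Synthetic patient cohorts: per-subject FA volumes over a tract
# phantom with smooth noise, group-specific FA lesions, FA-score
# couplings, and neuropsychological z-scores drawn from per-group
# normal distributions.

#' Specify a spherical FA lesion
#'
#' A mean FA reduction of `delta_fa` applied inside a sphere (intersected
#' with the tract mask) for subjects of the target patient group(s).
#'
#' @param center_mm length-3 world position of the sphere center (mm).
#' @param radius_mm sphere radius (mm).
#' @param delta_fa mean FA reduction, in `(0, 0.3]`.
#' @param target_groups subset of `c("svPPA", "lvPPA")`.
#' @return an object of class `lesion_spec`.
#' @export
lesion_spec <- function(center_mm, radius_mm, delta_fa,
                        target_groups = c("svPPA", "lvPPA")) {
  if (!(delta_fa > 0 && delta_fa <= 0.3))
    abort("lesion_spec: delta_fa must lie in (0, 0.3]")
  if (!is.finite(radius_mm) || radius_mm <= 0)
    abort("lesion_spec: radius_mm must be positive")
  target_groups <- match.arg(target_groups, c("svPPA", "lvPPA"),
                             several.ok = TRUE)
  structure(list(center_mm = as.numeric(center_mm), radius_mm = radius_mm,
                 delta_fa = delta_fa, target_groups = target_groups),
            class = "lesion_spec")
}

#' Specify an FA-score coupling region
#'
#' Within a spherical region, each subject's FA is shifted by
#' `beta * z` where `z` is the subject's score on `score_name`; used to
#' plant score-FA correlations that regression analyses should recover.
#'
#' @param score_name `"Animals"` or `"BNT"`.
#' @param center_mm,radius_mm coupling sphere (mm).
#' @param beta slope in FA units per z-score unit; finite.
#' @param applies_to group subset the coupling acts on.
#' @return an object of class `coupling_spec`.
#' @export
coupling_spec <- function(score_name = c("Animals", "BNT"), center_mm,
                          radius_mm, beta,
                          applies_to = c("svPPA", "lvPPA")) {
  score_name <- match.arg(score_name)
  if (!is.finite(beta)) abort("coupling_spec: beta must be finite")
  if (!is.finite(radius_mm) || radius_mm <= 0)
    abort("coupling_spec: radius_mm must be positive")
  applies_to <- match.arg(applies_to, c("svPPA", "lvPPA", "control"),
                          several.ok = TRUE)
  structure(list(score_name = score_name, center_mm = as.numeric(center_mm),
                 radius_mm = radius_mm, beta = beta, applies_to = applies_to),
            class = "coupling_spec")
}

# default per-group score distributions (mean, sd) in z units; patient
# values follow the study-sized cohort summaries, controls are the
# z-reference population by construction
default_score_distributions <- function() {
  list(
    Animals = list(lvPPA = c(-2.3, 0.9), svPPA = c(-2.8, 0.8), control = c(0, 1)),
    BNT     = list(lvPPA = c(-5.6, 3.8), svPPA = c(-13.2, 3.4), control = c(0, 1))
  )
}

#' Specify a synthetic cohort
#'
#' Defaults reproduce the study design this package's analyses are
#' exercised on: 13 lvPPA, 11 svPPA, and 34 control subjects, language
#' z-scores per group, a baseline tract FA of 0.45 with smooth Gaussian
#' noise (SD 0.03, FWHM 6 mm), and optional lesions and couplings.
#'
#' @param n_per_group named integer vector with entries `lvPPA`,
#'   `svPPA`, `control` (all >= 2).
#' @param score_distributions nested list `score -> group -> c(mean, sd)`
#'   in z units.
#' @param baseline_fa baseline FA inside the tract mask, in (0, 1).
#' @param background_fa baseline FA outside the tract mask; must stay
#'   below `baseline_fa` so the tract is a ridge of FA, which is what
#'   makes maximum-intensity projection along spokes meaningful.
#' @param fa_noise_sd marginal standard deviation of the smoothed noise
#'   field (FA units).
#' @param smoothness_mm FWHM of the Gaussian noise smoothing kernel (mm).
#' @param lesions list of [lesion_spec()].
#' @param couplings list of [coupling_spec()].
#' @param truncate_z scores are truncated at `mean +/- truncate_z * sd`
#'   of their group distribution to avoid absurd draws.
#' @param seed integer RNG seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(lvPPA = 13L, svPPA = 11L, control = 34L),
                        score_distributions = default_score_distributions(),
                        baseline_fa = 0.45,
                        background_fa = 0.25,
                        fa_noise_sd = 0.03,
                        smoothness_mm = 6,
                        lesions = list(),
                        couplings = list(),
                        truncate_z = 6,
                        seed = 1L) {
  req <- c("lvPPA", "svPPA", "control")
  if (!all(req %in% names(n_per_group)))
    abort("cohort_spec: n_per_group needs entries ", paste(req, collapse = ", "))
  n_per_group <- vapply(n_per_group[req], as.integer, integer(1))
  if (any(n_per_group < 2L)) abort("cohort_spec: all group sizes must be >= 2")
  if (!(baseline_fa > 0 && baseline_fa < 1))
    abort("cohort_spec: baseline_fa must lie in (0, 1)")
  if (!(background_fa > 0 && background_fa < baseline_fa))
    abort("cohort_spec: background_fa must lie in (0, baseline_fa)")
  if (fa_noise_sd <= 0) abort("cohort_spec: fa_noise_sd must be > 0")
  for (sc in names(score_distributions))
    for (g in names(score_distributions[[sc]]))
      if (score_distributions[[sc]][[g]][2] <= 0)
        abort("cohort_spec: score SDs must be > 0 (", sc, "/", g, ")")
  for (l in lesions) {
    if (!inherits(l, "lesion_spec")) abort("cohort_spec: lesions must be lesion_spec objects")
    if (baseline_fa - l$delta_fa <= 0)
      abort("cohort_spec: baseline_fa - delta_fa must stay > 0")
  }
  for (cp in couplings)
    if (!inherits(cp, "coupling_spec"))
      abort("cohort_spec: couplings must be coupling_spec objects")
  structure(list(n_per_group = n_per_group,
                 score_distributions = score_distributions,
                 baseline_fa = baseline_fa, background_fa = background_fa,
                 fa_noise_sd = fa_noise_sd,
                 smoothness_mm = smoothness_mm, lesions = lesions,
                 couplings = couplings, truncate_z = truncate_z,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# separable Gaussian smoothing of a 3-D array; fwhm in mm per axis
smooth_gaussian3d <- function(a, fwhm_mm, spacing) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  for (ax in 1:3) {
    s_vox <- sigma / spacing[ax]
    if (s_vox <= 0) next
    r <- max(1L, ceiling(3 * s_vox))
    k <- exp(-((-r:r)^2) / (2 * s_vox^2))
    k <- k / sum(k)
    out <- a * k[r + 1L]
    for (o in 1:r) {
      out <- out + k[r + 1L + o] * shift3d(a, ax, -o, 0) +
                   k[r + 1L - o] * shift3d(a, ax, +o, 0)
    }
    a <- out
  }
  a
}

# theoretical SD attenuation of unit white noise under the above kernel
smooth_attenuation <- function(fwhm_mm, spacing) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  att <- 1
  for (ax in 1:3) {
    s_vox <- sigma / spacing[ax]
    if (s_vox <= 0) next
    r <- max(1L, ceiling(3 * s_vox))
    k <- exp(-((-r:r)^2) / (2 * s_vox^2))
    k <- k / sum(k)
    att <- att * sqrt(sum(k^2))
  }
  att
}

# lesion / coupling sphere as logical array on the mask grid
sphere_region <- function(mask, center_mm, radius_mm) {
  d <- dim(mask$data)
  ax <- lapply(1:3, function(j) mask$origin[j] + ((1:d[j]) - 1) * mask$spacing[j])
  dx2 <- (ax[[1]] - center_mm[1])^2
  dy2 <- (ax[[2]] - center_mm[2])^2
  dz2 <- (ax[[3]] - center_mm[3])^2
  arr <- outer(outer(dx2, dy2, "+"), dz2, "+")
  arr <= radius_mm^2
}

#' Simulate one subject's FA volume
#'
#' FA = baseline (inside the tract mask; `background_fa` outside) plus
#' smooth zero-mean Gaussian noise (marginal SD `fa_noise_sd` after
#' smoothing), minus `delta_fa` inside each lesion
#' whose target groups include the subject's group, plus `beta * z`
#' inside each coupling region that applies; the result is clipped to
#' `[0, 1]`. The field covers the whole grid; lesions and couplings act
#' only inside the tract mask.
#'
#' @param mask logical [volume3d] tract mask.
#' @param spec a [cohort_spec()].
#' @param subject list with `group` (character) and `scores` (named
#'   numeric, z units), as produced by [simulate_cohort()].
#' @param seed integer seed for this subject's noise field.
#' @return an FA [volume3d].
#' @export
simulate_fa <- function(mask, spec, subject, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  mask <- as_volume3d(mask)
  d <- dim(mask$data)
  noise <- with_seed(seed, array(stats::rnorm(prod(d)), d))
  noise <- smooth_gaussian3d(noise, spec$smoothness_mm, mask$spacing)
  att <- smooth_attenuation(spec$smoothness_mm, mask$spacing)
  base <- ifelse(mask$data, spec$baseline_fa, spec$background_fa)
  fa <- base + spec$fa_noise_sd * noise / att
  for (l in spec$lesions) {
    if (!(subject$group %in% l$target_groups)) next
    reg <- sphere_region(mask, l$center_mm, l$radius_mm) & mask$data
    if (!any(reg)) abort("simulate_fa: lesion sphere misses the tract mask")
    fa[reg] <- fa[reg] - l$delta_fa
  }
  for (cp in spec$couplings) {
    if (!(subject$group %in% cp$applies_to)) next
    z <- subject$scores[[cp$score_name]]
    if (is.null(z) || !is.finite(z))
      abort("simulate_fa: subject lacks score ", cp$score_name)
    reg <- sphere_region(mask, cp$center_mm, cp$radius_mm) & mask$data
    if (!any(reg)) abort("simulate_fa: coupling sphere misses the tract mask")
    fa[reg] <- fa[reg] + cp$beta * z
  }
  volume3d(pmin(pmax(fa, 0), 1), spacing = mask$spacing, origin = mask$origin)
}

# draw truncated-normal scores for one group/score
draw_scores <- function(n, ms, truncate_z) {
  z <- stats::rnorm(n, ms[1], ms[2])
  lim <- truncate_z * ms[2]
  pmin(pmax(z, ms[1] - lim), ms[1] + lim)
}

#' Simulate a full cohort
#'
#' Draws group labels, language z-scores, and (optionally) one FA
#' volume per subject over the given tract mask. Fully reproducible
#' from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @param mask logical [volume3d] tract mask (required when
#'   `volumes = TRUE`).
#' @param volumes generate per-subject FA volumes? Scores-only cohorts
#'   (`FALSE`) are cheap and useful for distributional checks.
#' @return list with `table` (data.frame: `id`, `group`, one column per
#'   score, `fa_index`) and `volumes` (list of FA [volume3d] or `NULL`).
#' @export
simulate_cohort <- function(spec, mask = NULL, volumes = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (volumes && is.null(mask))
    abort("simulate_cohort: mask required when volumes = TRUE")
  groups <- rep(names(spec$n_per_group), spec$n_per_group)
  n <- length(groups)
  score_names <- names(spec$score_distributions)
  tab <- data.frame(id = sprintf("sub-%03d", seq_len(n)),
                    group = groups, stringsAsFactors = FALSE)
  seeds <- derive_seeds(spec$seed, n + 1L)
  tab_scores <- with_seed(seeds[n + 1L], {
    out <- matrix(NA_real_, n, length(score_names),
                  dimnames = list(NULL, score_names))
    for (sc in score_names) {
      for (g in names(spec$n_per_group)) {
        ms <- spec$score_distributions[[sc]][[g]]
        if (is.null(ms)) abort("simulate_cohort: no distribution for ", sc, "/", g)
        sel <- which(groups == g)
        out[sel, sc] <- draw_scores(length(sel), ms, spec$truncate_z)
      }
    }
    out
  })
  for (sc in score_names) tab[[score_column(sc)]] <- tab_scores[, sc]
  vols <- NULL
  if (volumes) {
    vols <- vector("list", n)
    for (i in seq_len(n)) {
      subject <- list(group = groups[i],
                      scores = as.list(tab_scores[i, , drop = TRUE]))
      vols[[i]] <- simulate_fa(mask, spec, subject, seed = seeds[i])
    }
  }
  tab$fa_index <- seq_len(n)
  list(table = tab, volumes = vols)
}

# CSV column name for a score ("Animals" -> "animals_z")
score_column <- function(score_name) paste0(tolower(score_name), "_z")
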