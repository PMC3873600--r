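small_spec <- function(...) {
  cohort_spec(n_per_group = c(lvPPA = 2L, svPPA = 2L, control = 2L), ...)
}

test_that("default cohort reproduces the study group sizes", {
  sim <- simulate_cohort(cohort_spec(seed = 1), volumes = FALSE)
  expect_equal(nrow(sim$table), 58L)
  expect_equal(as.vector(table(sim$table$group)[c("lvPPA", "svPPA", "control")]),
               c(13L, 11L, 34L))
  expect_equal(anyDuplicated(sim$table$id), 0L)
  expect_true(all(is.finite(sim$table$animals_z)) &&
              all(is.finite(sim$table$bnt_z)))
})

test_that("cohort simulation is bit-reproducible from the seed", {
  spec <- small_spec(seed = 77)
  a <- simulate_cohort(spec, slab_mask())
  b <- simulate_cohort(spec, slab_mask())
  expect_identical(a$table, b$table)
  expect_identical(a$volumes, b$volumes)
  c <- simulate_cohort(small_spec(seed = 78), slab_mask(), volumes = FALSE)
  expect_false(identical(a$table$bnt_z, c$table$bnt_z))
})

test_that("score draws match their group distributions (10,000 draws)", {
  spec <- cohort_spec(n_per_group = c(lvPPA = 2L, svPPA = 10000L, control = 2L),
                      seed = 5)
  sim <- simulate_cohort(spec, volumes = FALSE)
  bnt <- sim$table$bnt_z[sim$table$group == "svPPA"]
  expect_lt(abs(mean(bnt) - (-13.2)), 0.1)
  expect_lt(abs(sd(bnt) - 3.4), 0.1)
  an <- sim$table$animals_z[sim$table$group == "svPPA"]
  expect_lt(abs(mean(an) - (-2.8)), 0.1)
  expect_lt(abs(sd(an) - 0.8), 0.1)
})

test_that("score truncation bounds draws at mean +/- k sd", {
  spec <- cohort_spec(n_per_group = c(lvPPA = 2L, svPPA = 2000L, control = 2L),
                      truncate_z = 1, seed = 11)
  sim <- simulate_cohort(spec, volumes = FALSE)
  bnt <- sim$table$bnt_z[sim$table$group == "svPPA"]
  expect_true(all(bnt >= -13.2 - 3.4 - 1e-9 & bnt <= -13.2 + 3.4 + 1e-9))
})

test_that("control FA fields average to the baseline inside the mask", {
  mask <- stat_mask()
  spec <- cohort_spec(n_per_group = c(lvPPA = 2L, svPPA = 2L, control = 40L),
                      seed = 3)
  sim <- simulate_cohort(spec, mask)
  ctl <- which(sim$table$group == "control")
  means <- vapply(sim$volumes[ctl], function(v) mean(v$data[mask$data]),
                  numeric(1))
  # per-subject mean of the correlated field has SD below the marginal
  # noise SD, so 4 * 0.03 / sqrt(n) safely bounds the grand mean error
  expect_lt(abs(mean(means) - 0.45), 4 * 0.03 / sqrt(length(ctl)))
  # marginal noise SD is calibrated after smoothing: across subjects at
  # fixed voxels the SD is 0.03 (within-mask sample SDs would be biased
  # low by the spatial correlation of the smoothed field)
  stack <- vapply(sim$volumes[ctl], function(v) v$data[mask$data],
                  numeric(sum(mask$data)))
  per_voxel_sd <- apply(stack, 1, sd)
  expect_lt(abs(mean(per_voxel_sd) - 0.03), 0.004)
})

test_that("lesions lower group-mean FA by delta inside the sphere only", {
  mask <- stat_mask()
  ctr <- (dim(mask$data) - 1) / 2 * mask$spacing
  les <- lesion_spec(center_mm = ctr, radius_mm = 6, delta_fa = 0.10,
                     target_groups = "svPPA")
  spec <- cohort_spec(n_per_group = c(lvPPA = 2L, svPPA = 110L, control = 20L),
                      lesions = list(les), seed = 8)
  sim <- simulate_cohort(spec, mask)
  reg <- tractfa:::sphere_region(mask, ctr, 6) & mask$data
  outside <- mask$data & !tractfa:::sphere_region(mask, ctr, 9)
  sv <- which(sim$table$group == "svPPA")
  ctl <- which(sim$table$group == "control")
  sv_in <- mean(vapply(sim$volumes[sv], function(v) mean(v$data[reg]), numeric(1)))
  sv_out <- mean(vapply(sim$volumes[sv], function(v) mean(v$data[outside]), numeric(1)))
  ctl_in <- mean(vapply(sim$volumes[ctl], function(v) mean(v$data[reg]), numeric(1)))
  se <- 3 * 0.03 / sqrt(110)
  expect_lt(abs(sv_in - (0.45 - 0.10)), se + 0.002)
  expect_lt(abs(sv_out - 0.45), se + 0.002)
  expect_lt(abs(ctl_in - 0.45), 3 * 0.03 / sqrt(20) + 0.002)
})

test_that("zero coupling leaves score and regional FA uncorrelated", {
  mask <- stat_mask()
  ctr <- (dim(mask$data) - 1) / 2 * mask$spacing
  spec <- cohort_spec(n_per_group = c(lvPPA = 2L, svPPA = 100L, control = 2L),
                      seed = 21)
  sim <- simulate_cohort(spec, mask)
  reg <- tractfa:::sphere_region(mask, ctr, 6) & mask$data
  sv <- which(sim$table$group == "svPPA")
  fa <- vapply(sim$volumes[sv], function(v) mean(v$data[reg]), numeric(1))
  r <- cor(fa, sim$table$bnt_z[sv])
  expect_lt(abs(r), 0.3)   # ~3 standard errors at n = 100
})

test_that("couplings tie regional FA to the score with slope beta", {
  mask <- stat_mask()
  ctr <- (dim(mask$data) - 1) / 2 * mask$spacing
  cp <- coupling_spec("BNT", center_mm = ctr, radius_mm = 7, beta = 0.01,
                      applies_to = "svPPA")
  spec <- cohort_spec(n_per_group = c(lvPPA = 2L, svPPA = 80L, control = 2L),
                      couplings = list(cp), seed = 13)
  sim <- simulate_cohort(spec, mask)
  reg <- tractfa:::sphere_region(mask, ctr, 5) & mask$data
  sv <- which(sim$table$group == "svPPA")
  fa <- vapply(sim$volumes[sv], function(v) mean(v$data[reg]), numeric(1))
  z <- sim$table$bnt_z[sv]
  fit <- coef(lm(fa ~ z))
  expect_lt(abs(fit[["z"]] - 0.01), 0.004)
  expect_gt(cor(fa, z), 0.5)
})

test_that("FA fields are clipped to [0, 1] and invalid specs are rejected", {
  mask <- stat_mask()
  ctr <- (dim(mask$data) - 1) / 2 * mask$spacing
  spec <- small_spec(fa_noise_sd = 0.4, seed = 2)
  sim <- simulate_cohort(spec, mask)
  rng <- range(vapply(sim$volumes, function(v) range(v$data), numeric(2)))
  expect_gte(rng[1], 0); expect_lte(rng[2], 1)
  expect_error(lesion_spec(ctr, 5, 0.5), "delta_fa")
  expect_error(cohort_spec(n_per_group = c(lvPPA = 1L, svPPA = 2L, control = 2L)),
               ">= 2")
  expect_error(cohort_spec(baseline_fa = 1.2), "baseline_fa")
  expect_error(cohort_spec(lesions = list(lesion_spec(ctr, 5, 0.3)),
                           baseline_fa = 0.25, background_fa = 0.1),
               "delta_fa")
  expect_error(cohort_spec(background_fa = 0.6), "background_fa")
  # lesion sphere missing the mask is a simulation-time error
  far <- lesion_spec(c(-50, -50, -50), 2, 0.1)
  spec2 <- small_spec(lesions = list(far), seed = 4)
  expect_error(simulate_cohort(spec2, mask), "misses")
})
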