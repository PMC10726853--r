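test_that("reference model: per-patch mean and n-1 SD, degeneracy flags", {
  prof <- profiles_from_matrix(matrix(c(2.0, 2.2, 2.4), 3, 1))
  ref <- fit_reference(prof)
  expect_equal(ref$patch_mean_ref, 2.2)
  expect_equal(ref$patch_sd_ref, 0.2)
  expect_equal(ref$n_ref, 3L)

  same <- fit_reference(profiles_from_matrix(matrix(2.2, 4, 2)))
  expect_true(all(same$degenerate))

  expect_error(fit_reference(prof[1]), "at least 2")
  expect_error(fit_reference(list(patch_profile(1:3), patch_profile(1:2))),
               "mixed")
})

test_that("z-scores against the reference, with affine invariance", {
  ref <- fit_reference(profiles_from_matrix(matrix(c(2.0, 2.2, 2.4), 3, 1)))
  expect_equal(zscore_patches(patch_profile(2.2), ref), 0)
  expect_equal(zscore_patches(patch_profile(1.8), ref), -2.0)

  # z is invariant under x -> c*x + d applied to patient and reference alike
  set.seed(7)
  mat <- matrix(rnorm(5 * 4, 2.4, 0.2), 5, 4)
  pat <- rnorm(4, 2.2, 0.2)
  z0 <- zscore_patches(patch_profile(pat),
                       fit_reference(profiles_from_matrix(mat)))
  z1 <- zscore_patches(patch_profile(1.7 * pat + 0.3),
                       fit_reference(profiles_from_matrix(1.7 * mat + 0.3)))
  expect_equal(z1, z0, tolerance = 1e-10)

  # degenerate patch yields NA, never infinity
  refd <- fit_reference(profiles_from_matrix(matrix(2.2, 3, 1)))
  expect_true(is.na(zscore_patches(patch_profile(1.9), refd)))
})

test_that("the Crawford-Howell scaling flag divides z by sqrt(1 + 1/n)", {
  mat <- matrix(c(2.0, 2.2, 2.4), 3, 1)
  ref <- fit_reference(profiles_from_matrix(mat))
  z <- zscore_patches(patch_profile(1.8), ref)
  zch <- zscore_patches(patch_profile(1.8), ref, ch_correction = TRUE)
  expect_equal(zch, z / sqrt(1 + 1 / 3))
})

test_that("exhaustive null enumerates all leave-one-as-singleton relabelings", {
  ctl <- profiles_from_matrix(matrix(c(2.0, 2.1, 2.2), 3, 1))
  ref <- fit_reference(ctl)
  pat <- patch_profile(1.5)
  null_z <- exhaustive_null(pat, ref)
  expect_equal(dim(null_z), c(4L, 1L))

  # row 1 (the true patient as singleton) reproduces zscore_patches exactly
  expect_identical(null_z[1, ], zscore_patches(pat, ref))

  # every row verified against independent enumeration of the 4 relabelings
  oracle <- oracle_singleton_enumeration(rbind(1.5, matrix(c(2.0, 2.1, 2.2))))
  expect_equal(null_z, oracle$z, tolerance = 1e-12)

  # all pooled values equal: z undefined everywhere, p = 1 by the tie rule
  refc <- fit_reference(profiles_from_matrix(matrix(2, 3, 1)))
  nz <- exhaustive_null(patch_profile(2), refc)
  expect_true(all(is.na(nz)))
})

test_that("permutation p-values: tie-inclusive ratio on the discrete grid", {
  # observed strictly the minimum of 4 rows -> p = 1/4
  nz <- matrix(c(-3, 0, 1, 2), 4, 1)
  expect_equal(patch_pvalues(-3, nz), 0.25)
  # observed the maximum -> p = 1
  expect_equal(patch_pvalues(2, nz), 1.0)
  # all rows tie -> p = 1
  expect_equal(patch_pvalues(0, matrix(0, 4, 1)), 1.0)
  # undefined null cells count as not smaller
  nz2 <- matrix(c(-3, NA, NA, 2), 4, 1)
  expect_equal(patch_pvalues(-3, nz2), 0.25)
  # undefined observed -> NA
  expect_true(is.na(patch_pvalues(NA_real_, nz)))
})

test_that("p-values agree exactly with brute-force enumeration on random instances", {
  set.seed(2024)
  for (n_ref in 2:6) {
    for (N in c(1, 3, 5)) {
      pooled <- matrix(rnorm((n_ref + 1) * N, 2.4, 0.15), n_ref + 1, N)
      ref <- fit_reference(profiles_from_matrix(pooled[-1, , drop = FALSE]))
      pat <- patch_profile(pooled[1, ])
      p <- patch_pvalues(zscore_patches(pat, ref), exhaustive_null(pat, ref))
      expect_identical(p, oracle_singleton_enumeration(pooled)$p)
    }
  }
})

test_that("thresholding: per-patch calls, discreteness warning, N=1 max-stat reduction", {
  expect_equal(threshold_map(c(0.011, 0.5, 1.0), 0.05),
               c(TRUE, FALSE, FALSE))
  expect_error(threshold_map(c(0.5), alpha = 1.5), "alpha")

  # alpha below the attainable grid minimum: warn, nothing can be thin
  nz <- matrix(rnorm(40), 4, 10)
  p <- rep(0.25, 10)
  expect_warning(res <- threshold_map(p, alpha = 0.2, null_z = nz),
                 "attainable")
  expect_false(any(res))

  # with a single patch, max-stat equals the per-patch test
  set.seed(5)
  pooled <- matrix(rnorm(8), 8, 1)
  ref <- fit_reference(profiles_from_matrix(pooled[-1, , drop = FALSE]))
  pat <- patch_profile(pooled[1, ])
  z <- zscore_patches(pat, ref)
  nz1 <- exhaustive_null(pat, ref)
  p1 <- patch_pvalues(z, nz1)
  for (a in c(0.15, 0.4, 0.9))
    expect_identical(threshold_map(p1, a, "max-stat", z, nz1),
                     threshold_map(p1, a, "per-patch"))
})

test_that("thin-patch fraction uses evaluable patches as denominator", {
  expect_equal(thin_patch_fraction(rep(FALSE, 100)), 0.0)
  expect_equal(thin_patch_fraction(c(rep(TRUE, 5), rep(FALSE, 95))), 0.05)
  # 3 thin of 50 evaluable among 60 patches -> 0.06
  evaluable <- c(rep(TRUE, 50), rep(FALSE, 10))
  thin <- c(rep(TRUE, 3), rep(FALSE, 57))
  expect_equal(thin_patch_fraction(thin, evaluable), 0.06)
  expect_error(thin_patch_fraction(logical(3), rep(FALSE, 3)), "evaluable")
})

test_that("end-to-end mosaic run: known-answer cases", {
  v <- 40
  sch <- make_parcellation(v, 8)
  ctl <- make_control_maps(25, v, seed = 300)

  # patient equal to the control mean at every vertex: all z = 0, fraction 0
  mean_map <- vertex_map(colMeans(do.call(rbind,
                                          lapply(ctl, `[[`, "values"))))
  res0 <- run_map_subject(mean_map, ctl, sch)
  expect_true(all(abs(res0$z) < 1e-10))
  expect_equal(res0$thin_patch_fraction, 0)
  expect_equal(res0$n_permutations, 26L)

  # one patch shifted far down is called thin at the grid minimum p
  pat_vals <- mean_map$values
  ref <- fit_reference(lapply(ctl, patch_means, scheme = sch))
  hit <- sch$labels == 3
  pat_vals[hit] <- pat_vals[hit] - 6 * ref$patch_sd_ref[3]
  res1 <- run_map_subject(vertex_map(pmax(pat_vals, 0)), ctl, sch)
  expect_equal(res1$p[3], 1 / 26)
  expect_true(res1$thin[3])
  expect_equal(res1$thin_patch_fraction, 1 / 8)
})

test_that("monotonicity: lowering a vertex never raises that patch's z or p", {
  set.seed(88)
  v <- 30
  sch <- make_parcellation(v, 5)
  ctl <- make_control_maps(21, v, seed = 40)
  base <- make_control_maps(1, v, seed = 999)[[1]]
  res_a <- run_map_subject(base, ctl, sch)
  for (drop in c(0.1, 0.5, 1.0)) {
    vals <- base$values
    vx <- sample(v, 1)
    vals[vx] <- max(vals[vx] - drop, 0)
    res_b <- run_map_subject(vertex_map(vals), ctl, sch)
    k <- sch$labels[vx]
    expect_lte(res_b$z[k], res_a$z[k])
    expect_lte(res_b$p[k], res_a$p[k])
  }
})

test_that("the mosaic output is invariant to global shift and positive rescaling", {
  v <- 24
  sch <- make_parcellation(v, 6)
  ctl <- make_control_maps(21, v, seed = 77)
  pat <- make_control_maps(1, v, seed = 1234)[[1]]
  res <- run_map_subject(pat, ctl, sch)
  tr <- function(m) vertex_map(1.3 * m$values + 0.4, m$subject_id)
  res_t <- run_map_subject(tr(pat), lapply(ctl, tr), sch)
  expect_equal(res_t$z, res$z, tolerance = 1e-9)
  expect_identical(res_t$p, res$p)
  expect_identical(res_t$thin, res$thin)
})

test_that("cohort runner matches per-subject runs and supports residualization", {
  v <- 30
  sch <- make_parcellation(v, 6)
  ctl <- make_control_maps(21, v, seed = 60)
  pats <- make_control_maps(3, v, seed = 160)
  fr <- run_map_cohort(pats, ctl, sch)
  expect_equal(nrow(fr), 3)
  one <- run_map_subject(pats[[1]], ctl, sch)
  expect_identical(fr$thin_patch_fraction[1], one$thin_patch_fraction)

  covs <- data.frame(age = rnorm(24, 40, 10),
                     sex = sample(c("F", "M"), 24, replace = TRUE))
  fr2 <- run_map_cohort(pats, ctl, sch, covariates = covs)
  expect_true(all(fr2$thin_patch_fraction >= 0 &
                    fr2$thin_patch_fraction <= 1))
})
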