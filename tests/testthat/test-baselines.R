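test_that("sigma to FWHM conversion", {
  expect_equal(sigma_to_fwhm(2), 4.7096, tolerance = 1e-4)
  expect_equal(sigma_to_fwhm(0), 0)
  expect_equal(sigma_to_fwhm(3), 7.0645, tolerance = 1e-4)
  expect_equal(sigma_to_fwhm(1), 2 * sqrt(2 * log(2)))
  expect_equal(fwhm_to_sigma(sigma_to_fwhm(2.7)), 2.7)
  expect_error(sigma_to_fwhm(-1), ">= 0")
})

test_that("mesh smoothing: identity at sigma 0, constants preserved, hand example", {
  mesh <- make_mesh(9, "grid")
  vals <- abs(rnorm(9, 2.4, 0.3))
  vm <- vertex_map(vals)
  expect_identical(smooth_on_mesh(vm, mesh, 0)$values, vals)
  const <- smooth_on_mesh(vertex_map(rep(2.2, 9)), mesh, 3)
  expect_equal(const$values, rep(2.2, 9), tolerance = 1e-12)

  # 1D chain [0,1,0], one iteration, w = 0.5: center 0.5, ends 0.25
  chain <- make_mesh(3, "path")
  sm <- smooth_on_mesh(vertex_map(c(0, 1, 0)), chain, sigma = 0.7, w = 0.5)
  expect_equal(sm$values, c(0.25, 0.5, 0.25))
})

test_that("smoothing conserves the global mean on a closed mesh and contracts variance", {
  mesh <- make_mesh(60, "ring")
  set.seed(21)
  vals <- abs(rnorm(60, 2.4, 0.3))
  for (sigma in c(1, 2, 4)) {
    sm <- smooth_on_mesh(vertex_map(vals), mesh, sigma)
    expect_equal(mean(sm$values), mean(vals), tolerance = 1e-10)
    expect_lt(var(sm$values), var(vals))
  }
  # more smoothing contracts more
  v2 <- var(smooth_on_mesh(vertex_map(vals), mesh, 2)$values)
  v4 <- var(smooth_on_mesh(vertex_map(vals), mesh, 4)$values)
  expect_lt(v4, v2)
})

test_that("singleton-versus-group without covariates is the Crawford-Howell test", {
  # hand example: controls {2.0, 2.2, 2.4}, patient 1.8
  res <- singleton_vs_group(vertex_map(1.8),
                            lapply(c(2.0, 2.2, 2.4), vertex_map))
  expect_equal(res$t, -1.7321, tolerance = 1e-4)
  expect_equal(res$df, 2)
  expect_equal(res$p, 0.1127, tolerance = 1e-4)

  # patient at the control mean: t = 0, one-sided p = 0.5
  res0 <- singleton_vs_group(vertex_map(2.2),
                             lapply(c(2.0, 2.2, 2.4), vertex_map))
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 0.5)

  # random instances agree with the closed form to 1e-10
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(5:12, 1)
    ctl_vals <- matrix(rnorm(n * 6, 2.4, 0.2), n, 6)
    pat_vals <- rnorm(6, 2.2, 0.2)
    res <- singleton_vs_group(vertex_map(abs(pat_vals)),
                              lapply(seq_len(n), function(i)
                                vertex_map(abs(ctl_vals)[i, ])))
    for (k in 1:6) {
      or <- oracle_crawford_howell(abs(pat_vals)[k], abs(ctl_vals)[, k])
      expect_equal(res$t[k], or$t, tolerance = 1e-10)
      expect_equal(res$p[k], or$p, tolerance = 1e-10)
    }
  }
})

test_that("covariate-adjusted singleton test matches an lm-based oracle", {
  set.seed(77)
  n <- 12
  v <- 6
  covs <- data.frame(age = c(rnorm(n, 40, 12), 43),
                     sex = c(rep(c("F", "M"), n / 2), "F"))
  ctl <- make_control_maps(n, v, seed = 500)
  pat <- make_control_maps(1, v, seed = 501)[[1]]
  res <- singleton_vs_group(pat, ctl, covariates = covs)
  expect_equal(res$df, n - 3)

  # oracle via lm() per vertex
  sex01 <- as.integer(covs$sex == "M")
  X <- cbind(1, covs$age[1:n], sex01[1:n])
  x0 <- c(1, covs$age[n + 1], sex01[n + 1])
  h <- drop(1 + t(x0) %*% solve(crossprod(X)) %*% x0)
  for (k in seq_len(v)) {
    y <- vapply(ctl, function(m) m$values[k], 0)
    fit <- lm(y ~ covs$age[1:n] + sex01[1:n])
    pred <- sum(coef(fit) * x0)
    t_or <- (pat$values[k] - pred) / (summary(fit)$sigma * sqrt(h))
    expect_equal(res$t[k], t_or, tolerance = 1e-10)
    expect_equal(res$p[k], pt(t_or, n - 3), tolerance = 1e-10)
  }

  # a patient lying exactly on the control regression plane scores t = 0
  X3 <- X
  beta <- solve(crossprod(X3), crossprod(X3, vapply(ctl, function(m)
    m$values[1], 0)))
  pat0 <- vertex_map(rep(max(drop(x0 %*% beta), 0.01), v))
  res0 <- singleton_vs_group(pat0, ctl, covariates = covs)
  expect_equal(res0$t[1], 0, tolerance = 1e-8)
  expect_equal(res0$p[1], 0.5, tolerance = 1e-8)

  # collinear design is rejected with the offending column named
  covs2 <- covs
  covs2$age <- 5
  expect_error(singleton_vs_group(pat, ctl, covariates = covs2),
               "collinear")
})

test_that("BH-FDR step-up matches hand-derived rejections and is monotone in alpha", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.04, 0.5), 0.05),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_false(any(fdr_bh(rep(1, 10), 0.05)))
  expect_true(fdr_bh(0.04, 0.05))
  expect_equal(fdr_bh(numeric(0)), logical(0))

  set.seed(9)
  p <- runif(50)^2
  alphas <- c(0.01, 0.05, 0.1, 0.2)
  counts <- vapply(alphas, function(a) sum(fdr_bh(p, a)), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("max-statistic FWE: null-typical data rejected nowhere, depressed vertex caught", {
  set.seed(12)
  null_stats <- matrix(rnorm(200 * 10), 200, 10)
  observed <- colMeans(null_stats)
  expect_false(any(maxstat_fwe(observed, null_stats, 0.05)))

  observed2 <- observed
  observed2[4] <- min(null_stats) - 1
  rej <- maxstat_fwe(observed2, null_stats, 0.05)
  expect_true(rej[4])
  expect_false(any(rej[-4]))

  # 1-element map reduces to the element-wise permutation test
  ns <- matrix(rnorm(100), 100, 1)
  obs <- -1.2
  expect_identical(maxstat_fwe(obs, ns, 0.05),
                   sum(ns <= obs) / 100 <= 0.05)
  expect_warning(maxstat_fwe(0, matrix(rnorm(5), 5, 1), 0.05), "unreliable")
})

test_that("burden fraction counts only masked elements", {
  expect_equal(burden_fraction(rep(FALSE, 200), rep(TRUE, 200)), 0.0)
  expect_equal(burden_fraction(c(rep(TRUE, 10), rep(FALSE, 190)),
                               rep(TRUE, 200)), 0.05)
  # rejections outside the mask are ignored: 5 rejected, 3 inside a 60-mask
  rej <- c(rep(TRUE, 5), rep(FALSE, 75))
  mask <- c(rep(FALSE, 2), rep(TRUE, 60), rep(FALSE, 18))
  expect_equal(burden_fraction(rej, mask), 0.05)
  expect_error(burden_fraction(logical(3), rep(FALSE, 3)), "empty mask")
})

test_that("baseline pipeline returns a burden fraction for both corrections", {
  v <- 60
  ctl <- make_control_maps(25, v, seed = 700)
  pat_vals <- colMeans(do.call(rbind, lapply(ctl, `[[`, "values")))
  pat_vals[1:6] <- pat_vals[1:6] - 1.2
  pat <- vertex_map(pmax(pat_vals, 0.05))
  for (corr in c("fdr", "maxstat")) {
    res <- run_baseline_subject(pat, ctl, correction = corr)
    expect_true(res$burden_fraction >= 0.05 && res$burden_fraction <= 0.5)
    expect_true(all(which(res$rejected) %in% 1:6))
  }
})
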