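test_that("pair responses enumerate ordered pairs correctly", {
  expect_equal(pair_response(c(1, 1, 2), "squared_difference"), c(0, 1, 1))
  expect_equal(pair_response(c(0, 2, 1), "cross_product"), c(0, 0, 2))
  expect_error(pair_response(c(1, 2), "squared_difference"), "at least 3")
  # pair order matches the GRM upper triangle (column-major)
  y <- c(1, 2, 4)
  expect_equal(pair_response(y, "squared_difference"),
               c((1 - 2)^2, (1 - 4)^2, (2 - 4)^2))
})

test_that("pair moments match theory: intercept 2*var and var(Y) = 8 sigma_y^4", {
  set.seed(41)
  y <- rnorm(2500, 5, sqrt(2))
  yy <- pair_response(y, "squared_difference")
  v <- var(y)
  # E(Y) = 2 sigma_y^2 for unrelated pairs
  expect_lt(abs(mean(yy) - 2 * v), 4 * sd(yy) / sqrt(length(y)))
  # var(Y) = 8 sigma_y^4 for a Gaussian phenotype
  expect_lt(abs(var(yy) - 8 * v^2), 0.05 * 8 * v^2)
})

test_that("he_fit recovers heritability and its intercept expectation", {
  set.seed(42)
  pf <- polygenic_fit(n = 800, m = 100, rho = 0)
  fit <- pf$fit
  expect_lt(abs(fit$h2 - 0.5), 0.1)
  expect_equal(fit$mu, 2, tolerance = 0.05)  # standardized y: 2 sigma_y^2 = 2
  expect_equal(fit$n_pairs, 800 * 799 / 2)
  # sufficient-statistic OLS agrees with an explicit pair regression
  y <- standardize_phenotype(pf$sim$phenotype$y[1:60])
  sub <- pf$sim$grm$omega[1:60, 1:60]
  grm_sub <- structure(list(omega = sub, n = 60, m = pf$sim$grm$m,
                            scores = NULL, denominator = "markers"),
                       class = "grm")
  f2 <- suppressWarnings(he_fit(y, grm_sub, standardize = FALSE))
  ref <- lm(pair_response(y) ~ grm_offdiag(grm_sub))
  expect_equal(f2$b, unname(coef(ref)[2]), tolerance = 1e-9)
  expect_equal(f2$mu, unname(coef(ref)[1]), tolerance = 1e-9)
  expect_equal(f2$se_b_ols, unname(summary(ref)$coefficients[2, 2]),
               tolerance = 1e-9)
})

test_that("null phenotypes give heritability near zero", {
  set.seed(43)
  calls <- matrix(rbinom(500 * 60, 2, 0.5), 500, 60)
  grm <- compute_grm(standardize_genotypes(calls))
  fit <- suppressWarnings(he_fit(rnorm(500), grm))
  expect_lt(abs(fit$h2), 3 * fit$se_h2 + 0.05)
})

test_that("heritability is invariant to affine phenotype transforms", {
  set.seed(44)
  pf <- polygenic_fit(n = 300, m = 50, rho = 0)
  y <- pf$sim$phenotype$y
  f1 <- suppressWarnings(he_fit(y, pf$sim$grm, standardize = FALSE))
  f2 <- suppressWarnings(he_fit(3.7 * y, pf$sim$grm, standardize = FALSE))
  f3 <- suppressWarnings(he_fit(y + 11, pf$sim$grm, standardize = FALSE))
  expect_equal(f1$h2, f2$h2, tolerance = 1e-10)
  expect_equal(f1$h2, f3$h2, tolerance = 1e-10)
})

test_that("cross-product coefficient is half the squared-difference one", {
  set.seed(45)
  bs <- bc <- numeric(25)
  for (r in 1:25) {
    pf <- polygenic_fit(n = 400, m = 60, rho = 0)
    y <- pf$sim$phenotype$y
    bs[r] <- suppressWarnings(he_fit(y, pf$sim$grm)$b)
    bc[r] <- suppressWarnings(he_fit(y, pf$sim$grm, method = "cross_product")$b)
  }
  # magnitude relation |b_CP| = |b_SD| / 2; observed sign of b_CP is positive
  expect_lt(abs(mean(abs(bc)) - mean(abs(bs)) / 2),
            3 * sd(abs(bc) - abs(bs) / 2) / sqrt(25) + 0.01)
  expect_gt(mean(sign(bc)), 0.9)
  expect_lt(mean(sign(bs)), -0.9)
  # and the cross-product heritability matches the squared-difference one
  expect_lt(abs(mean(bc) - mean(-bs / 2)), 0.05)
})

test_that("analytic SEs reproduce the closed-form reference points", {
  expect_equal(round(analytic_se(1000, 1)$se_b, 3), 0.004)
  expect_equal(round(analytic_se(1000, 1)$se_h2, 3), 0.002)
  expect_equal(round(analytic_se(1000, 100)$se_h2, 3), 0.020)
  expect_equal(analytic_se(1000, 29, simplified = TRUE)$se_h2,
               sqrt(16 * 29 / (1000 * 999)) / 2, tolerance = 1e-12)
  expect_equal(analytic_se(1000, 29, simplified = TRUE)$se_h2,
               2 * sqrt(29) / 1000, tolerance = 1e-2)
  expect_equal(round(analytic_se(1000, 29)$se_h2, 3), 0.011)
  expect_error(analytic_se(2, 1), "n >= 3")
})

test_that("covariate residualization behaves like least squares", {
  set.seed(46)
  y <- rnorm(50, 3)
  expect_equal(residualize_covariates(y), y - mean(y), tolerance = 1e-12)
  x <- rnorm(50)
  expect_lt(max(abs(residualize_covariates(2 + 3 * x, cbind(x)))), 1e-10)
  expect_error(residualize_covariates(y, cbind(x, x)), "rank deficient")
  # orthogonal covariate leaves the heritability estimate unchanged
  pf <- polygenic_fit(n = 300, m = 40, rho = 0)
  yy <- pf$sim$phenotype$y
  z <- rnorm(300)
  z <- residualize_covariates(z) - drop(crossprod(yy - mean(yy), z)) /
    sum((yy - mean(yy))^2) * (yy - mean(yy))
  y_res <- residualize_covariates(yy, cbind(z))
  f1 <- suppressWarnings(he_fit(residualize_covariates(yy), pf$sim$grm,
                                standardize = FALSE))
  f2 <- suppressWarnings(he_fit(y_res, pf$sim$grm, standardize = FALSE))
  expect_equal(f1$h2, f2$h2, tolerance = 1e-10)
})

test_that("multi-component regression splits tagged variance", {
  set.seed(47)
  n <- 500
  g1 <- matrix(rbinom(n * 50, 2, 0.5), n, 50)
  g2 <- matrix(rbinom(n * 50, 2, 0.5), n, 50)
  b1 <- rnorm(50); b2 <- rnorm(50)
  gv <- drop(g1 %*% b1 + g2 %*% b2)
  s2a <- 0.5 * (sum(b1^2) + sum(b2^2))
  y <- gv + rnorm(n, 0, sqrt(s2a))   # h2 = 0.5, split over the two blocks
  grm1 <- compute_grm(standardize_genotypes(g1))
  grm2 <- compute_grm(standardize_genotypes(g2))
  mc <- multi_component_he(y, list(grm1, grm2))
  share1 <- 0.5 * sum(b1^2) / (sum(b1^2) + sum(b2^2))
  expect_lt(abs(mc$h2[[1]] - share1), 0.12)
  expect_lt(abs(mc$h2_total - 0.5), 0.2)
  # single component reduces to he_fit
  one <- multi_component_he(y, grm1)
  ref <- suppressWarnings(he_fit(y, grm1))
  expect_equal(unname(one$b[1]), ref$b, tolerance = 1e-8)
  # null component tags nothing
  g3 <- matrix(rbinom(n * 50, 2, 0.5), n, 50)
  grm3 <- compute_grm(standardize_genotypes(g3))
  mc3 <- multi_component_he(y, list(grm1, grm3))
  expect_lt(abs(mc3$h2[[2]]), 0.1)
  expect_error(multi_component_he(y, list(grm1, grm1)), "collinear")
})
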