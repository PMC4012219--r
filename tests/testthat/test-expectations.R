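test_that("single-marker expectation evaluates the tagging formula", {
  # standardized trait, QTL variance 0.5 (beta = 1 at p = 0.5)
  expect_equal(expected_b_single(ld_pair(0.5, 0.5, rho = 0.25), 1), -0.0625)
  expect_equal(expected_b_single(ld_pair(0.5, 0.5, rho = 0.5), 1), -0.25)
  expect_equal(expected_b_single(ld_pair(0.5, 0.5, rho = 0.75), 1), -0.5625)
  expect_equal(expected_b_single(ld_pair(0.4, 0.7, D = 0), 2), 0)
})

test_that("the tau-form and rho-form coefficients agree over the grid", {
  for (g in ld_grid()) {
    pr <- ld_pair(g["p_k"], g["p_l"], D = g["D"])
    for (beta in c(0.5, 2)) {
      e_tau <- -4 * pr$tau^2 * pr$p_k * pr$q_k * beta^2
      e_rho <- -2 * pr$rho^2 * (2 * pr$p_l * pr$q_l * beta^2)
      expect_equal(e_tau, e_rho, tolerance = 1e-12)
      expect_equal(expected_b_single(pr, beta), e_tau, tolerance = 1e-12)
    }
  }
})

test_that("one-marker multi-QTL expectation matches its double-sum form", {
  set.seed(51)
  for (rep in 1:10) {
    p_k <- runif(1, 0.2, 0.8)
    L <- sample(2:4, 1)
    pairs <- lapply(seq_len(L), function(i) {
      p_l <- runif(1, 0.2, 0.8)
      lo <- max(-p_k * p_l, -(1 - p_k) * (1 - p_l))
      hi <- min(p_k * (1 - p_l), (1 - p_k) * p_l)
      ld_pair(p_k, p_l, D = runif(1, 0.8 * lo, 0.8 * hi))
    })
    betas <- rnorm(L)
    e8 <- expected_b_one_marker_multi_qtl(pairs, betas)
    # double sum over rho_kl1 rho_kl2 sigma_l1 sigma_l2
    rho <- vapply(pairs, function(x) x$rho, 1)
    sig <- vapply(pairs, function(x) sqrt(2 * x$p_l * x$q_l), 1) * betas
    e9 <- -2 * sum(outer(rho * sig, rho * sig))
    expect_equal(e8, e9, tolerance = 1e-10)
  }
  # L = 1 reduces to the single-QTL form
  pr <- ld_pair(0.5, 0.3, rho = 0.4)
  expect_equal(expected_b_one_marker_multi_qtl(list(pr), 1.3),
               expected_b_single(pr, 1.3), tolerance = 1e-12)
  # equal and opposite tagged effects cancel exactly
  p1 <- ld_pair(0.5, 0.5, rho = 0.5); p2 <- ld_pair(0.5, 0.5, rho = 0.5)
  expect_equal(expected_b_one_marker_multi_qtl(list(p1, p2), c(1, -1)), 0)
})

test_that("one-marker expectation matches a simulation oracle", {
  set.seed(52)
  # marker = locus 1 of an AR(1) chain; QTLs at loci 2..4
  rho <- 0.6; n <- 2000; reps <- 40
  betas <- c(0.8, -0.5, 0.6)
  pairs <- lapply(1:3, function(d) ld_pair(0.5, 0.5, rho = rho^d))
  e_b_raw <- expected_b_one_marker_multi_qtl(pairs, betas)
  b_hat <- numeric(reps)
  for (r in seq_len(reps)) {
    g <- simulate_ar1_genotypes(n, 4, rho = rho)
    gv <- drop(g$calls[, 2:4] %*% betas)
    y <- gv + rnorm(n, 0, 1)
    grm <- compute_grm(standardize_genotypes(g$calls[, 1, drop = FALSE]))
    b_hat[r] <- suppressWarnings(he_fit(y, grm, standardize = FALSE, me = 1))$b
  }
  expect_lt(abs(mean(b_hat) - e_b_raw), 3 * sd(b_hat) / sqrt(reps))
})

test_that("multi-marker expectation decomposes into lambda and delta", {
  m <- 50
  # markers identical to QTLs: lambda = 1 whatever the LD
  for (rho in c(0, 0.5)) {
    model <- qtl_model(rep(0.5, m), rep(0.5, m), rnorm(m),
                       ar1_corr(1:m, rho = rho), ar1_corr(1:m, rho = rho),
                       ar1_corr(1:m, rho = rho))
    ec <- expected_b_multi(model)
    expect_equal(ec$lambda, 1, tolerance = 1e-12)
    expect_equal(ec$e_b, -2 * ec$sigma2A_within * ec$lambda + ec$delta,
                 tolerance = 1e-10)
  }
  # perfect one-to-one tagging by independent markers: lambda = 1
  model2 <- qtl_model(rep(0.5, m), rep(0.5, m), rnorm(m),
                      diag(m), diag(m))
  ec2 <- expected_b_multi(model2)
  expect_equal(ec2$lambda, 1, tolerance = 1e-12)
  expect_equal(ec2$rho2_Q, 1 / m, tolerance = 1e-12)
  expect_equal(ec2$rho2_M, 1 / m, tolerance = 1e-12)
  expect_equal(ec2$delta, 0, tolerance = 1e-10)
})

test_that("multi-marker expectation predicts the fitted coefficient", {
  set.seed(53)
  reps <- 40; n <- 700; m <- 60; rho <- 0.5
  diff <- numeric(reps)
  sds <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_polygenic_study(n = n, m = m, rho = rho, sorted = TRUE)
    fit <- suppressWarnings(he_fit(sim$phenotype$y, sim$grm))
    diff[r] <- fit$h2 - sim$expectation$h2_pred
  }
  expect_lt(abs(mean(diff)), 3 * sd(diff) / sqrt(reps))
})

test_that("breakeven sample sizes reproduce the published grid", {
  expect_identical(breakeven_sample_size(0.01, 0.25), 6400L)
  expect_identical(breakeven_sample_size(0.005, 0.75), 1423L)
  expect_identical(breakeven_sample_size(0.05, 0.5), 320L)
  expect_error(breakeven_sample_size(0, 0.5))
})

test_that("non-centrality parameters cross at the breakeven point", {
  h2 <- 0.01; rho <- 0.5
  n_star <- 4 / (h2 * rho^2)
  expect_equal(he_ncp(n_star, h2, rho, "he"),
               he_ncp(n_star, h2, rho, "linear", exact = FALSE),
               tolerance = 1e-12)
  # both vanish as the signal goes to zero
  expect_lt(he_ncp(1000, 1e-6, 0.1, "he"), 1e-6)
  expect_lt(he_ncp(1000, 1e-6, 0.1, "linear"), 1e-2)
  expect_error(he_ncp(100, 0.9, 1.2), "must be")
  # generic solver is monotone in the signal
  expect_gt(solve_sample_size(0.005, 0.5), solve_sample_size(0.01, 0.5))
})

test_that("the single-marker HE test is calibrated conservatively", {
  set.seed(54)
  g <- simulate_ar1_genotypes(400, 1500, rho = 0)
  y <- rnorm(400)
  sc <- assoc_scan(g, y)
  rate <- mean(sc$p < 0.05)
  mc_se <- sqrt(0.05 * 0.95 / nrow(sc))
  # the analytic SE over-states the null spread, so the test never exceeds
  # its nominal level (it runs conservative)
  expect_lt(rate, 0.05 + 3 * mc_se)
  expect_gt(rate, 0)
})
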