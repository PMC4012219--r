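#' Expected single-marker HE coefficient
#'
#' For one marker in LD with one additive QTL (genotypic values
#' \eqn{-\beta, 0, +\beta}), the expected HE regression coefficient on the
#' squared-difference response is
#' \deqn{E(b) = -4\tau^2 p_k q_k \beta^2 = -2\rho^2 \sigma_l^2,}
#' with \eqn{\sigma_l^2 = 2 p_l q_l \beta^2} the QTL's additive variance.
#' The two forms are algebraically identical; both are computed and checked.
#'
#' @param pair an \code{ld_pair} (marker k, QTL l).
#' @param beta additive QTL effect.
#' @return Expected coefficient (scalar, non-positive).
#' @export
expected_b_single <- function(pair, beta) {
  stopifnot(inherits(pair, "ld_pair"))
  e_tau <- -4 * pair$tau^2 * pair$p_k * pair$q_k * beta^2
  e_rho <- -2 * pair$rho^2 * (2 * pair$p_l * pair$q_l * beta^2)
  stopifnot(abs(e_tau - e_rho) < 1e-10 * max(1, abs(e_tau)))
  e_tau
}

#' Expected HE coefficient: one marker, several QTLs
#'
#' With L QTLs all in LD with the same marker k,
#' \deqn{E(b) = -4 p_k q_k \Big[\sum_l \tau_{kl} \beta_l\Big]^2
#'            = -2 \sum_{l_1}\sum_{l_2} \rho_{kl_1}\rho_{kl_2}
#'              \sigma_{l_1}\sigma_{l_2}.}
#' Opposite-signed contributions can cancel exactly.
#'
#' @param pairs list of \code{ld_pair}s sharing the marker locus k.
#' @param betas additive effects, one per QTL.
#' @return Expected coefficient.
#' @export
expected_b_one_marker_multi_qtl <- function(pairs, betas) {
  if (inherits(pairs, "ld_pair")) pairs <- list(pairs)
  stopifnot(length(pairs) == length(betas))
  p_k <- pairs[[1]]$p_k
  stopifnot(all(vapply(pairs, function(x) abs(x$p_k - p_k) < 1e-12, TRUE)))
  tau <- vapply(pairs, function(x) x$tau, 1)
  -4 * p_k * (1 - p_k) * sum(tau * betas)^2
}

#' AR(1) locus-locus correlation matrix
#'
#' Correlation \eqn{\rho^{|k-l|}} between loci at positions \code{idx_k} and
#' \code{idx_l} along a chain with adjacent-locus correlation \code{rho}.
#'
#' @param idx_k,idx_l integer position vectors.
#' @param rho adjacent-locus correlation.
#' @return \code{length(idx_k)} x \code{length(idx_l)} matrix.
#' @export
ar1_corr <- function(idx_k, idx_l = idx_k, rho) {
  outer(idx_k, idx_l, function(a, b) rho^abs(a - b))
}

#' QTL/marker tagging model for the multi-marker expectation
#'
#' Bundles the quantities entering the multi-marker expected coefficient:
#' allele frequencies, QTL effects, and the marker-QTL and marker-marker
#' correlation matrices.
#'
#' @param p_markers marker reference-allele frequencies (length M).
#' @param p_qtls QTL frequencies (length L).
#' @param betas QTL additive effects (length L).
#' @param rho_mq M x L marker-QTL correlation matrix.
#' @param rho_mm M x M marker-marker correlation matrix (unit diagonal).
#' @param rho_qq L x L QTL-QTL correlation matrix (for the additive-variance
#'   covariance term); identity when \code{NULL}.
#' @return Object of class \code{qtl_model}.
#' @export
qtl_model <- function(p_markers, p_qtls, betas, rho_mq, rho_mm,
                      rho_qq = NULL) {
  m <- length(p_markers); l <- length(p_qtls)
  stopifnot(length(betas) == l,
            nrow(rho_mq) == m, ncol(rho_mq) == l,
            nrow(rho_mm) == m, ncol(rho_mm) == m,
            max(abs(rho_mq)) <= 1 + 1e-12, max(abs(rho_mm)) <= 1 + 1e-12)
  if (is.null(rho_qq)) rho_qq <- diag(l)
  structure(list(p_markers = p_markers, p_qtls = p_qtls, betas = betas,
                 rho_mq = rho_mq, rho_mm = rho_mm, rho_qq = rho_qq),
            class = "qtl_model")
}

#' Additive genetic variance of a QTL model
#'
#' \deqn{\sigma^2_A = \sum_l 2 p_l q_l \beta_l^2 +
#'   \sum_{l_1 \ne l_2} 2 \rho_{l_1 l_2}
#'   \sqrt{p_{l_1} q_{l_1} p_{l_2} q_{l_2}}\, \beta_{l_1} \beta_{l_2}.}
#' The second (between-locus covariance) term vanishes in expectation when
#' effects are randomly allocated along the genome.
#'
#' @param model a \code{qtl_model}.
#' @return List with \code{within} (first sum), \code{between} (covariance
#'   sum), \code{total}.
#' @export
additive_variance <- function(model) {
  stopifnot(inherits(model, "qtl_model"))
  p <- model$p_qtls; q <- 1 - p; b <- model$betas
  within <- sum(2 * p * q * b^2)
  sig <- sqrt(p * q) * b
  cov_mat <- 2 * model$rho_qq * tcrossprod(sig)
  between <- sum(cov_mat) - sum(diag(cov_mat))
  list(within = within, between = between, total = within + between)
}

#' Expected multi-marker HE coefficient and its decomposition
#'
#' The exact expectation of the HE coefficient when the GRM is built from M
#' markers, each possibly in LD with L QTLs:
#' \deqn{E(b) = \frac{\sum_k -4 p_k q_k [\sum_l \tau_{kl}\beta_l]^2 / M}
#'                   {\sum_k \sum_l \rho^2_{kl} / M^2},}
#' where the denominator runs over marker pairs (the mean squared
#' marker-marker correlation, diagonal included).  The decomposition
#' \eqn{E(b) = -2\sigma^2_{A}\Lambda + \Delta} reports
#' \eqn{\Lambda = \bar\rho^2_Q/\bar\rho^2_M} (mean squared marker-QTL over
#' mean squared marker-marker correlation) with \eqn{\Delta} defined as the
#' exact remainder, which vanishes when the marker-QTL cross-products of
#' distinct loci cancel (randomly allocated effects).
#'
#' @param model a \code{qtl_model}.
#' @param var_y phenotypic variance used to express the coefficient on a
#'   standardized-phenotype scale; \code{NULL} leaves the raw scale (the
#'   prediction of \eqn{\hat h^2} is then \code{-e_b/2/var_y}).
#' @return Object of class \code{expected_coefficient}: \code{e_b} (raw
#'   scale), \code{e_b_std} (standardized scale, if \code{var_y} given),
#'   \code{h2_pred} (\eqn{-e_b_{std}/2}), \code{sigma2A_within},
#'   \code{sigma2A_total}, \code{lambda}, \code{delta}, \code{rho2_M},
#'   \code{rho2_Q}.
#' @export
expected_b_multi <- function(model, var_y = NULL) {
  stopifnot(inherits(model, "qtl_model"))
  pm <- model$p_markers; qm <- 1 - pm
  pq <- model$p_qtls; qq <- 1 - pq
  m <- length(pm); l <- length(pq)
  # tau_kl = -rho_kl * sqrt(p_l q_l) / sqrt(p_k q_k)
  tau <- -model$rho_mq * outer(1 / sqrt(pm * qm), sqrt(pq * qq))
  num <- sum(-4 * pm * qm * drop(tau %*% model$betas)^2) / m
  rho2_M <- sum(model$rho_mm^2) / m^2
  rho2_Q <- sum(model$rho_mq^2) / (m * l)
  e_b <- num / rho2_M
  av <- additive_variance(model)
  lambda <- rho2_Q / rho2_M
  delta <- e_b - (-2 * av$within * lambda)
  e_b_std <- if (!is.null(var_y)) e_b / var_y else NA_real_
  structure(list(e_b = e_b, e_b_std = e_b_std,
                 h2_pred = if (!is.null(var_y)) -e_b_std / 2 else NA_real_,
                 sigma2A_within = av$within, sigma2A_total = av$total,
                 lambda = lambda, delta = delta,
                 rho2_M = rho2_M, rho2_Q = rho2_Q),
            class = "expected_coefficient")
}

#' @export
print.expected_coefficient <- function(x, ...) {
  cat(sprintf("E(b) = %.6g (lambda = %.4g, delta = %.4g, rho2_M = %.4g, rho2_Q = %.4g)\n",
              x$e_b, x$lambda, x$delta, x$rho2_M, x$rho2_Q))
  if (!is.na(x$e_b_std))
    cat(sprintf("standardized scale: E(b) = %.6g, predicted h2 = %.4f\n",
                x$e_b_std, x$h2_pred))
  invisible(x)
}

## ---- power / sample size ----------------------------------------------

#' Breakeven sample size: HE versus single-marker linear regression
#'
#' The single-marker HE test overtakes the conventional linear-regression
#' association test once \eqn{N} reaches \eqn{4/(h^2 \rho^2)}; this returns
#' \eqn{\lceil 4/(h^2\rho^2) \rceil}.
#'
#' @param h2 per-QTL heritability, in (0, 1).
#' @param rho marker-QTL correlation, in (0, 1\].
#' @return Minimum sample size (integer).
#' @export
breakeven_sample_size <- function(h2, rho) {
  stopifnot(h2 > 0, h2 < 1, rho > 0, rho <= 1)
  as.integer(ceiling(4 / (h2 * rho^2)))
}

#' Non-centrality parameter of the single-marker tests
#'
#' Linear regression of the phenotype on one standardized marker has
#' one-degree chi-square NCP \eqn{N h^2 \rho^2 / (1 - h^2\rho^2)}
#' (\eqn{\approx N h^2 \rho^2}).  The single-marker HE test statistic
#' \eqn{t = h^2\rho^2 / (2/N)} gives NCP \eqn{(N h^2 \rho^2 / 2)^2}; the
#' ratio of the two is \eqn{N h^2 \rho^2 / 4}, which crosses 1 at the
#' breakeven sample size.
#'
#' @param n sample size.
#' @param h2 per-QTL heritability.
#' @param rho marker-QTL correlation.
#' @param test \code{"he"} or \code{"linear"}.
#' @param exact for \code{"linear"}, use the exact
#'   \eqn{Nh^2\rho^2/(1-h^2\rho^2)} rather than the approximation.
#' @return Non-centrality parameter of the chi-square(1) statistic.
#' @export
he_ncp <- function(n, h2, rho, test = c("he", "linear"), exact = TRUE) {
  test <- match.arg(test)
  v <- h2 * rho^2
  if (v >= 1) stop("h2 * rho^2 must be below 1")
  if (v <= 0) stop("h2 * rho^2 must be positive")
  if (test == "linear") {
    if (exact) n * v / (1 - v) else n * v
  } else {
    (n * v / 2)^2
  }
}

#' Sample size for a target power of the single-marker HE test
#'
#' Generic chi-square(1) power solver on the HE non-centrality parameter:
#' finds the smallest N whose NCP reaches the target power at significance
#' level alpha.
#'
#' @param h2 per-QTL heritability.
#' @param rho marker-QTL correlation.
#' @param alpha significance level (default genome-wide 5e-8).
#' @param power target power (default 0.8).
#' @param test \code{"he"} or \code{"linear"}.
#' @return Required sample size (integer).
#' @export
solve_sample_size <- function(h2, rho, alpha = 5e-8, power = 0.8,
                              test = c("he", "linear")) {
  test <- match.arg(test)
  crit <- stats::qchisq(alpha, df = 1, lower.tail = FALSE)
  pow <- function(n) stats::pchisq(crit, df = 1,
                                   ncp = he_ncp(n, h2, rho, test),
                                   lower.tail = FALSE)
  lo <- 4; hi <- 8
  while (pow(hi) < power) {
    hi <- hi * 2
    if (hi > 1e9) stop("required sample size exceeds 1e9")
  }
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (pow(mid) >= power) hi <- mid else lo <- mid
  }
  as.integer(hi)
}
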