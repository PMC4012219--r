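#' Pairwise phenotype response
#'
#' The HE regression response over all N(N-1)/2 unordered pairs, in
#' lexicographic (column-major upper-triangle) order matching
#' \code{\link{grm_offdiag}}.  The squared difference
#' \eqn{Y_{ij} = (y_i - y_j)^2} is the classical choice; the cross-product
#' \eqn{Y_{ij} = y_i y_j} is the similarity-score variant.
#'
#' @param y numeric phenotype vector (length >= 3).
#' @param method \code{"squared_difference"} or \code{"cross_product"}.
#' @return Numeric vector of length N(N-1)/2.
#' @export
pair_response <- function(y, method = c("squared_difference", "cross_product")) {
  method <- match.arg(method)
  if (length(y) < 3) stop("need at least 3 individuals to form a pair regression")
  ut <- upper.tri(diag(length(y)))
  if (method == "squared_difference") outer(y, y, function(a, b) (a - b)^2)[ut]
  else tcrossprod(y)[ut]
}

#' Standardize a phenotype to zero mean and unit variance
#' @param y numeric vector.
#' @return z-scored copy of \code{y}.
#' @export
standardize_phenotype <- function(y) {
  s <- stats::sd(y)
  if (!is.finite(s) || s == 0) stop("phenotype has zero variance")
  (y - mean(y)) / s
}

#' Residualize a phenotype on covariates
#'
#' Replaces the phenotype by its least-squares residuals on the covariates
#' plus an intercept (e.g. principal components against stratification).
#'
#' @param y numeric phenotype vector.
#' @param covariates numeric matrix, one row per individual; \code{NULL}
#'   centers only.
#' @return Residual vector.
#' @export
residualize_covariates <- function(y, covariates = NULL) {
  x <- cbind(intercept = rep(1, length(y)), covariates)
  if (qr(x)$rank < ncol(x)) stop("covariate matrix is rank deficient")
  stats::lm.fit(x, y)$residuals
}

# Sufficient statistics for the pair regression, computed without
# materializing the pair design: O(N^2) time, O(N) extra memory.
he_suffstats <- function(y, omega, method) {
  n <- length(y)
  a <- omega; diag(a) <- 0
  s_om <- sum(a) / 2
  s_om2 <- sum(a^2) / 2
  r <- rowSums(a)
  s1 <- sum(y); s2 <- sum(y^2); s3 <- sum(y^3); s4 <- sum(y^4)
  if (method == "squared_difference") {
    s_y <- n * s2 - s1^2
    s_y2 <- n * s4 - 4 * s3 * s1 + 3 * s2^2
    s_yom <- sum(y^2 * r) - drop(crossprod(y, a %*% y))
  } else {
    s_y <- (s1^2 - s2) / 2
    s_y2 <- (s2^2 - s4) / 2
    s_yom <- drop(crossprod(y, a %*% y)) / 2
  }
  list(n_pairs = n * (n - 1) / 2, s_om = s_om, s_om2 = s_om2,
       s_y = s_y, s_y2 = s_y2, s_yom = s_yom)
}

#' Fit the IBS Haseman-Elston regression
#'
#' Ordinary least squares of the pairwise response \eqn{Y_{ij}} on the
#' relatedness \eqn{\Omega_{ij}} over all pairs,
#' \eqn{Y_{ij} = \mu + b\,\Omega_{ij} + e_{ij}}.  For the squared-difference
#' response on a standardized phenotype, \eqn{\hat h^2 = -b/2}; on the raw
#' scale, \eqn{\hat h^2 = -b/\mu} (the intercept estimates twice the
#' phenotypic variance).  For the cross-product response the coefficient
#' carries the tagged additive variance directly (half the magnitude of the
#' squared-difference coefficient), so \eqn{\hat h^2 = b} on the
#' standardized scale.
#'
#' The default analytic standard error treats the pair observations'
#' dependence through the effective marker count:
#' \eqn{se(b)^2 = [(8\hat\sigma_y^4 - 4\hat\sigma_A^4)/(n_{pairs}-d)]\,M_e}
#' with \eqn{se(\hat h^2) = se(b)/2}; the naive OLS standard error is also
#' reported (it is anti-conservative, pairs being dependent).
#'
#' @param y phenotype vector aligned with the GRM sample order.
#' @param grm a \code{grm}.
#' @param method pair response type; see \code{\link{pair_response}}.
#' @param standardize z-score the phenotype before fitting (default).  The
#'   unstandardized path reports \eqn{\hat h^2 = -b/\mu}.
#' @param me effective marker count for the analytic SE; estimated from the
#'   GRM when \code{NULL}.
#' @param d number of regression parameters charged in the error sum of
#'   squares denominator (default 1).
#' @return Object of class \code{he_fit}: \code{mu}, \code{b},
#'   \code{se_b_analytic}, \code{se_b_ols}, \code{h2}, \code{se_h2},
#'   \code{n_pairs}, \code{me}, \code{method}, \code{standardized},
#'   \code{out_of_range} flag.
#' @export
he_fit <- function(y, grm, method = c("squared_difference", "cross_product"),
                   standardize = TRUE, me = NULL, d = 1) {
  method <- match.arg(method)
  stopifnot(inherits(grm, "grm"))
  if (length(y) != grm$n) stop("phenotype length does not match GRM dimension")
  if (length(y) < 3) stop("need at least 3 individuals")
  if (anyNA(y)) stop("phenotype contains NA; subset the GRM and phenotype first")
  if (standardize) y <- standardize_phenotype(y)
  st <- he_suffstats(y, grm$omega, method)
  np <- st$n_pairs
  sxx <- st$s_om2 - st$s_om^2 / np
  if (sxx <= 0) stop("relatedness has zero variance across pairs")
  b <- (st$s_yom - st$s_y * st$s_om / np) / sxx
  mu <- (st$s_y - b * st$s_om) / np
  # naive OLS residual variance over pairs
  sse_ols <- st$s_y2 + np * mu^2 + b^2 * st$s_om2 -
    2 * mu * st$s_y - 2 * b * st$s_yom + 2 * mu * b * st$s_om
  sse_ols <- max(sse_ols, 0)
  se_b_ols <- sqrt(sse_ols / (np - 2) / sxx)
  if (is.null(me)) me <- effective_marker_count(grm)$me
  sig2_y <- stats::var(y)
  if (method == "squared_difference") {
    h2 <- if (standardize) -b / 2 else -b / mu
  } else {
    h2 <- if (standardize) b else b / sig2_y
  }
  sig2_a <- h2 * sig2_y
  ase <- analytic_se(grm$n, me, sigma2_A = sig2_a, sigma2_y = sig2_y, d = d)
  out_of_range <- is.finite(h2) && (h2 < 0 || h2 > 1)
  if (out_of_range)
    warning(sprintf("heritability estimate %.3f outside [0, 1]; reported unclipped", h2))
  structure(list(mu = mu, b = b,
                 se_b_analytic = ase$se_b, se_b_ols = se_b_ols,
                 h2 = h2, se_h2 = ase$se_h2,
                 n_pairs = np, me = me, method = method,
                 standardized = standardize, out_of_range = out_of_range),
            class = "he_fit")
}

#' @export
print.he_fit <- function(x, ...) {
  cat(sprintf("HE regression (%s%s)\n", x$method,
              if (x$standardized) ", standardized phenotype" else ""))
  cat(sprintf("  mu = %.6g  b = %.6g (analytic SE %.3g, OLS SE %.3g)\n",
              x$mu, x$b, x$se_b_analytic, x$se_b_ols))
  cat(sprintf("  h2 = %.4f (SE %.4f)  pairs = %d  Me = %.1f%s\n",
              x$h2, x$se_h2, x$n_pairs, x$me,
              if (x$out_of_range) "  [outside 0..1]" else ""))
  invisible(x)
}

#' Analytic standard errors of the HE coefficient and heritability
#'
#' The error sum of squares of the pair regression is
#' \eqn{SSE = 8\sigma_y^4 - 4\sigma_A^4}, giving
#' \deqn{se(b)^2 = \frac{SSE / (n_{pairs} - d)}{var(\Omega)}, \qquad
#'       var(\Omega) = 1/M_e.}
#' For a standardized phenotype and \eqn{8 M_e \gg 4\sigma_A^4}, this
#' simplifies to \eqn{se(b) \approx \sqrt{16 M_e / (N(N-1))}} and
#' \eqn{se(\hat h^2) = se(b)/2}.
#'
#' @param n sample size.
#' @param me effective marker count (\eqn{1/var(\Omega)}).
#' @param sigma2_A additive genetic variance (default 0 gives the simplified
#'   form for a standardized phenotype).
#' @param sigma2_y phenotypic variance (default 1).
#' @param d number of regression parameters (default 1).
#' @param simplified force the \eqn{\sqrt{16 M_e/(N(N-1))}} form.
#' @return List with \code{se_b} and \code{se_h2}.
#' @export
analytic_se <- function(n, me, sigma2_A = 0, sigma2_y = 1, d = 1,
                        simplified = FALSE) {
  stopifnot(n >= 3, me >= 1, d >= 1)
  np <- n * (n - 1) / 2
  if (np <= d) stop("too few pairs for the requested parameter count")
  if (simplified) {
    se_b <- sqrt(16 * me / (n * (n - 1)))
  } else {
    sse <- 8 * sigma2_y^2 - 4 * sigma2_A^2
    se_b <- sqrt(max(sse, 0) / (np - d) * me)
  }
  list(se_b = se_b, se_h2 = se_b / 2)
}

#' Multi-component HE regression
#'
#' Multiple OLS of the pairwise response on several relatedness components
#' (e.g. per-chromosome GRMs): \eqn{Y_{ij} = \mu + \sum_c b_c \Omega^{(c)}_{ij}}.
#' On a standardized phenotype each \eqn{\hat h^2_c = -b_c/2} estimates the
#' variance tagged by component c.
#'
#' @param y phenotype vector.
#' @param grms list of \code{grm} objects, all aligned to the same samples.
#' @param standardize z-score the phenotype first (default).
#' @return List with \code{mu}, \code{b} (per component), \code{h2} (per
#'   component), \code{h2_total}, \code{n_pairs}.
#' @export
multi_component_he <- function(y, grms, standardize = TRUE) {
  if (inherits(grms, "grm")) grms <- list(grms)
  stopifnot(length(grms) >= 1, all(vapply(grms, inherits, TRUE, "grm")))
  n <- length(y)
  if (any(vapply(grms, function(g) g$n, 1L) != n))
    stop("all GRMs must match the phenotype length")
  if (standardize) y <- standardize_phenotype(y)
  ut <- upper.tri(diag(n))
  x <- vapply(grms, function(g) g$omega[ut], numeric(sum(ut)))
  if (length(grms) > 1) {
    cx <- stats::cor(x)
    if (any(abs(cx[upper.tri(cx)]) > 0.999))
      stop("relatedness components are collinear (|cor| > 0.999)")
  }
  yy <- pair_response(y, "squared_difference")
  fit <- stats::lm.fit(cbind(1, x), yy)
  b <- fit$coefficients[-1]
  names(b) <- paste0("component", seq_along(b))
  h2 <- -b / 2
  list(mu = fit$coefficients[1], b = b, h2 = h2, h2_total = sum(h2),
       n_pairs = length(yy))
}
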