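#' Restricted log-likelihood of the one-component animal model
#'
#' Model \eqn{y = X\beta + g + e} with \eqn{cov(g) = \sigma^2_g \Omega},
#' \eqn{cov(e) = \sigma^2_e I}.  Writing the GRM eigendecomposition
#' \eqn{\Omega = U D U'} and the heritability \eqn{h^2 =
#' \sigma^2_g/(\sigma^2_g + \sigma^2_e)}, the covariance in the rotated
#' basis is \eqn{\sigma^2_p\,\mathrm{diag}(w_i)} with
#' \eqn{w_i = h^2 d_i + 1 - h^2}.  The total variance \eqn{\sigma^2_p} is
#' profiled out analytically, leaving a one-dimensional restricted
#' likelihood in \eqn{h^2}:
#' \deqn{-2\,\ell_R(h^2) = \sum_i \log w_i + (n-p)\log\hat\sigma^2_p +
#'   \log |X' W^{-1} X| + (n-p),}
#' up to an additive constant, with \eqn{\hat\sigma^2_p = r' W^{-1} r/(n-p)}
#' the GLS residual quadratic form.
#'
#' @param h2 heritability at which to evaluate.
#' @param d GRM eigenvalues (non-negative; clipped upstream).
#' @param zy rotated response \eqn{U'y}.
#' @param zx rotated fixed-effect design \eqn{U'X} (matrix, same rows as
#'   \code{zy}).
#' @param n_extra_zero count of additional eigen-coordinates with eigenvalue
#'   zero and exactly zero rotated response/design, supplied implicitly (the
#'   economy SVD path of a rank-deficient GRM); they contribute
#'   \eqn{\log(1-h^2)} terms and degrees of freedom only.
#' @return Restricted log-likelihood (up to a constant); \code{-Inf} where
#'   any \eqn{w_i \le 0} (singular covariance).
#' @export
reml_loglik <- function(h2, d, zy, zx, n_extra_zero = 0) {
  w <- h2 * d + (1 - h2)
  if (any(w <= 0) || (n_extra_zero > 0 && 1 - h2 <= 0)) return(-Inf)
  n <- length(zy) + n_extra_zero
  p <- ncol(zx)
  wi <- 1 / w
  xtwx <- crossprod(zx, zx * wi)
  xtwy <- crossprod(zx, zy * wi)
  ch <- tryCatch(chol(xtwx), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), xtwy))
  rss <- sum(zy^2 * wi) - sum(xtwy * beta)
  if (rss <= 0) return(-Inf)
  s2 <- rss / (n - p)
  -0.5 * (sum(log(w)) + n_extra_zero * log(1 - h2) + (n - p) * log(s2) +
            2 * sum(log(diag(ch))) + (n - p))
}

# Rotation of (y, X) onto the GRM eigenbasis.  When standardized scores are
# attached to the GRM and M < N, an economy SVD of the N x M score matrix
# replaces the full N x N eigendecomposition: the GRM has at most M non-zero
# eigenvalues, and in the null space the likelihood only needs the parts of
# y and X that live there, which a reduced QR basis captures exactly.
reml_rotation <- function(y, grm, X) {
  if (!is.null(grm$scores) && ncol(grm$scores) < grm$n) {
    u1 <- svd(grm$scores, nu = min(dim(grm$scores)), nv = 0)
    d1 <- u1$d^2 / grm$m
    d1[d1 < 1e-10 * max(d1)] <- 0
    u1 <- u1$u
    z1y <- drop(crossprod(u1, y))
    z1x <- crossprod(u1, X)
    res_x <- X - u1 %*% z1x
    res_y <- y - u1 %*% z1y
    qr_ <- qr(cbind(res_x, res_y))
    rank <- sum(abs(diag(qr_$qr)) > 1e-9 * max(abs(diag(qr_$qr)), 1))
    q0 <- qr.Q(qr_)[, seq_len(rank), drop = FALSE]
    z0y <- drop(crossprod(q0, y))
    z0x <- crossprod(q0, X)
    list(d = c(d1, rep(0, rank)),
         zy = c(z1y, z0y),
         zx = rbind(z1x, z0x),
         n_extra_zero = grm$n - length(d1) - rank)
  } else {
    ei <- eigen(grm$omega, symmetric = TRUE)
    d <- ei$values
    # sample-frequency centering leaves one (near-)zero eigenvalue; clip
    # numerical dust to exactly zero so the h2 -> 1 boundary is detected
    d[d < 1e-10 * max(d)] <- 0
    list(d = d,
         zy = drop(crossprod(ei$vectors, y)),
         zx = crossprod(ei$vectors, X),
         n_extra_zero = 0L)
  }
}

#' Fit the single-component GREML model
#'
#' Restricted-maximum-likelihood fit of \eqn{y = \mu + g + e} with
#' \eqn{cov(g) = \sigma^2_g\Omega}: one eigendecomposition (or economy SVD
#' of the standardized scores when attached to the GRM), then a
#' one-dimensional profile optimization of the restricted likelihood over
#' the heritability.
#'
#' @param y phenotype vector aligned with the GRM.
#' @param grm a \code{grm}.
#' @param constrained restrict \eqn{h^2} to \[0, 1\] (default); otherwise
#'   the search covers the whole interval on which the profiled covariance
#'   stays positive definite (note a rank-deficient GRM caps it below 1
#'   from above regardless, since some eigenvalues are exactly zero).
#' @param covariates optional fixed-effect matrix (intercept always added).
#' @param tol convergence tolerance on \eqn{h^2} (default 1e-8).
#' @return Object of class \code{reml_fit}: \code{h2}, \code{sigma2_g},
#'   \code{sigma2_e}, \code{loglik}, \code{se_h2} (profile-curvature based),
#'   \code{constrained}, \code{converged}.
#' @export
reml_fit <- function(y, grm, constrained = TRUE, covariates = NULL,
                     tol = 1e-8) {
  stopifnot(inherits(grm, "grm"))
  n <- length(y)
  if (n != grm$n) stop("phenotype length does not match GRM dimension")
  if (n < 10) stop("REML fit requires at least 10 individuals")
  X <- cbind(intercept = rep(1, n), covariates)
  rot <- reml_rotation(y, grm, X)
  f <- function(h2) reml_loglik(h2, rot$d, rot$zy, rot$zx, rot$n_extra_zero)
  dmax <- max(rot$d)
  dmin <- if (rot$n_extra_zero > 0) 0 else min(rot$d)
  eps_b <- 1e-9
  lower <- if (constrained) 0 else
    if (dmax > 1) -1 / (dmax - 1) + eps_b else -5
  upper <- if (constrained) 1 else
    if (dmin > 1e-10) 5 else 1 - eps_b
  opt <- stats::optimize(f, c(lower, upper), maximum = TRUE, tol = tol)
  h2 <- opt$maximum; ll <- opt$objective
  for (cand in c(lower, upper)) {   # optimize() can miss boundary maxima
    lc <- f(cand)
    if (is.finite(lc) && lc > ll) { h2 <- cand; ll <- lc }
  }
  converged <- is.finite(ll)
  if (!converged)
    warning("REML profile likelihood is degenerate; fit flagged unconverged")
  eps <- 1e-4
  h_lo <- h2 - eps; h_hi <- h2 + eps
  f1 <- f(h_lo); f2 <- f(h_hi); f0 <- ll
  se_h2 <- NA_real_
  if (all(is.finite(c(f0, f1, f2)))) {
    curv <- (f1 - 2 * f0 + f2) / eps^2
    if (is.finite(curv) && curv < 0) se_h2 <- sqrt(-1 / curv)
  }
  vy <- stats::var(y)
  structure(list(h2 = h2, sigma2_g = h2 * vy, sigma2_e = (1 - h2) * vy,
                 loglik = ll, se_h2 = se_h2, constrained = constrained,
                 converged = converged),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("GREML fit (%s): h2 = %.4f (SE %.4g), logLik = %.3f%s\n",
              if (x$constrained) "constrained" else "non-constrained",
              x$h2, x$se_h2, x$loglik,
              if (!x$converged) "  [not converged]" else ""))
  invisible(x)
}
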