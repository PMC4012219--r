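#' Single-marker HE association scan
#'
#' Runs the single-marker HE regression at every marker: the per-marker
#' relatedness \eqn{\Omega_{ijk} = s_{ik}s_{jk}} has unit variance, so each
#' coefficient estimates \eqn{-2\rho^2_{kl}\sigma^2_l} and
#' \eqn{\hat h^2_k = -b_k/2} is the variance tagged by the marker.  The
#' analytic standard error uses \eqn{M_e = 1}; squaring the t-statistic
#' gives a one-degree chi-square test.
#'
#' @param g a \code{genotype_matrix} (or 0/1/2 matrix).
#' @param y phenotype vector; standardized internally.
#' @param maf minor-allele-frequency floor; markers below it are skipped.
#' @param alpha genome-wide significance threshold for the \code{signif}
#'   flag (default 5e-8).
#' @return data.frame with one row per retained marker: \code{id},
#'   \code{freq}, \code{b}, \code{h2}, \code{se_b}, \code{t}, \code{chisq},
#'   \code{p}, \code{signif}.
#' @export
assoc_scan <- function(g, y, maf = 0.01, alpha = 5e-8) {
  calls <- if (inherits(g, "genotype_matrix")) g$calls else as.matrix(g)
  ids <- if (inherits(g, "genotype_matrix")) g$loci$id else
    paste0("snp", seq_len(ncol(calls)))
  n <- nrow(calls)
  if (length(y) != n) stop("phenotype length does not match genotypes")
  y <- standardize_phenotype(y)
  st <- standardize_genotypes(calls, maf = maf)
  s <- st$scores
  np <- n * (n - 1) / 2
  # per-marker pair-regression sufficient statistics in O(NM)
  cs1 <- colSums(s); cs2 <- colSums(s^2); cs4 <- colSums(s^4)
  s_om <- (cs1^2 - cs2) / 2
  s_om2 <- (cs2^2 - cs4) / 2
  ya <- colSums(y * s); y2a2 <- colSums(y^2 * s^2)
  w <- colSums(y^2 * s) * cs1 - colSums(y^2 * s^2)   # sum (yi^2+yj^2) ai aj over i<j
  cross <- (ya^2 - y2a2) / 2
  s_yom <- w - 2 * cross
  s_y <- n * sum(y^2) - sum(y)^2
  sxx <- s_om2 - s_om^2 / np
  b <- (s_yom - s_y * s_om / np) / sxx
  se_b <- sqrt(16 / (n * (n - 1)))
  tstat <- b / se_b
  chisq <- tstat^2
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  data.frame(id = ids[st$kept], freq = st$freqs, b = b, h2 = -b / 2,
             se_b = se_b, t = tstat, chisq = chisq, p = p,
             signif = p < alpha, stringsAsFactors = FALSE)
}
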