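#' Two-locus linkage-disequilibrium parameterization
#'
#' Builds the full haplotype parameterization of a pair of biallelic loci
#' from allele frequencies and the haplotype covariance \eqn{D}.  Writing
#' \eqn{A_k/a_k} for the reference/alternative alleles at locus \eqn{k},
#' \deqn{D = f_{A_kA_l} - p_k p_l = f_{a_ka_l} - q_k q_l,}
#' the derived quantities are the coupling-haplotype conditional
#' probabilities \eqn{r = P(a_l | a_k) = q_l + D/q_k} and
#' \eqn{R = P(A_l | A_k) = p_l + D/p_k}, the correlation
#' \eqn{\rho = D / \sqrt{p_k q_k p_l q_l}}, and
#' \eqn{\tau = 1 - r - R = -D/(p_k q_k)}.
#'
#' @param p_k,p_l reference-allele frequencies, both in (0, 1).
#' @param D haplotype covariance; must lie in the admissible interval
#'   \eqn{[\max(-p_k p_l, -q_k q_l), \min(p_k q_l, q_k p_l)]}.
#' @param rho alternatively, the locus-locus correlation; converted to
#'   \code{D} via \eqn{D = \rho \sqrt{p_k q_k p_l q_l}}.  Supply exactly one
#'   of \code{D} and \code{rho}.
#' @return Object of class \code{ld_pair} with fields \code{p_k}, \code{q_k},
#'   \code{p_l}, \code{q_l}, \code{D}, \code{r}, \code{R}, \code{rho},
#'   \code{tau}, and the four haplotype frequencies \code{hap}.
#' @export
ld_pair <- function(p_k, p_l, D = NULL, rho = NULL) {
  if (!is.null(D) && !is.null(rho)) stop("supply only one of D and rho")
  p_k <- unname(p_k); p_l <- unname(p_l)
  if (!is.null(D)) D <- unname(D)
  if (!is.null(rho)) rho <- unname(rho)
  stopifnot(p_k > 0, p_k < 1, p_l > 0, p_l < 1)
  q_k <- 1 - p_k; q_l <- 1 - p_l
  if (is.null(D)) {
    if (is.null(rho)) rho <- 0
    D <- rho * sqrt(p_k * q_k * p_l * q_l)
  }
  lo <- max(-p_k * p_l, -q_k * q_l); hi <- min(p_k * q_l, q_k * p_l)
  if (D < lo - 1e-12 || D > hi + 1e-12)
    stop(sprintf("D = %g outside the admissible interval [%g, %g]", D, lo, hi))
  D <- min(max(D, lo), hi)
  hap <- c(AA = p_k * p_l + D, Aa = p_k * q_l - D,
           aA = q_k * p_l - D, aa = q_k * q_l + D)
  structure(list(p_k = p_k, q_k = q_k, p_l = p_l, q_l = q_l, D = D,
                 r = q_l + D / q_k, R = p_l + D / p_k,
                 rho = D / sqrt(p_k * q_k * p_l * q_l),
                 tau = -D / (p_k * q_k), hap = hap),
            class = "ld_pair")
}

#' Build an \code{ld_pair} from haplotype frequencies
#'
#' @param f named or positional vector of the four haplotype frequencies in
#'   the order \eqn{A_kA_l, A_ka_l, a_kA_l, a_ka_l}; must sum to 1.
#' @return An \code{ld_pair}.
#' @export
ld_pair_from_haplotypes <- function(f) {
  if (length(f) != 4 || abs(sum(f) - 1) > 1e-8 || any(f < 0))
    stop("haplotype frequencies must be 4 non-negative values summing to 1")
  p_k <- f[1] + f[2]; p_l <- f[1] + f[3]
  ld_pair(p_k, p_l, D = f[1] - p_k * p_l)
}

#' @export
print.ld_pair <- function(x, ...) {
  cat(sprintf("ld_pair: p_k=%.4g p_l=%.4g D=%.4g rho=%.4g r=%.4g R=%.4g tau=%.4g\n",
              x$p_k, x$p_l, x$D, x$rho, x$r, x$R, x$tau))
  invisible(x)
}

#' Joint two-locus genotype distribution
#'
#' The 3 x 3 probability table of genotype pairs under random mating, built
#' from the coupling conditional probabilities of an \code{\link{ld_pair}}.
#' Rows index the second (l-th) locus genotype (aa, Aa, AA), columns the
#' first (k-th) locus genotype.  Row and column sums reproduce the
#' Hardy-Weinberg marginals \eqn{(q^2, 2pq, p^2)}.
#'
#' @param pair an \code{ld_pair}.
#' @return 3 x 3 numeric matrix summing to 1, with dimnames
#'   \code{c("aa","Aa","AA")} for both loci.
#' @export
joint_genotype_probs <- function(pair) {
  stopifnot(inherits(pair, "ld_pair"))
  r <- pair$r; R <- pair$R; p <- pair$p_k; q <- pair$q_k
  tab <- rbind(
    c(q^2 * r^2,           2 * p * q * r * (1 - R),                 p^2 * (1 - R)^2),
    c(2 * q^2 * r * (1 - r), 2 * p * q * (r * R + (1 - r) * (1 - R)), 2 * p^2 * R * (1 - R)),
    c(q^2 * (1 - r)^2,     2 * p * q * R * (1 - r),                 p^2 * R^2))
  dimnames(tab) <- list(l = c("aa", "Aa", "AA"), k = c("aa", "Aa", "AA"))
  tab
}

#' Expected phenotype given the marker genotype
#'
#' For a biallelic QTL with additive genotypic values \eqn{(-\beta, 0, +\beta)}
#' in LD with an observed marker, the expected phenotype conditional on the
#' marker genotype is \eqn{(1-2r)\beta}, \eqn{(R-r)\beta}, \eqn{(2R-1)\beta}
#' for marker genotypes \eqn{a_ka_k}, \eqn{A_ka_k}, \eqn{A_kA_k}.  With
#' several QTLs tagged by the same marker the contributions add.
#'
#' @param pair an \code{ld_pair} (marker = locus k, QTL = locus l), or a list
#'   of them sharing the marker.
#' @param beta additive QTL effect(s), one per pair.
#' @return Named numeric vector of length 3 (\code{aa}, \code{Aa}, \code{AA}).
#' @export
conditional_phenotype_expectation <- function(pair, beta) {
  if (inherits(pair, "ld_pair")) pair <- list(pair)
  stopifnot(length(pair) == length(beta))
  out <- c(aa = 0, Aa = 0, AA = 0)
  for (i in seq_along(pair)) {
    p <- pair[[i]]
    out <- out + beta[i] * c(1 - 2 * p$r, p$R - p$r, 2 * p$R - 1)
  }
  out
}
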