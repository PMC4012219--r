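#' Compute the IBS genomic relationship matrix
#'
#' The relatedness of individuals \eqn{i} and \eqn{j} is the dot product of
#' their standardized genotype scores divided by the marker count,
#' \deqn{\Omega_{ij} = s_i \cdot s_j / M.}
#' With sample-estimated allele frequencies, unrelated pairs have
#' \eqn{\Omega_{ij} \approx 0}; duplicates (or monozygotic twins) have
#' expectation 1, first-degree relatives 0.5, second-degree 0.25.
#'
#' @param s a \code{standardized_genotypes} object (see
#'   \code{\link{standardize_genotypes}}) or a plain standardized matrix.
#' @param keep_scores keep the standardized score matrix inside the result;
#'   downstream REML fits then use an economy SVD instead of a full N x N
#'   eigendecomposition.
#' @param denominator \code{"markers"} divides every pairwise product by M;
#'   \code{"pairwise_complete"} divides each pair's product by the count of
#'   mutually non-missing markers (requires a \code{standardized_genotypes}
#'   object carrying missingness under mean imputation).
#' @param miss_mask optional N x M logical matrix marking originally missing
#'   calls, used by the \code{"pairwise_complete"} denominator.
#' @return Object of class \code{grm}: list with \code{omega} (N x N
#'   symmetric), \code{n}, \code{m}, and optionally \code{scores}.
#' @export
compute_grm <- function(s, keep_scores = FALSE,
                        denominator = c("markers", "pairwise_complete"),
                        miss_mask = NULL) {
  denominator <- match.arg(denominator)
  scores <- if (inherits(s, "standardized_genotypes")) s$scores else as.matrix(s)
  m <- ncol(scores); n <- nrow(scores)
  if (m == 0) stop("cannot build a GRM from zero markers")
  if (anyNA(scores)) stop("standardized scores contain NA; apply a missing policy first")
  omega <- tcrossprod(scores)
  if (denominator == "markers") {
    omega <- omega / m
  } else {
    obs <- if (!is.null(miss_mask)) (!miss_mask) * 1 else
      matrix(1, n, m) # no mask: every call observed
    cnt <- tcrossprod(obs)
    if (any(cnt == 0)) stop("some pairs share no non-missing marker")
    omega <- omega / cnt
  }
  structure(list(omega = omega, n = n, m = m,
                 scores = if (keep_scores) scores else NULL,
                 denominator = denominator),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  od <- x$omega[upper.tri(x$omega)]
  cat(sprintf("grm: N=%d, M=%d, off-diagonal mean=%.3g var=%.3g\n",
              x$n, x$m, mean(od), stats::var(od)))
  invisible(x)
}

#' Off-diagonal entries of a GRM
#' @param grm a \code{grm}.
#' @return Numeric vector of the N(N-1)/2 upper-triangle relatedness values.
#' @export
grm_offdiag <- function(grm) grm$omega[upper.tri(grm$omega)]

#' Effective number of markers
#'
#' \eqn{M_e = 1/\widehat{var}(\Omega_{ij})} over the off-diagonal
#' relatedness of nominally unrelated individuals.  Inter-marker LD inflates
#' \eqn{var(\Omega)} above \eqn{1/M} and so shrinks \eqn{M_e} below the
#' genotyped marker count: \eqn{var(\Omega_{ij}) = 1/M + (1/M^2)\sum_{k \ne l}
#' \rho^2_{kl}}.  The centered sample variance is used (sample-estimated
#' frequencies leave a small negative mean of order \eqn{-1/(N-1)}).
#'
#' @param grm a \code{grm} with at least 3 samples.
#' @return Object of class \code{pair_statistics}: list with \code{n_pairs},
#'   \code{mean_omega}, \code{var_omega}, \code{me}.
#' @export
effective_marker_count <- function(grm) {
  stopifnot(inherits(grm, "grm"))
  if (grm$n < 3) stop("at least 3 individuals required to estimate M_e")
  od <- grm_offdiag(grm)
  v <- stats::var(od)
  if (!is.finite(v) || v <= 0)
    stop("off-diagonal relatedness has zero variance; M_e undefined")
  structure(list(n_pairs = length(od), mean_omega = mean(od),
                 var_omega = v, me = 1 / v),
            class = "pair_statistics")
}

#' @export
print.pair_statistics <- function(x, ...) {
  cat(sprintf("pairs=%d mean(omega)=%.4g var(omega)=%.4g Me=%.2f\n",
              x$n_pairs, x$mean_omega, x$var_omega, x$me))
  invisible(x)
}

#' Analytic variance of the relatedness under AR(1) marker LD
#'
#' For M equally spaced markers whose pairwise correlation decays as
#' \eqn{\rho^{|k-l|}}, \eqn{var(\Omega) = 1/M + (2/M^2)\sum_{d=1}^{M-1}
#' (M-d)\rho^{2d}}; its reciprocal is the expected effective marker count.
#'
#' @param m marker count.
#' @param rho adjacent-marker correlation in \[0, 1).
#' @return List with \code{var_omega} and \code{me}.
#' @export
ar1_effective_markers <- function(m, rho) {
  stopifnot(m >= 1, rho >= 0, rho < 1)
  d <- seq_len(m - 1)
  v <- 1 / m + if (m > 1) 2 / m^2 * sum((m - d) * rho^(2 * d)) else 0
  list(var_omega = v, me = 1 / v)
}

#' Enumeration oracle for the per-locus relatedness covariance
#'
#' Brute-force check that \eqn{cov(\Omega_{ijk}, \Omega_{ijl}) = \rho^2_{kl}}:
#' enumerates the 9 x 9 joint distribution of two individuals' genotype pairs
#' at two loci (each individual's pair drawn independently from the two-locus
#' joint genotype table) and accumulates the exact covariance of the two
#' single-locus standardized products.
#'
#' @param pair an \code{ld_pair}.
#' @return Exact covariance (a scalar); equals \code{pair$rho^2} analytically.
#' @export
pairwise_ld_cov_oracle <- function(pair) {
  stopifnot(inherits(pair, "ld_pair"))
  tab <- joint_genotype_probs(pair)       # rows: locus l, cols: locus k
  sk <- function(x, p) (x - 2 * p) / sqrt(2 * p * (1 - p))
  s_k <- sk(0:2, pair$p_k); s_l <- sk(0:2, pair$p_l)
  e_kl <- e_k <- e_l <- 0
  for (xi_k in 0:2) for (xi_l in 0:2) for (xj_k in 0:2) for (xj_l in 0:2) {
    pr <- tab[xi_l + 1, xi_k + 1] * tab[xj_l + 1, xj_k + 1]
    if (pr == 0) next
    ok <- s_k[xi_k + 1] * s_k[xj_k + 1]   # Omega_ijk
    ol <- s_l[xi_l + 1] * s_l[xj_l + 1]   # Omega_ijl
    e_kl <- e_kl + pr * ok * ol
    e_k <- e_k + pr * ok
    e_l <- e_l + pr * ol
  }
  e_kl - e_k * e_l
}

#' Filter cryptic relatedness
#'
#' Greedy pruning: while any pair exceeds the relatedness cutoff, drop the
#' individual involved in the most offending pairs (ties broken by sample
#' order).  Mirrors the usual GRM-cutoff cleaning of GWAS samples.
#'
#' @param grm a \code{grm}.
#' @param cutoff positive relatedness threshold (e.g. 0.05).
#' @return Integer vector of retained sample indices.
#' @export
filter_relatedness <- function(grm, cutoff = 0.05) {
  stopifnot(inherits(grm, "grm"), cutoff > 0)
  omega <- grm$omega
  adj <- omega > cutoff
  diag(adj) <- FALSE
  keep <- rep(TRUE, grm$n)
  repeat {
    deg <- rowSums(adj[, keep, drop = FALSE]) * keep
    if (all(deg == 0)) break
    worst <- which.max(deg)       # first max = smallest index tie-break
    keep[worst] <- FALSE
    adj[worst, ] <- FALSE
    adj[, worst] <- FALSE
  }
  which(keep)
}

#' Write a GRM in GCTA text format
#'
#' Emits \code{prefix.grm.gz} (i, j, marker count, relatedness; lower
#' triangle including the diagonal, 1-based indices) and \code{prefix.grm.id}
#' (FID, IID).
#'
#' @param grm a \code{grm}.
#' @param prefix output path prefix.
#' @param samples data.frame with \code{fid}/\code{iid}; synthetic ids when
#'   \code{NULL}.
#' @return \code{prefix}, invisibly.
#' @export
write_gcta_grm <- function(grm, prefix, samples = NULL) {
  stopifnot(inherits(grm, "grm"))
  n <- grm$n
  if (is.null(samples))
    samples <- data.frame(fid = paste0("F", seq_len(n)),
                          iid = paste0("I", seq_len(n)))
  ij <- which(lower.tri(grm$omega, diag = TRUE), arr.ind = TRUE)
  ord <- order(ij[, 1], ij[, 2])
  ij <- ij[ord, , drop = FALSE]
  con <- gzfile(paste0(prefix, ".grm.gz"), "w")
  utils::write.table(data.frame(ij[, 1], ij[, 2], grm$m,
                                grm$omega[ij]),
                     con, quote = FALSE, row.names = FALSE, col.names = FALSE,
                     sep = "\t")
  close(con)
  utils::write.table(samples[, c("fid", "iid")], paste0(prefix, ".grm.id"),
                     quote = FALSE, row.names = FALSE, col.names = FALSE,
                     sep = "\t")
  invisible(prefix)
}

#' Read a GCTA text-format GRM
#'
#' @param prefix path prefix of a \code{.grm.gz}/\code{.grm.id} pair.
#' @return A \code{grm} (with an attached \code{samples} element).
#' @export
read_gcta_grm <- function(prefix) {
  idf <- utils::read.table(paste0(prefix, ".grm.id"), header = FALSE,
                           stringsAsFactors = FALSE)
  n <- nrow(idf)
  df <- utils::read.table(gzfile(paste0(prefix, ".grm.gz")), header = FALSE)
  omega <- matrix(0, n, n)
  omega[cbind(df[[1]], df[[2]])] <- df[[4]]
  omega[cbind(df[[2]], df[[1]])] <- df[[4]]
  out <- structure(list(omega = omega, n = n, m = as.integer(df[[3]][1]),
                        scores = NULL, denominator = "markers"),
                   class = "grm")
  out$samples <- data.frame(fid = as.character(idf[[1]]),
                            iid = as.character(idf[[2]]),
                            stringsAsFactors = FALSE)
  out
}
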