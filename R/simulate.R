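#' Simulate AR(1)-LD biallelic genotypes
#'
#' Each individual receives two independent haplotypes.  Along a haplotype
#' the first allele is Bernoulli(p); each subsequent allele is drawn from
#' the coupling conditional probabilities of the adjacent-locus LD pair with
#' correlation \code{rho} (for p = 0.5 this copies the previous allele with
#' probability (1 + rho)/2).  The implied correlation between loci at
#' distance d is \eqn{\rho^d} on both the haplotype and the genotype scale
#' (random mating).  The genotype is the sum of the two haplotypes.
#'
#' @param n individuals.
#' @param m loci.
#' @param p reference-allele frequency shared by all loci (default 0.5,
#'   equifrequent loci).
#' @param rho adjacent-locus haplotype correlation, in \[0, 1).
#' @return A \code{genotype_matrix}.
#' @export
simulate_ar1_genotypes <- function(n, m, p = 0.5, rho = 0) {
  stopifnot(n >= 1, m >= 1, p > 0, p < 1, rho >= 0)
  if (rho >= 1) stop("adjacent-locus correlation must be below 1")
  h1 <- simulate_ar1_haplotypes(n, m, p, rho)
  h2 <- simulate_ar1_haplotypes(n, m, p, rho)
  genotype_matrix(h1 + h2)
}

#' Simulate AR(1) haplotypes
#'
#' The haplotype chain underlying \code{\link{simulate_ar1_genotypes}};
#' exposed for LD calibration checks.
#'
#' @inheritParams simulate_ar1_genotypes
#' @return n x m 0/1 integer matrix of reference-allele indicators.
#' @export
simulate_ar1_haplotypes <- function(n, m, p = 0.5, rho = 0) {
  hap <- matrix(0L, n, m)
  hap[, 1] <- stats::rbinom(n, 1, p)
  if (m > 1 && rho > 0) {
    pr <- ld_pair(p, p, rho = rho)  # adjacent-locus conditionals
    # P(A at next | A at prev) = R, P(A at next | a at prev) = 1 - r
    for (k in 2:m) {
      prev <- hap[, k - 1]
      prob <- ifelse(prev == 1L, pr$R, 1 - pr$r)
      hap[, k] <- stats::rbinom(n, 1, prob)
    }
  } else if (m > 1) {
    hap[, 2:m] <- stats::rbinom(n * (m - 1), 1, p)
  }
  hap
}

#' Simulate two loci in LD
#'
#' Draws individuals at a (marker, QTL) pair with a given correlation by
#' sampling both haplotypes from the four-haplotype distribution.
#'
#' @param n individuals.
#' @param pair an \code{ld_pair} (locus k first, locus l second).
#' @return List with 0/1/2 vectors \code{x_k} and \code{x_l}.
#' @export
simulate_ld_pair_genotypes <- function(n, pair) {
  stopifnot(inherits(pair, "ld_pair"))
  draw <- function() {
    h <- sample.int(4, n, replace = TRUE, prob = pair$hap)
    # haplotypes ordered AA, Aa, aA, aa over (locus k, locus l)
    cbind(k = as.integer(h <= 2), l = as.integer(h == 1 | h == 3))
  }
  g <- draw() + draw()
  list(x_k = g[, "k"], x_l = g[, "l"])
}

#' Simulate QTL effects
#'
#' Effects are iid normal.  With \code{sorted = TRUE} they are sorted
#' ascending along the locus order, creating like-signed neighbours and
#' hence a non-zero between-locus covariance under LD (the configuration
#' that separates the HE regression from REML).
#'
#' @param l number of QTLs.
#' @param sd effect standard deviation (default 1).
#' @param sorted sort ascending along the segment.
#' @return Numeric effect vector.
#' @export
simulate_effects <- function(l, sd = 1, sorted = FALSE) {
  b <- stats::rnorm(l, 0, sd)
  if (sorted) sort(b) else b
}

#' Simulate a polygenic quantitative phenotype
#'
#' Genetic value \eqn{g_i = \sum_l x_{il}\beta_l}; residuals are Gaussian
#' with variance \eqn{\sigma^2_e = \sigma^2_{A}(1 - h^2)/h^2} where
#' \eqn{\sigma^2_A} is the analytic covariance-inclusive additive variance
#' computed from the generator's known LD (\eqn{\rho^{|l_1-l_2|}}), so the
#' target heritability holds by construction for every effect draw.
#'
#' @param g a \code{genotype_matrix} whose loci are the QTLs.
#' @param betas additive effects aligned to the loci.
#' @param h2 target heritability, in (0, 1).
#' @param rho adjacent-locus correlation used by the generator (for the
#'   analytic additive variance).
#' @param p QTL allele frequency used by the generator.
#' @return List with \code{y} (phenotype), \code{g_value} (genetic values),
#'   \code{sigma2_A} (analytic total additive variance), \code{sigma2_e},
#'   \code{var_y} (analytic phenotypic variance).
#' @export
simulate_phenotype <- function(g, betas, h2, rho = 0, p = 0.5) {
  calls <- if (inherits(g, "genotype_matrix")) g$calls else as.matrix(g)
  l <- ncol(calls)
  stopifnot(length(betas) == l, h2 > 0, h2 < 1)
  model <- qtl_model(p_markers = rep(p, l), p_qtls = rep(p, l), betas = betas,
                     rho_mq = ar1_corr(seq_len(l), rho = rho),
                     rho_mm = ar1_corr(seq_len(l), rho = rho),
                     rho_qq = ar1_corr(seq_len(l), rho = rho))
  s2a <- additive_variance(model)$total
  if (s2a <= 0)
    stop("covariance-inclusive additive variance is non-positive for these effects")
  s2e <- s2a * (1 - h2) / h2
  gv <- drop(calls %*% betas)
  y <- gv + stats::rnorm(nrow(calls), 0, sqrt(s2e))
  list(y = y, g_value = gv, sigma2_A = s2a, sigma2_e = s2e,
       var_y = s2a + s2e)
}

#' One replicate of the polygenic marker-equals-QTL study
#'
#' The workhorse behind the quantitative-trait simulation studies: N
#' individuals at M = L equifrequent loci with AR(1) LD, iid (optionally
#' sorted) standard-normal effects, residual variance set for the target
#' covariance-inclusive heritability, GRM built from the same loci with
#' sample-estimated frequencies.
#'
#' @param n individuals (default 1000).
#' @param m loci = QTLs (default 100).
#' @param rho adjacent-locus correlation.
#' @param h2 target heritability (default 0.5).
#' @param sorted sort effects ascending (default FALSE).
#' @param p allele frequency (default 0.5).
#' @param keep_scores retain standardized scores in the GRM (fast REML).
#' @return List with \code{genotypes}, \code{betas}, \code{phenotype} (the
#'   \code{\link{simulate_phenotype}} output), \code{grm}, and the
#'   \code{\link{expected_b_multi}} prediction \code{expectation}.
#' @export
simulate_polygenic_study <- function(n = 1000, m = 100, rho = 0, h2 = 0.5,
                                     sorted = FALSE, p = 0.5,
                                     keep_scores = TRUE) {
  geno <- simulate_ar1_genotypes(n, m, p = p, rho = rho)
  betas <- simulate_effects(m, sorted = sorted)
  ph <- simulate_phenotype(geno, betas, h2 = h2, rho = rho, p = p)
  s <- standardize_genotypes(geno)
  grm <- compute_grm(s, keep_scores = keep_scores)
  model <- qtl_model(p_markers = rep(p, m), p_qtls = rep(p, m), betas = betas,
                     rho_mq = ar1_corr(seq_len(m), rho = rho),
                     rho_mm = ar1_corr(seq_len(m), rho = rho),
                     rho_qq = ar1_corr(seq_len(m), rho = rho))
  expectation <- expected_b_multi(model, var_y = ph$var_y)
  list(genotypes = geno, betas = betas, phenotype = ph, grm = grm,
       expectation = expectation)
}

#' One replicate of the single-marker study
#'
#' One marker and one QTL, both equifrequent, in LD \code{rho}; the QTL
#' explains \code{h2} of the phenotypic variance; the GRM is built on the
#' single marker.
#'
#' @param n individuals.
#' @param rho marker-QTL correlation.
#' @param h2 QTL heritability.
#' @param p allele frequency.
#' @return List with \code{y} (standardized phenotype), \code{grm},
#'   \code{fit} (the \code{\link{he_fit}} with \code{me = 1}).
#' @export
simulate_single_marker_study <- function(n = 1000, rho = 0.5, h2 = 0.5,
                                         p = 0.5) {
  pair <- ld_pair(p, p, rho = rho)
  gg <- simulate_ld_pair_genotypes(n, pair)
  beta <- 1
  s2a <- 2 * p * (1 - p) * beta^2
  s2e <- s2a * (1 - h2) / h2
  y <- gg$x_l * beta + stats::rnorm(n, 0, sqrt(s2e))
  s <- standardize_genotypes(matrix(gg$x_k, ncol = 1))
  grm <- compute_grm(s)
  fit <- he_fit(y, grm, me = 1)
  list(y = y, grm = grm, fit = fit)
}

#' Simulate an ascertained case-control sample
#'
#' Liability-threshold model: L equifrequent loci in linkage equilibrium,
#' effects iid \eqn{N(0, h^2_l / (2 p q L))}; the genetic value is centered
#' and scaled by its analytic standard deviation so the unit-variance
#' liability carries exactly a share \eqn{h^2_l} of genetic variance; an
#' individual is a case when liability exceeds \eqn{\Phi^{-1}(1-K)}.
#' Candidates are drawn in batches until the case and control quotas fill.
#'
#' @param n_cases,n_controls ascertainment quotas.
#' @param l number of QTLs.
#' @param h2_liab liability-scale heritability, in \[0, 1).
#' @param K population prevalence.
#' @param p allele frequency (default 0.5).
#' @param batch candidate batch size (default 10000).
#' @param max_draws cap on total candidates examined; low-prevalence,
#'   high-quota settings that would exceed it raise an error suggesting a
#'   scaled-down design.
#' @return List with \code{genotypes} (a \code{genotype_matrix} of the
#'   retained individuals), \code{status} (0/1 vector), \code{betas},
#'   \code{n_drawn}, \code{case_rate} (casual batch case rate before
#'   ascertainment).
#' @export
simulate_case_control <- function(n_cases = 1000, n_controls = 1000,
                                  l = 100, h2_liab = 0.5, K = 0.1,
                                  p = 0.5, batch = 10000,
                                  max_draws = 5e6) {
  stopifnot(K > 0, K < 1, h2_liab >= 0, h2_liab < 1)
  expected <- (n_cases / K + n_controls / (1 - K)) * 1.2
  if (expected > max_draws)
    stop(sprintf(paste0("expected sampling effort ~%.0f candidates exceeds the cap %g; ",
                        "reduce the quotas or raise the prevalence/cap"),
                 expected, max_draws))
  sigma_b <- sqrt(h2_liab / (2 * p * (1 - p) * l))
  betas <- stats::rnorm(l, 0, sigma_b)
  sd_g <- sqrt(sum(2 * p * (1 - p) * betas^2))
  mu_g <- 2 * p * sum(betas)
  thr <- stats::qnorm(1 - K)
  got_case <- got_ctrl <- 0L
  keep_calls <- vector("list", 0)
  keep_status <- vector("list", 0)
  n_drawn <- 0L; n_case_seen <- 0L
  while (got_case < n_cases || got_ctrl < n_controls) {
    if (n_drawn >= max_draws)
      stop("case-control sampling cap reached before the quotas filled")
    calls <- matrix(stats::rbinom(batch * l, 2, p), batch, l)
    gv <- drop(calls %*% betas)
    gl <- if (sd_g > 0) (gv - mu_g) / sd_g * sqrt(h2_liab) else numeric(batch)
    liab <- gl + stats::rnorm(batch, 0, sqrt(1 - h2_liab))
    case <- liab > thr
    n_drawn <- n_drawn + batch
    n_case_seen <- n_case_seen + sum(case)
    need_case <- n_cases - got_case
    need_ctrl <- n_controls - got_ctrl
    take_case <- which(case)[seq_len(min(need_case, sum(case)))]
    take_ctrl <- which(!case)[seq_len(min(need_ctrl, sum(!case)))]
    take <- c(take_case, take_ctrl)
    if (length(take)) {
      keep_calls[[length(keep_calls) + 1L]] <- calls[take, , drop = FALSE]
      keep_status[[length(keep_status) + 1L]] <-
        as.integer(case[take])
      got_case <- got_case + length(take_case)
      got_ctrl <- got_ctrl + length(take_ctrl)
    }
  }
  calls <- do.call(rbind, keep_calls)
  status <- unlist(keep_status)
  list(genotypes = genotype_matrix(calls), status = status, betas = betas,
       n_drawn = n_drawn, case_rate = n_case_seen / n_drawn)
}
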