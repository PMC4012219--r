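#' Liability-threshold transformation parameters
#'
#' For a disease of population prevalence K studied with case proportion P,
#' the liability threshold is \eqn{t = \Phi^{-1}(1 - K)} (cases exceed it)
#' and \eqn{z = \phi(t)} is the standard normal density at the threshold.
#'
#' @param K population prevalence, in (0, 1).
#' @param P case proportion in the sample, in (0, 1); defaults to K
#'   (unascertained sampling).
#' @return Object of class \code{liability_params}: \code{K}, \code{P},
#'   \code{t}, \code{z}.
#' @export
liability_params <- function(K, P = K) {
  if (K <= 0 || K >= 1) stop("prevalence K must be in (0, 1)")
  if (P <= 0 || P >= 1) stop("case proportion P must be in (0, 1)")
  t <- stats::qnorm(1 - K)
  structure(list(K = K, P = P, t = t, z = stats::dnorm(t)),
            class = "liability_params")
}

#' Observed-scale to liability-scale heritability
#'
#' The ascertainment-corrected transformation of Lee et al. from the
#' heritability estimated on the observed 0/1 scale to the liability scale:
#' \deqn{h^2_l = h^2_o \; \frac{K(1-K)}{z^2} \; \frac{K(1-K)}{P(1-P)}.}
#' Observed-scale estimates from ascertained case-control samples can
#' legitimately exceed 1; the transformation is linear in \eqn{h^2_o}.
#'
#' @param h2_obs observed-scale heritability (any finite value).
#' @param params a \code{liability_params}, or prevalence K (then \code{P}).
#' @param P case proportion when \code{params} is given as a prevalence.
#' @return Liability-scale heritability.
#' @export
observed_to_liability <- function(h2_obs, params, P = NULL) {
  if (!inherits(params, "liability_params"))
    params <- liability_params(params, if (is.null(P)) params else P)
  h2_obs * liability_factor(params)
}

#' Liability-scale to observed-scale heritability
#'
#' Exact algebraic inverse of \code{\link{observed_to_liability}}.
#'
#' @inheritParams observed_to_liability
#' @param h2_liab liability-scale heritability.
#' @return Observed-scale heritability.
#' @export
liability_to_observed <- function(h2_liab, params, P = NULL) {
  if (!inherits(params, "liability_params"))
    params <- liability_params(params, if (is.null(P)) params else P)
  h2_liab / liability_factor(params)
}

# multiplicative constant K^2(1-K)^2 / (z^2 P(1-P))
liability_factor <- function(params) {
  with(params, K^2 * (1 - K)^2 / (z^2 * P * (1 - P)))
}
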