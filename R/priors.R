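# Prior components: beta-prime on exponentiated thresholds, Cauchy slabs,
# Bernoulli / beta-Bernoulli indicator priors, and single-indicator prior odds.

#' Bernoulli indicator prior
#'
#' Fixed inclusion probability `pi` for every indicator independently. With
#' `pi = 0.5` every configuration of indicators is equally likely a priori,
#' but the prior carries no multiplicity correction.
#'
#' @param pi inclusion probability, strictly inside (0, 1).
#' @return list of class `indicator_prior`.
#' @export
bernoulli_prior <- function(pi = 0.5) {
  if (!is.finite(pi) || pi <= 0 || pi >= 1) {
    stop("bernoulli_prior: pi must lie strictly inside (0, 1)", call. = FALSE)
  }
  structure(list(type = "bernoulli", pi = pi), class = "indicator_prior")
}

#' Beta-Bernoulli indicator prior
#'
#' Hierarchical prior: inclusion probability drawn from Beta(alpha, beta) and
#' shared by all indicators of a family. With `alpha = beta = 1` the implied
#' distribution over the *number* of included effects is uniform, which
#' provides automatic multiplicity correction.
#'
#' @param alpha,beta positive shape parameters.
#' @return list of class `indicator_prior`.
#' @export
beta_bernoulli_prior <- function(alpha = 1, beta = 1) {
  if (!is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0) {
    stop("beta_bernoulli_prior: alpha and beta must be positive",
         call. = FALSE)
  }
  structure(list(type = "beta_bernoulli", alpha = alpha, beta = beta),
            class = "indicator_prior")
}

#' Prior configuration for the two-group OMRF
#'
#' @param threshold_shape_a,threshold_shape_b positive shapes of the
#'   beta-prime prior placed on the exponentially transformed overall
#'   category thresholds (defaults 1, 1: logistic density on the log scale).
#' @param overall_interaction_scale Cauchy scale of the prior on overall
#'   pairwise interactions (default 2.5).
#' @param difference_scale Cauchy scale of the slab on difference parameters,
#'   shared by threshold and interaction differences unless overridden via
#'   `threshold_difference_scale` / `interaction_difference_scale`.
#' @param threshold_difference_scale,interaction_difference_scale optional
#'   per-family overrides of `difference_scale`.
#' @param threshold_indicator_prior,interaction_indicator_prior an
#'   [bernoulli_prior()] or [beta_bernoulli_prior()] per indicator family.
#' @return list of class `prior_config`.
#' @export
prior_config <- function(threshold_shape_a = 1,
                         threshold_shape_b = 1,
                         overall_interaction_scale = 2.5,
                         difference_scale = 1,
                         threshold_difference_scale = NULL,
                         interaction_difference_scale = NULL,
                         threshold_indicator_prior = bernoulli_prior(0.5),
                         interaction_indicator_prior = bernoulli_prior(0.5)) {
  scales <- c(threshold_shape_a, threshold_shape_b,
              overall_interaction_scale, difference_scale)
  if (any(!is.finite(scales)) || any(scales <= 0)) {
    stop("prior_config: shapes and scales must be strictly positive",
         call. = FALSE)
  }
  stopifnot(inherits(threshold_indicator_prior, "indicator_prior"),
            inherits(interaction_indicator_prior, "indicator_prior"))
  structure(list(
    threshold_shape_a = threshold_shape_a,
    threshold_shape_b = threshold_shape_b,
    overall_interaction_scale = overall_interaction_scale,
    threshold_difference_scale =
      threshold_difference_scale %||% difference_scale,
    interaction_difference_scale =
      interaction_difference_scale %||% difference_scale,
    threshold_indicator_prior = threshold_indicator_prior,
    interaction_indicator_prior = interaction_indicator_prior
  ), class = "prior_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Log-density of the threshold prior
#'
#' The prior on a category threshold `mu` is beta-prime on `exp(mu)`:
#' after the change of variables the log-density is
#' `a * mu - (a + b) * log(1 + exp(mu)) - log B(a, b)`, evaluated in a
#' numerically stable way for large `|mu|`.
#'
#' @param mu threshold value(s), log-odds scale.
#' @param a,b positive beta-prime shapes.
#' @return log-density, vectorized over `mu`.
#' @export
log_threshold_prior <- function(mu, a = 1, b = 1) {
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) {
    stop("log_threshold_prior: shapes must be positive", call. = FALSE)
  }
  # log(1 + e^mu) = max(mu, 0) + log1p(exp(-|mu|))
  log1pe <- pmax(mu, 0) + log1p(exp(-abs(mu)))
  a * mu - (a + b) * log1pe - lbeta(a, b)
}

#' Log-density of a centered Cauchy distribution
#'
#' @param x value(s).
#' @param scale positive scale.
#' @return log-density, vectorized over `x`.
#' @export
log_cauchy <- function(x, scale = 1) {
  if (!is.finite(scale) || scale <= 0) {
    stop("log_cauchy: scale must be positive", call. = FALSE)
  }
  -log(pi * scale) - log1p((x / scale)^2)
}

#' Log prior mass of an indicator configuration
#'
#' Bernoulli: `k log(pi) + (K - k) log(1 - pi)` for `k` included of `K`.
#' Beta-Bernoulli: `log B(alpha + k, beta + K - k) - log B(alpha, beta)`
#' (indicator-exchangeable; depends on the configuration only through `k`).
#'
#' @param indicators binary vector.
#' @param prior an `indicator_prior`.
#' @return scalar log-probability.
#' @export
log_indicator_prior <- function(indicators, prior) {
  stopifnot(inherits(prior, "indicator_prior"))
  indicators <- as.integer(indicators)
  if (length(indicators) < 1L || any(!indicators %in% c(0L, 1L))) {
    stop("log_indicator_prior: indicators must be a nonempty 0/1 vector",
         call. = FALSE)
  }
  K <- length(indicators)
  k <- sum(indicators)
  if (prior$type == "bernoulli") {
    k * log(prior$pi) + (K - k) * log1p(-prior$pi)
  } else {
    lbeta(prior$alpha + k, prior$beta + K - k) -
      lbeta(prior$alpha, prior$beta)
  }
}

#' Prior odds of including a single indicator
#'
#' Bernoulli: `pi / (1 - pi)`. Beta-Bernoulli: the marginal inclusion
#' probability of any single indicator is `alpha / (alpha + beta)` by
#' exchangeability, hence odds `alpha / beta`. These are the prior odds used
#' in inclusion Bayes factors.
#'
#' @param prior an `indicator_prior`.
#' @return positive scalar.
#' @export
single_indicator_prior_odds <- function(prior) {
  stopifnot(inherits(prior, "indicator_prior"))
  if (prior$type == "bernoulli") prior$pi / (1 - prior$pi)
  else prior$alpha / prior$beta
}
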