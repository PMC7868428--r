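#' Weight on the data in a conjugate posterior mean
#'
#' `w = J / (nu0 + J)`: the share of the posterior point estimate
#' contributed by the sample estimate. `nu0 = 0` gives `w = 1` (no prior
#' information); larger prior sample sizes shrink the estimate further
#' toward the prior guess.
#'
#' @param J Number of groups (>= 1).
#' @param nu0 Prior sample size (>= 0).
#' @return A proportion in (0, 1].
#' @export
#' @examples
#' shrinkage_weight(20, 5)  # 0.8
shrinkage_weight <- function(J, nu0) {
  if (!is.numeric(J) || any(J < 1)) stop("'J' must be >= 1", call. = FALSE)
  .check_nu0(nu0)
  J / (nu0 + J)
}

.new_estimate <- function(value, method, weight_w = numeric(0),
                          flags = character(0)) {
  structure(list(value = value, method = method, weight_w = weight_w,
                 flags = flags),
            class = "mlc_estimate")
}

#' @export
print.mlc_estimate <- function(x, ...) {
  cat(sprintf("Between-group slope estimate (%s): %g\n", x$method, x$value))
  if (length(x$weight_w))
    cat("  data weight(s) w:", paste(signif(x$weight_w, 6), collapse = ", "),
        "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Maximum-likelihood estimator of the between-group slope
#'
#' For balanced data the ML estimator is the ratio of the between-group
#' covariance to the between-group variance of the predictor,
#' `tau_yx_hat / tau2_x_hat`. A non-positive denominator still yields a
#' numeric value but carries a `"degenerate"` flag: the moment estimate of a
#' variance has undershot zero and the ratio is not interpretable as a
#' slope.
#'
#' @param stats An `"mlc_suffstats"`.
#' @return An `"mlc_estimate"` with `method = "ml"`.
#' @export
ml_slope <- function(stats) {
  stopifnot(inherits(stats, "mlc_suffstats"))
  if (stats$tau2_x_hat == 0)
    stop("tau2_x_hat is exactly 0: the ML slope is undefined", call. = FALSE)
  flags <- if (stats$tau2_x_hat < 0) "degenerate" else character(0)
  .new_estimate(stats$tau_yx_hat / stats$tau2_x_hat, "ml", flags = flags)
}

#' Posterior of the slope under the direct normal prior
#'
#' Combining the normal prior `beta_b ~ N(beta0, tau2_y / (nu0 * tau2_x))`
#' with the normal likelihood centred at the ML slope with variance
#' `tau2_y_hat / (J * tau2_x_hat)` gives a normal posterior with mean
#' `(1 - w) * beta0 + w * beta_hat` and variance
#' `w * tau2_y_hat / (J * tau2_x_hat)`, where `w = J / (nu0 + J)`.
#'
#' @param stats An `"mlc_suffstats"` with `tau2_x_hat > 0` (the direct
#'   strategy needs a usable likelihood) and `tau2_y_hat > 0`.
#' @param prior An `"mlc_direct_prior"`.
#' @return For `direct_posterior()`, a list of class
#'   `"mlc_normal_posterior"` with elements `mean` and `variance`. For
#'   `direct_eap()`, an `"mlc_estimate"` whose value is the posterior mean
#'   (the expected a posteriori point estimate).
#' @export
#' @examples
#' s <- suffstats(tau2_x_hat = 0.1, tau_yx_hat = 0.07, tau2_y_hat = 0.15,
#'                sigma2_x_hat = 0.9, J = 20, n = 5)
#' direct_posterior(s, direct_prior(0, 1))
#' direct_eap(s, direct_prior(0, 1))
direct_posterior <- function(stats, prior) {
  stopifnot(inherits(stats, "mlc_suffstats"),
            inherits(prior, "mlc_direct_prior"))
  if (stats$tau2_x_hat <= 0)
    stop("direct strategy requires tau2_x_hat > 0 (got ",
         signif(stats$tau2_x_hat, 4), ")", call. = FALSE)
  if (stats$tau2_y_hat <= 0)
    stop("direct posterior variance requires tau2_y_hat > 0 (got ",
         signif(stats$tau2_y_hat, 4), ")", call. = FALSE)
  w <- shrinkage_weight(stats$J, prior$nu0)
  bhat <- stats$tau_yx_hat / stats$tau2_x_hat
  structure(
    list(mean = (1 - w) * prior$beta0 + w * bhat,
         variance = w * stats$tau2_y_hat / (stats$J * stats$tau2_x_hat)),
    class = "mlc_normal_posterior"
  )
}

#' @rdname direct_posterior
#' @export
direct_eap <- function(stats, prior) {
  stopifnot(inherits(stats, "mlc_suffstats"),
            inherits(prior, "mlc_direct_prior"))
  if (stats$tau2_x_hat <= 0)
    stop("direct strategy requires tau2_x_hat > 0 (got ",
         signif(stats$tau2_x_hat, 4), ")", call. = FALSE)
  w <- shrinkage_weight(stats$J, prior$nu0)
  bhat <- stats$tau_yx_hat / stats$tau2_x_hat
  .new_estimate((1 - w) * prior$beta0 + w * bhat, "direct", weight_w = w)
}

#' @export
print.mlc_normal_posterior <- function(x, ...) {
  cat(sprintf("Normal posterior for the slope: mean = %g, variance = %g\n",
              x$mean, x$variance))
  invisible(x)
}

#' Posterior of the inverse group-level variance under the indirect prior
#'
#' The gamma prior `1/tau2_x ~ Gamma(nu0/2, nu0 * tau0_sq / 2)` combined
#' with the gamma likelihood `Gamma(J/2, J * tau2_x_hat / 2)` yields
#' `Gamma((nu0 + J)/2, (nu0 * tau0_sq + J * tau2_x_hat)/2)`. A negative
#' `tau2_x_hat` is truncated to 0 before entering the posterior rate (the
#' prior term keeps the rate positive whenever `nu0 > 0`).
#'
#' @param stats An `"mlc_suffstats"`, or `NULL` for the prior-only (no
#'   data, `J = 0`) limit.
#' @param prior An `"mlc_indirect_prior"`.
#' @return A list of class `"mlc_gamma_posterior"` with elements `shape`
#'   and `rate` (for the distribution of `1/tau2_x`).
#' @export
#' @examples
#' s <- suffstats(0.1, 0.07, 0.199, 0.9, J = 20, n = 5)
#' indirect_posterior(s, indirect_prior(1, 1))  # shape 10.5, rate 1.5
indirect_posterior <- function(stats, prior) {
  stopifnot(inherits(prior, "mlc_indirect_prior"))
  if (is.null(stats)) {
    J <- 0
    t2x <- 0
  } else {
    stopifnot(inherits(stats, "mlc_suffstats"))
    J <- stats$J
    t2x <- max(stats$tau2_x_hat, 0)
  }
  shape <- (prior$nu0 + J) / 2
  rate <- (prior$nu0 * prior$tau0_sq + J * t2x) / 2
  if (rate <= 0)
    stop("posterior rate is not positive (flat prior and non-positive ",
         "tau2_x_hat)", call. = FALSE)
  structure(list(shape = shape, rate = rate), class = "mlc_gamma_posterior")
}

#' @export
print.mlc_gamma_posterior <- function(x, ...) {
  cat(sprintf("Gamma posterior for 1/tau2_x: shape = %g, rate = %g\n",
              x$shape, x$rate))
  invisible(x)
}

#' Stabilized estimate of the between-group predictor variance
#'
#' `indirect_variance_eap()` is the weighted-average approximation to the
#' posterior mean of `tau2_x`:
#' `(1 - w) * tau0_sq + w * max(tau2_x_hat, 0)` with `w = J / (nu0 + J)`.
#' It is strictly positive whenever `nu0 > 0`, even when the moment
#' estimate has been truncated at zero — this is precisely how the indirect
#' prior pulls variance estimates away from zero.
#'
#' `indirect_variance_exact()` is the exact mean of the inverse-gamma
#' posterior, `rate / (shape - 1)`, exposed as a diagnostic for the quality
#' of the weighted-average approximation (it requires `shape > 1`, i.e.,
#' `nu0 + J > 2`).
#'
#' @inheritParams indirect_posterior
#' @return A single positive number (variance units).
#' @export
#' @examples
#' s <- suffstats(0.1, 0.07, 0.199, 0.9, J = 20, n = 5)
#' indirect_variance_eap(s, indirect_prior(1, 1))
#' indirect_variance_exact(s, indirect_prior(1, 1))
indirect_variance_eap <- function(stats, prior) {
  stopifnot(inherits(stats, "mlc_suffstats"),
            inherits(prior, "mlc_indirect_prior"))
  w <- shrinkage_weight(stats$J, prior$nu0)
  (1 - w) * prior$tau0_sq + w * max(stats$tau2_x_hat, 0)
}

#' @rdname indirect_variance_eap
#' @export
indirect_variance_exact <- function(stats, prior) {
  post <- indirect_posterior(stats, prior)
  if (post$shape <= 1)
    stop("exact inverse-gamma mean requires shape > 1 (nu0 + J > 2)",
         call. = FALSE)
  post$rate / (post$shape - 1)
}

#' Indirect-prior estimator of the between-group slope
#'
#' Replaces the denominator of the ML ratio with the stabilized variance
#' estimate: `tau_yx_hat / ((1 - w) * tau0_sq + w * tau2_x_hat)`. Because
#' the denominator is bounded away from zero for `nu0 > 0`, the estimator
#' stays finite even when the moment estimate of the variance collapses,
#' and large-magnitude slopes are attenuated (the Bayesian analogue of the
#' ridge technique).
#'
#' @inheritParams indirect_variance_eap
#' @return An `"mlc_estimate"` with `method = "indirect"`. Carries a
#'   `"truncated"` flag when `tau2_x_hat < 0` was truncated to zero.
#' @export
indirect_slope <- function(stats, prior) {
  stopifnot(inherits(stats, "mlc_suffstats"),
            inherits(prior, "mlc_indirect_prior"))
  w <- shrinkage_weight(stats$J, prior$nu0)
  denom <- indirect_variance_eap(stats, prior)
  if (denom <= 0)
    stop("stabilized variance is not positive (nu0 = 0 and tau2_x_hat <= 0)",
         call. = FALSE)
  flags <- if (stats$tau2_x_hat < 0) "truncated" else character(0)
  .new_estimate(stats$tau_yx_hat / denom, "indirect", weight_w = w,
                flags = flags)
}

#' Combined estimator: both priors applied simultaneously
#'
#' The two strategies are not mutually exclusive. The combined estimator
#' first stabilizes the variance with the indirect prior, giving the
#' indirect slope, then shrinks that slope toward the direct prior guess:
#' `(1 - w_d) * beta0 + w_d * indirect_slope`, with
#' `w_d = J / (dprior$nu0 + J)`. The indirect stage comes first because the
#' slope likelihood itself depends on the variance estimate being usable.
#' Either prior with `nu0 = 0` drops out, so the estimator includes the
#' direct, indirect, and ML estimators as limiting cases.
#'
#' @param stats An `"mlc_suffstats"`.
#' @param dprior An `"mlc_direct_prior"`.
#' @param iprior An `"mlc_indirect_prior"`.
#' @return An `"mlc_estimate"` with `method = "combined"` and both weights
#'   in `weight_w` (named `direct`, `indirect`).
#' @export
combined_slope <- function(stats, dprior, iprior) {
  stopifnot(inherits(dprior, "mlc_direct_prior"))
  ind <- indirect_slope(stats, iprior)
  w_d <- shrinkage_weight(stats$J, dprior$nu0)
  .new_estimate((1 - w_d) * dprior$beta0 + w_d * ind$value, "combined",
                weight_w = c(direct = w_d, indirect = ind$weight_w[[1]]),
                flags = ind$flags)
}
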