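#' Slightly informative priors in the prior-guess / prior-sample-size form
#'
#' Both prior-specification strategies use an interpretable
#' reparameterization in which the posterior point estimate is a weighted
#' average of a prior guess and the sample estimate, with weight
#' `w = J / (nu0 + J)` on the data.
#'
#' `direct_prior()` places a normal prior on the between-group slope itself:
#' `beta_b ~ N(beta0, tau2_y / (nu0 * tau2_x))`. `indirect_prior()` places a
#' gamma prior on the inverse of the between-group predictor variance:
#' `1/tau2_x ~ Gamma(nu0 / 2, nu0 * tau0_sq / 2)`, i.e., an inverse-gamma
#' prior on the variance that pulls its estimates away from zero.
#'
#' `nu0 = 0` denotes the flat, no-prior-information limit in which every
#' shrinkage estimator reduces to maximum likelihood.
#'
#' @param beta0 Prior guess for the between-group slope.
#' @param tau0_sq Prior guess for the between-group predictor variance
#'   (> 0).
#' @param nu0 Prior sample size in pseudo-groups (>= 0).
#'
#' @return An object of class `"mlc_direct_prior"` or
#'   `"mlc_indirect_prior"`.
#' @export
#' @examples
#' direct_prior(beta0 = 0, nu0 = 1)
#' indirect_prior(tau0_sq = 1, nu0 = 1)
direct_prior <- function(beta0, nu0) {
  if (!is.numeric(beta0) || length(beta0) != 1L || !is.finite(beta0))
    stop("'beta0' must be a single finite number", call. = FALSE)
  .check_nu0(nu0)
  structure(list(beta0 = beta0, nu0 = nu0), class = "mlc_direct_prior")
}

#' @rdname direct_prior
#' @export
indirect_prior <- function(tau0_sq, nu0) {
  if (!is.numeric(tau0_sq) || length(tau0_sq) != 1L || tau0_sq <= 0)
    stop("'tau0_sq' must be a single positive number", call. = FALSE)
  .check_nu0(nu0)
  structure(list(tau0_sq = tau0_sq, nu0 = nu0), class = "mlc_indirect_prior")
}

.check_nu0 <- function(nu0) {
  if (!is.numeric(nu0) || length(nu0) != 1L || !is.finite(nu0) || nu0 < 0)
    stop("'nu0' must be a single number >= 0", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.mlc_direct_prior <- function(x, ...) {
  cat(sprintf("Direct prior on the slope: beta0 = %g, nu0 = %g\n",
              x$beta0, x$nu0))
  invisible(x)
}

#' @export
print.mlc_indirect_prior <- function(x, ...) {
  cat(sprintf(
    "Indirect prior on the group-level variance: tau0_sq = %g, nu0 = %g\n",
    x$tau0_sq, x$nu0))
  invisible(x)
}

#' Translate priors into the Mplus hyperparameterization
#'
#' Mplus parameterizes a normal prior as `N(a, b)` with mean `a` and
#' variance `b`, and an inverse-gamma prior as `IG(a, b)` with shape `a` and
#' rate `b`. For the direct strategy, `a = beta0` and
#' `b = tau2_y / (nu0 * tau2_x)`; since the two variances are unknown they
#' are replaced by sample estimates. For the indirect strategy, `a = nu0/2`
#' and `b = nu0 * tau0_sq / 2`.
#'
#' @param prior An `"mlc_direct_prior"` or `"mlc_indirect_prior"` with
#'   `nu0 > 0` (a flat prior has no proper Mplus form).
#' @param tau2_y,tau2_x Group-level variance (estimates) of outcome and
#'   predictor used to evaluate the direct prior's variance parameter.
#' @return A named numeric vector `c(a = , b = )`.
#' @export
#' @examples
#' direct_prior_to_mplus(direct_prior(0, 1), tau2_y = 0.15, tau2_x = 0.1)
#' indirect_prior_to_mplus(indirect_prior(1, 1))
direct_prior_to_mplus <- function(prior, tau2_y, tau2_x) {
  stopifnot(inherits(prior, "mlc_direct_prior"))
  if (prior$nu0 == 0)
    stop("a flat direct prior (nu0 = 0) has no proper N(a, b) form",
         call. = FALSE)
  if (!is.numeric(tau2_x) || length(tau2_x) != 1L || tau2_x <= 0)
    stop("'tau2_x' must be a single positive number", call. = FALSE)
  if (!is.numeric(tau2_y) || length(tau2_y) != 1L || tau2_y <= 0)
    stop("'tau2_y' must be a single positive number", call. = FALSE)
  c(a = prior$beta0, b = tau2_y / (prior$nu0 * tau2_x))
}

#' @rdname direct_prior_to_mplus
#' @export
indirect_prior_to_mplus <- function(prior) {
  stopifnot(inherits(prior, "mlc_indirect_prior"))
  if (prior$nu0 == 0)
    stop("a flat indirect prior (nu0 = 0) has no proper IG(a, b) form",
         call. = FALSE)
  c(a = prior$nu0 / 2, b = prior$nu0 * prior$tau0_sq / 2)
}

# minimal-decimal rendering: 1.5 not 1.50, 2 not 2.0
.fmt_mplus <- function(x) {
  format(x, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
}

#' Render an Mplus MODEL PRIORS block
#'
#' Emits the exact `MODEL PRIORS:` syntax for one or both prior strategies,
#' with caller-supplied parameter labels, e.g.
#' \preformatted{MODEL PRIORS:
#'    slope ~ N(0, 1.5);}
#'
#' @param direct Optional `"mlc_direct_prior"`.
#' @param indirect Optional `"mlc_indirect_prior"`.
#' @param tau2_y,tau2_x Variance estimates; required with a direct prior,
#'   because its Mplus variance parameter is `tau2_y / (nu0 * tau2_x)`.
#' @param slope_label,variance_label Parameter names to print.
#' @return A single string (lines separated by newlines, no trailing
#'   newline); print it with `cat()`.
#' @export
#' @examples
#' cat(mplus_priors(direct = direct_prior(0, 1),
#'                  tau2_y = 0.15, tau2_x = 0.1), "\n")
mplus_priors <- function(direct = NULL, indirect = NULL,
                         tau2_y = NULL, tau2_x = NULL,
                         slope_label = "slope",
                         variance_label = "variance") {
  if (is.null(direct) && is.null(indirect))
    stop("specify at least one prior", call. = FALSE)
  lines <- "MODEL PRIORS:"
  if (!is.null(direct)) {
    if (is.null(tau2_y) || is.null(tau2_x))
      stop("the direct prior's Mplus variance parameter is ",
           "b = tau2_y / (nu0 * tau2_x); supply 'tau2_y' and 'tau2_x' ",
           "estimates to evaluate it", call. = FALSE)
    ab <- direct_prior_to_mplus(direct, tau2_y = tau2_y, tau2_x = tau2_x)
    lines <- c(lines, sprintf("   %s ~ N(%s, %s);", slope_label,
                              .fmt_mplus(ab[["a"]]), .fmt_mplus(ab[["b"]])))
  }
  if (!is.null(indirect)) {
    ab <- indirect_prior_to_mplus(indirect)
    lines <- c(lines, sprintf("   %s ~ IG(%s, %s);", variance_label,
                              .fmt_mplus(ab[["a"]]), .fmt_mplus(ab[["b"]])))
  }
  paste(lines, collapse = "\n")
}
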