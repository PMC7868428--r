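# Shared quantities of the first-order accuracy expansions.
#
# c  = (1 - rho_x) / (n * rho_x): unreliability of a group mean of X --
#      within-group noise variance relative to the true between variance.
# r  = beta_w / beta_b (defined as 0 when both slopes are 0).
# A  = rho_y/rho_x + c * (rho_y/rho_x + (1 - rho_y)/(1 - rho_x)): the
#      variance bracket common to all three estimators.
# Vr = Var(Y)/Var(X), the total-variance ratio multiplying A.
#
# rho_y and Vr use the *total* between/within decomposition of the outcome
# (between = tau2_y + beta_b^2 tau2_x, within = sigma2_y + beta_w^2 sigma2_x):
# a direct delta-method derivation of Var(tau_yx_hat / tau2_x_hat), checked
# by simulation, requires the total split; the residual split underestimates
# the variance by the structural share of Var(Y). Under Level-1
# standardization Vr = 1. See the methods vignette.
.expansion_terms <- function(pop, n) {
  rho_x <- icc_x(pop)
  rho_y <- icc_y(pop, type = "observed")
  cc <- (1 - rho_x) / (n * rho_x)
  if (pop$beta_b == 0) {
    if (pop$beta_w != 0)
      stop("the expansion involves beta_w/beta_b, undefined for beta_b = 0 ",
           "with beta_w != 0", call. = FALSE)
    r <- 0
  } else {
    r <- pop$beta_w / pop$beta_b
  }
  var_y <- pop$tau2_y + pop$beta_b^2 * pop$tau2_x +
    pop$sigma2_y + pop$beta_w^2 * pop$sigma2_x
  list(
    cc = cc, r = r,
    A = rho_y / rho_x + cc * (rho_y / rho_x + (1 - rho_y) / (1 - rho_x)),
    Vr = var_y / (pop$tau2_x + pop$sigma2_x)
  )
}

.check_accuracy_args <- function(pop, J, n) {
  stopifnot(inherits(pop, "mlc_population"))
  if (!is.numeric(J) || any(J < 2)) stop("'J' must be >= 2", call. = FALSE)
  if (!is.numeric(n) || any(n < 2)) stop("'n' must be >= 2", call. = FALSE)
  invisible(TRUE)
}

#' Population-level shrinkage ratio of the indirect strategy
#'
#' `f = tau2_x / ((1 - w) * tau0_sq + w * tau2_x)`, evaluated at the
#' population variance (the accuracy expansions are population-level).
#' `f = 1` when `w = 1` (flat prior) or when the prior guess equals the
#' population variance; `f < 1` when the prior guess exceeds it
#' (attenuation toward zero).
#'
#' @param pop An `"mlc_population"`.
#' @param prior An `"mlc_indirect_prior"`.
#' @param J Number of groups.
#' @return A positive scalar.
#' @export
f_ratio <- function(pop, prior, J) {
  stopifnot(inherits(pop, "mlc_population"),
            inherits(prior, "mlc_indirect_prior"))
  w <- shrinkage_weight(J, prior$nu0)
  pop$tau2_x / ((1 - w) * prior$tau0_sq + w * pop$tau2_x)
}

#' First-order accuracy approximations for the slope estimators
#'
#' Closed-form Taylor approximations of the bias and sampling variance of
#' the three point estimators of the between-group slope, as functions of
#' the population parameters, the number of groups `J`, the group size `n`,
#' and (for the Bayesian estimators) the prior. Terms of order `1/n^2` and
#' `1/(n^2 (n-1))` are dropped; all biases and variances vanish at rate
#' `1/(J - 1)` as `J` grows (asymptotic unbiasedness). The expansions are
#' rough in design ranges where a group mean is very unreliable (small ICC
#' and small `n`); see the methods vignette.
#'
#' With `c = (1 - rho_x)/(n rho_x)` and `r = beta_w/beta_b`:
#' \itemize{
#'   \item `ml_bias`: `-(2/(J-1)) * (-2c + c(1 + r)) * beta_b`
#'   \item `ml_variance`: `(1/(J-1)) * (A * Vr + (-1 - 2 c r) * beta_b^2)`
#'   \item `direct_bias`: `(1-w) beta0 + (-(1-w) - (2w/(J-1)) (-2c + c(1+r))) beta_b`
#'   \item `direct_variance`: `w^2 *` the ML variance
#'   \item `indirect_bias`: `(f-1) beta_b - (2 w f^2/(J-1)) (-w f (1+2c) + 1 + c(1+r)) beta_b`
#'   \item `indirect_variance`: `(f^2/(J-1)) * (A * Vr + (2wf(wf(1+2c) - 2(1 + c(1+r))) + 1 + 2cr) beta_b^2)`
#' }
#' where `A` and `Vr` are the shared variance bracket and total-variance
#' ratio (see [accuracy_report()] for the assembled bias/variance/MSE/RMSE),
#' `w = J/(nu0 + J)`, and `f` is [f_ratio()]. At `w = 1` (and hence
#' `f = 1`) the direct and indirect expressions reduce exactly to the ML
#' ones.
#'
#' @param pop An `"mlc_population"`. `beta_b = 0` with `beta_w != 0` is an
#'   error (the expansion involves `beta_w / beta_b`).
#' @param J Number of groups (>= 2).
#' @param n Persons per group (>= 2).
#' @param prior An `"mlc_direct_prior"` or `"mlc_indirect_prior"`.
#' @return A single number (bias on the slope scale; variance in squared
#'   slope units).
#' @export
#' @examples
#' pop <- standardized_population(0.1, 0.7, 0.2, 0.15)
#' ml_bias(pop, J = 20, n = 5)
#' ml_variance(pop, J = 20, n = 5)
ml_bias <- function(pop, J, n) {
  .check_accuracy_args(pop, J, n)
  e <- .expansion_terms(pop, n)
  -(2 / (J - 1)) * (-2 * e$cc + e$cc * (1 + e$r)) * pop$beta_b
}

#' @rdname ml_bias
#' @export
ml_variance <- function(pop, J, n) {
  .check_accuracy_args(pop, J, n)
  e <- .expansion_terms(pop, n)
  (1 / (J - 1)) *
    (e$A * e$Vr + (-1 - 2 * e$cc * e$r) * pop$beta_b^2)
}

#' @rdname ml_bias
#' @export
direct_bias <- function(pop, J, n, prior) {
  .check_accuracy_args(pop, J, n)
  stopifnot(inherits(prior, "mlc_direct_prior"))
  e <- .expansion_terms(pop, n)
  w <- shrinkage_weight(J, prior$nu0)
  (1 - w) * prior$beta0 +
    (-(1 - w) - (2 * w / (J - 1)) * (-2 * e$cc + e$cc * (1 + e$r))) *
      pop$beta_b
}

#' @rdname ml_bias
#' @export
direct_variance <- function(pop, J, n, prior) {
  stopifnot(inherits(prior, "mlc_direct_prior"))
  w <- shrinkage_weight(J, prior$nu0)
  w^2 * ml_variance(pop, J, n)
}

#' @rdname ml_bias
#' @export
indirect_bias <- function(pop, J, n, prior) {
  .check_accuracy_args(pop, J, n)
  stopifnot(inherits(prior, "mlc_indirect_prior"))
  e <- .expansion_terms(pop, n)
  w <- shrinkage_weight(J, prior$nu0)
  f <- f_ratio(pop, prior, J)
  (f - 1) * pop$beta_b -
    (2 * w * f^2 / (J - 1)) *
      (-w * f * (1 + 2 * e$cc) + 1 + e$cc * (1 + e$r)) * pop$beta_b
}

#' @rdname ml_bias
#' @export
indirect_variance <- function(pop, J, n, prior) {
  .check_accuracy_args(pop, J, n)
  stopifnot(inherits(prior, "mlc_indirect_prior"))
  e <- .expansion_terms(pop, n)
  w <- shrinkage_weight(J, prior$nu0)
  f <- f_ratio(pop, prior, J)
  slope_term <- 2 * w * f *
    (w * f * (1 + 2 * e$cc) - 2 * (1 + e$cc * (1 + e$r))) +
    1 + 2 * e$cc * e$r
  (f^2 / (J - 1)) * (e$A * e$Vr + slope_term * pop$beta_b^2)
}

#' Analytic accuracy report for one estimator
#'
#' Assembles bias, variance, `mse = bias^2 + variance`, and
#' `rmse = sqrt(mse)` from the matching approximation pair. No analytic
#' form exists for the combined estimator (use the Monte Carlo engine,
#' [run_study()]).
#'
#' @param method One of `"ml"`, `"direct"`, `"indirect"`.
#' @param pop An `"mlc_population"`.
#' @param J,n Design dimensions.
#' @param dprior Direct prior (required for `method = "direct"`).
#' @param iprior Indirect prior (required for `method = "indirect"`).
#' @return An object of class `"accuracy_report"`: a list with `bias`,
#'   `variance`, `mse`, `rmse`, `method`, `source = "analytic"`.
#' @export
#' @examples
#' pop <- standardized_population(0.1, 0.7, 0.2, 0.15)
#' accuracy_report("indirect", pop, J = 20, n = 5,
#'                 iprior = indirect_prior(1, 1))
accuracy_report <- function(method, pop, J, n, dprior = NULL, iprior = NULL) {
  method <- as.character(method)[1]
  if (method == "combined")
    stop("no analytic accuracy form exists for the combined estimator; ",
         "use run_study() for a Monte Carlo report", call. = FALSE)
  if (!method %in% c("ml", "direct", "indirect"))
    stop("'method' must be one of \"ml\", \"direct\", \"indirect\"",
         call. = FALSE)
  bias <- switch(method,
    ml = ml_bias(pop, J, n),
    direct = {
      if (is.null(dprior)) stop("'dprior' required", call. = FALSE)
      direct_bias(pop, J, n, dprior)
    },
    indirect = {
      if (is.null(iprior)) stop("'iprior' required", call. = FALSE)
      indirect_bias(pop, J, n, iprior)
    })
  variance <- switch(method,
    ml = ml_variance(pop, J, n),
    direct = direct_variance(pop, J, n, dprior),
    indirect = indirect_variance(pop, J, n, iprior))
  new_accuracy_report(bias, variance, method, "analytic")
}

new_accuracy_report <- function(bias, variance, method, source) {
  mse <- bias^2 + variance
  structure(list(bias = bias, variance = variance, mse = mse,
                 rmse = sqrt(mse), method = method, source = source),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("Accuracy report (%s, %s)\n", x$method, x$source))
  cat(sprintf("  bias = %.5f  variance = %.5f  mse = %.5f  rmse = %.5f\n",
              x$bias, x$variance, x$mse, x$rmse))
  invisible(x)
}
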