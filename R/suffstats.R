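# ANOVA/method-of-moments variance components from n x J data matrices.
.suffstats_from_matrices <- function(x, y) {
  n <- nrow(x)
  J <- ncol(x)
  xm <- colMeans(x)
  ym <- colMeans(y)
  msb_x <- n * sum((xm - mean(xm))^2) / (J - 1)
  msw_x <- sum(sweep(x, 2, xm)^2) / (J * (n - 1))
  msb_y <- n * sum((ym - mean(ym))^2) / (J - 1)
  msb_xy <- n * sum((xm - mean(xm)) * (ym - mean(ym))) / (J - 1)
  msw_xy <- sum(sweep(x, 2, xm) * sweep(y, 2, ym)) / (J * (n - 1))
  suffstats(
    tau2_x_hat = (msb_x - msw_x) / n,
    tau_yx_hat = (msb_xy - msw_xy) / n,
    tau2_y_hat = (msb_y - sum(sweep(y, 2, ym)^2) / (J * (n - 1))) / n,
    sigma2_x_hat = msw_x,
    J = J, n = n
  )
}

#' Bundle variance-component estimates
#'
#' Low-level constructor for the sufficient statistics consumed by the slope
#' estimators. Usually produced by [compute_suffstats()]; constructing one
#' directly is useful when the variance components are known from elsewhere
#' (e.g., published estimates).
#'
#' @param tau2_x_hat Estimated between-group variance of the predictor. May
#'   be negative (moment estimators can undershoot); downstream estimators
#'   flag or truncate as appropriate.
#' @param tau_yx_hat Estimated between-group covariance of predictor and
#'   outcome.
#' @param tau2_y_hat Estimated between-group variance of the outcome.
#' @param sigma2_x_hat Estimated within-group variance of the predictor
#'   (>= 0).
#' @param J,n Number of groups and persons per group of the source design.
#'
#' @return An object of class `"mlc_suffstats"`.
#' @export
suffstats <- function(tau2_x_hat, tau_yx_hat, tau2_y_hat,
                      sigma2_x_hat = NA_real_, J, n) {
  .check_design(J, n)
  if (!is.na(sigma2_x_hat) && sigma2_x_hat < 0)
    stop("'sigma2_x_hat' must be non-negative", call. = FALSE)
  structure(
    list(tau2_x_hat = tau2_x_hat, tau_yx_hat = tau_yx_hat,
         tau2_y_hat = tau2_y_hat, sigma2_x_hat = sigma2_x_hat,
         J = as.integer(J), n = as.integer(n)),
    class = "mlc_suffstats"
  )
}

#' Sample variance components of a balanced two-level dataset
#'
#' Computes the ANOVA-type (method-of-moments) estimators that all slope
#' estimators consume. With `MSB = n * sum((xbar_j - xbar)^2) / (J - 1)` and
#' `MSW = sum((x_ij - xbar_j)^2) / (J * (n - 1))`, the between-group variance
#' estimate of the predictor is `(MSB - MSW) / n`; the between-group
#' covariance and the between-group variance of the outcome use the analogous
#' cross-product and outcome decompositions. These estimators are closed-form
#' and unbiased for balanced designs. Negative between-variance estimates are
#' retained as-is (see [ml_slope()] for how they are flagged).
#'
#' @param data An `"mlc_dataset"` or data frame with columns `group_id`,
#'   `x`, `y`. The design must be balanced; unbalanced input is an error
#'   naming the offending group.
#'
#' @return An `"mlc_suffstats"` object.
#' @export
#' @examples
#' pop <- standardized_population(0.1, 0.7, 0.2, 0.15)
#' compute_suffstats(simulate_mlc(pop, J = 50, n = 5, seed = 1))
compute_suffstats <- function(data) {
  if (!is.data.frame(data) || !all(c("group_id", "x", "y") %in% names(data)))
    stop("'data' must have columns 'group_id', 'x', 'y'", call. = FALSE)
  counts <- table(data$group_id)
  J <- length(counts)
  if (J < 2) stop("need at least 2 groups", call. = FALSE)
  n <- as.integer(counts[[1]])
  bad <- names(counts)[counts != n]
  if (length(bad) > 0)
    stop("design is unbalanced: group '", bad[1], "' has ", counts[[bad[1]]],
         " rows but group '", names(counts)[1], "' has ", n, call. = FALSE)
  if (n < 2) stop("need at least 2 persons per group", call. = FALSE)
  ord <- order(match(data$group_id, names(counts)))
  x <- matrix(data$x[ord], nrow = n)
  y <- matrix(data$y[ord], nrow = n)
  .suffstats_from_matrices(x, y)
}

#' Admissibility of the between-level covariance estimate
#'
#' `TRUE` when the 2x2 between-level covariance matrix implied by the moment
#' estimates (`tau2_x_hat`, `tau_yx_hat`, `tau2_y_hat`) is positive definite.
#' This is the admissibility condition under which the maximum-likelihood
#' slope is a usable estimate; Monte Carlo studies screen ML replicates on
#' it (see [run_study()]).
#'
#' @param stats An `"mlc_suffstats"`.
#' @return A single logical.
#' @export
is_admissible <- function(stats) {
  stopifnot(inherits(stats, "mlc_suffstats"))
  stats$tau2_x_hat > 0 && stats$tau2_y_hat > 0 &&
    stats$tau2_x_hat * stats$tau2_y_hat - stats$tau_yx_hat^2 > 0
}

#' @export
print.mlc_suffstats <- function(x, ...) {
  cat("Two-level variance components (ANOVA estimators)\n")
  cat(sprintf("  J = %d groups, n = %d per group\n", x$J, x$n))
  cat(sprintf("  tau2_x_hat   = %g%s\n", x$tau2_x_hat,
              if (x$tau2_x_hat <= 0) "  [non-positive]" else ""))
  cat(sprintf("  tau_yx_hat   = %g\n", x$tau_yx_hat))
  cat(sprintf("  tau2_y_hat   = %g\n", x$tau2_y_hat))
  cat(sprintf("  sigma2_x_hat = %g\n", x$sigma2_x_hat))
  invisible(x)
}
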