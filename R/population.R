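#' Population parameters of the multilevel latent covariate model
#'
#' Defines the generating model for balanced two-level data. The
#' individual-level predictor splits into a latent group mean and an
#' individual deviation, `X_ij = X_b,j + X_w,ij`, with
#' `X_b,j ~ N(mu_x, tau2_x)` and `X_w,ij ~ N(0, sigma2_x)`. The outcome
#' follows the two-level regression
#' `Y_ij = alpha + beta_b * X_b,j + delta_j + beta_w * X_w,ij + eps_ij`,
#' with group-level residuals `delta_j ~ N(0, tau2_y)` and individual-level
#' residuals `eps_ij ~ N(0, sigma2_y)`, all components mutually independent.
#'
#' @param beta_b Between-group slope: regression of the group-level part of
#'   the outcome on the latent group mean of the predictor.
#' @param beta_w Within-group slope.
#' @param alpha Overall intercept.
#' @param mu_x Grand mean of the predictor.
#' @param tau2_x Between-group variance of the predictor (> 0).
#' @param sigma2_x Within-group variance of the predictor (> 0).
#' @param tau2_y Group-level residual variance of the outcome (> 0).
#' @param sigma2_y Individual-level residual variance of the outcome (> 0).
#'
#' @return An object of class `"mlc_population"`: a list of the eight
#'   parameters above.
#' @seealso [standardized_population()], [icc_x()], [simulate_mlc()]
#' @export
#' @examples
#' pop <- mlc_population(beta_b = 0.7, beta_w = 0.2, alpha = 0, mu_x = 0,
#'                       tau2_x = 0.1, sigma2_x = 0.9,
#'                       tau2_y = 0.15, sigma2_y = 0.765)
#' icc_x(pop)
mlc_population <- function(beta_b, beta_w, alpha = 0, mu_x = 0,
                           tau2_x, sigma2_x, tau2_y, sigma2_y) {
  for (nm in c("beta_b", "beta_w", "alpha", "mu_x",
               "tau2_x", "sigma2_x", "tau2_y", "sigma2_y")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  for (nm in c("tau2_x", "sigma2_x", "tau2_y", "sigma2_y")) {
    if (get(nm) <= 0)
      stop("'", nm, "' must be strictly positive (got ", get(nm), ")",
           call. = FALSE)
  }
  structure(
    list(beta_b = beta_b, beta_w = beta_w, alpha = alpha, mu_x = mu_x,
         tau2_x = tau2_x, sigma2_x = sigma2_x,
         tau2_y = tau2_y, sigma2_y = sigma2_y),
    class = "mlc_population"
  )
}

#' Standardized population (unit total variance at Level 1)
#'
#' Constructs a population in which predictor and outcome each have unit
#' total variance, the convention used throughout the accuracy studies:
#' `tau2_x = icc_x`, `sigma2_x = 1 - icc_x`, `mu_x = alpha = 0`, and the
#' individual-level residual variance absorbs what the structural parts do
#' not explain, `sigma2_y = 1 - beta_b^2 * tau2_x - tau2_y -
#' beta_w^2 * sigma2_x`.
#'
#' @param icc_x Intraclass correlation of the predictor, in (0, 1).
#' @param beta_b,beta_w Between- and within-group slopes.
#' @param tau2_y Group-level residual variance of the outcome.
#'
#' @return An `"mlc_population"` with `Var(X) = Var(Y) = 1`.
#' @export
#' @examples
#' standardized_population(icc_x = 0.1, beta_b = 0.7, beta_w = 0.2,
#'                         tau2_y = 0.15)
standardized_population <- function(icc_x, beta_b, beta_w, tau2_y) {
  if (!is.numeric(icc_x) || length(icc_x) != 1L || icc_x <= 0 || icc_x >= 1)
    stop("'icc_x' must lie strictly between 0 and 1", call. = FALSE)
  tau2_x <- icc_x
  sigma2_x <- 1 - icc_x
  sigma2_y <- 1 - beta_b^2 * tau2_x - tau2_y - beta_w^2 * sigma2_x
  if (!is.finite(sigma2_y) || sigma2_y <= 0)
    stop("parameter combination incompatible with unit total variance of Y ",
         "(implied sigma2_y = ", signif(sigma2_y, 4), " <= 0)", call. = FALSE)
  mlc_population(beta_b = beta_b, beta_w = beta_w, alpha = 0, mu_x = 0,
                 tau2_x = tau2_x, sigma2_x = sigma2_x,
                 tau2_y = tau2_y, sigma2_y = sigma2_y)
}

#' Intraclass correlations implied by a population
#'
#' `icc_x()` is the predictor ICC `tau2_x / (tau2_x + sigma2_x)`. `icc_y()`
#' is, by default, the ICC of the observed outcome, whose between-group
#' variance is `tau2_y + beta_b^2 * tau2_x` and whose within-group variance
#' is `sigma2_y + beta_w^2 * sigma2_x`; with `type = "residual"` it is the
#' residual-based ratio `tau2_y / (tau2_y + sigma2_y)`.
#'
#' @param pop An `"mlc_population"`.
#' @param type For `icc_y()`: `"observed"` (default) or `"residual"`.
#' @return A proportion in (0, 1).
#' @export
icc_x <- function(pop) {
  stopifnot(inherits(pop, "mlc_population"))
  pop$tau2_x / (pop$tau2_x + pop$sigma2_x)
}

#' @rdname icc_x
#' @export
icc_y <- function(pop, type = c("observed", "residual")) {
  stopifnot(inherits(pop, "mlc_population"))
  type <- match.arg(type)
  if (type == "residual") {
    pop$tau2_y / (pop$tau2_y + pop$sigma2_y)
  } else {
    b <- pop$tau2_y + pop$beta_b^2 * pop$tau2_x
    w <- pop$sigma2_y + pop$beta_w^2 * pop$sigma2_x
    b / (b + w)
  }
}

#' @export
print.mlc_population <- function(x, ...) {
  cat("Multilevel latent covariate population\n")
  cat(sprintf("  slopes:     beta_b = %g, beta_w = %g\n", x$beta_b, x$beta_w))
  cat(sprintf("  location:   alpha = %g, mu_x = %g\n", x$alpha, x$mu_x))
  cat(sprintf("  X variance: tau2_x = %g, sigma2_x = %g (ICC = %.3f)\n",
              x$tau2_x, x$sigma2_x, icc_x(x)))
  cat(sprintf("  Y residual: tau2_y = %g, sigma2_y = %g (observed ICC = %.3f)\n",
              x$tau2_y, x$sigma2_y, icc_y(x)))
  invisible(x)
}
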