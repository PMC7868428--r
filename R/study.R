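#' Describe one estimator for a Monte Carlo study
#'
#' @param method One of `"ml"`, `"direct"`, `"indirect"`, `"combined"`, or
#'   `"constant"` (a fixed value, useful as an oracle in tests; supply it
#'   via `value`).
#' @param label Unique label identifying the estimator in results.
#' @param dprior Direct prior (for `"direct"` and `"combined"`).
#' @param iprior Indirect prior (for `"indirect"` and `"combined"`).
#' @param value Fixed value (for `"constant"`).
#' @param exclude Replicate-exclusion policy: `"admissible"` drops
#'   replicates whose between-level covariance estimate is not positive
#'   definite (the default for `"ml"` and `"direct"`, whose estimates are
#'   otherwise not usable slopes); `"error"` drops only replicates on which
#'   the estimator itself fails (the default for `"indirect"` and
#'   `"combined"`, whose stabilized denominators keep them finite);
#'   `"none"` never drops (only sensible for `"constant"`).
#' @return An object of class `"estimator_spec"`.
#' @export
#' @examples
#' estimator_spec("indirect", "indirect-incorrect",
#'                iprior = indirect_prior(1, 1))
estimator_spec <- function(method = c("ml", "direct", "indirect",
                                      "combined", "constant"),
                           label = method, dprior = NULL, iprior = NULL,
                           value = NULL,
                           exclude = NULL) {
  method <- match.arg(method)
  if (method %in% c("direct", "combined") &&
      !inherits(dprior, "mlc_direct_prior"))
    stop("method '", method, "' needs a 'dprior'", call. = FALSE)
  if (method %in% c("indirect", "combined") &&
      !inherits(iprior, "mlc_indirect_prior"))
    stop("method '", method, "' needs an 'iprior'", call. = FALSE)
  if (method == "constant" && (!is.numeric(value) || length(value) != 1L))
    stop("method 'constant' needs a single numeric 'value'", call. = FALSE)
  if (is.null(exclude))
    exclude <- switch(method,
                      ml = "admissible", direct = "admissible",
                      indirect = "error", combined = "error",
                      constant = "none")
  exclude <- match.arg(exclude, c("admissible", "error", "none"))
  structure(list(method = method, label = label, dprior = dprior,
                 iprior = iprior, value = value, exclude = exclude),
            class = "estimator_spec")
}

# Evaluate one estimator spec on one replicate's sufficient statistics.
# Returns NA_real_ when the replicate is excluded under the spec's policy.
.apply_spec <- function(spec, stats) {
  if (spec$method == "constant") return(spec$value)
  if (spec$exclude == "admissible" && !is_admissible(stats)) return(NA_real_)
  out <- tryCatch(
    switch(spec$method,
      ml = ml_slope(stats)$value,
      direct = direct_eap(stats, spec$dprior)$value,
      indirect = indirect_slope(stats, spec$iprior)$value,
      combined = combined_slope(stats, spec$dprior, spec$iprior)$value),
    error = function(e) NA_real_)
  out
}

#' Configure a Monte Carlo accuracy study
#'
#' @param pop An `"mlc_population"`.
#' @param n Persons per group.
#' @param J_grid Ascending vector of group counts.
#' @param reps Replications per cell (>= 2 for variance estimation;
#'   `reps = 1` yields bias only).
#' @param seed Base seed. Per-replicate streams are derived by fixed
#'   increments (`seed + 100000 * cell + replicate`) so any replicate is
#'   independently reproducible.
#' @param specs List of [estimator_spec()] objects with unique labels.
#' @return An object of class `"study_config"`.
#' @export
study_config <- function(pop, n, J_grid, reps, seed, specs) {
  stopifnot(inherits(pop, "mlc_population"))
  if (length(J_grid) < 1 || is.unsorted(J_grid, strictly = TRUE))
    stop("'J_grid' must be non-empty and strictly ascending", call. = FALSE)
  if (!is.numeric(reps) || reps < 1)
    stop("'reps' must be >= 1", call. = FALSE)
  if (!all(vapply(specs, inherits, logical(1), "estimator_spec")))
    stop("'specs' must be a list of estimator_spec objects", call. = FALSE)
  labels <- vapply(specs, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("estimator labels must be unique", call. = FALSE)
  structure(list(pop = pop, n = n, J_grid = J_grid, reps = as.integer(reps),
                 seed = as.integer(seed), specs = specs),
            class = "study_config")
}

#' Run a Monte Carlo accuracy study
#'
#' For each cell (value of `J`), simulates `reps` datasets from the
#' population and applies every estimator spec to the *same* datasets
#' (common random numbers), then aggregates per estimator:
#' `bias = mean(estimate) - beta_b`, `variance` is the `(reps - 1)`-divisor
#' variance of the estimates, `mse = bias^2 + variance`,
#' `rmse = sqrt(mse)`, with a delta-method Monte Carlo standard error for
#' the RMSE. Replicates excluded under a spec's policy (inadmissible
#' between-level covariance for ML-type estimators, estimator failure
#' otherwise) are dropped from that spec's aggregation and counted; a cell
#' excluding more than 5% is flagged.
#'
#' @param config A [study_config()].
#' @param keep_estimates Keep the per-replicate estimate matrices (needed by
#'   [rmse_difference()] for paired comparisons). Default `TRUE`.
#' @return An object of class `"mlc_study"`: a list with `results` (a long
#'   data frame: `label`, `J`, `method`, `source`, `bias`, `variance`,
#'   `mse`, `rmse`, `rmse_se`, `reps`, `included`, `excluded`, `flagged`),
#'   the `config`, and (optionally) `estimates`, a list (one `reps x specs`
#'   matrix per `J`).
#' @export
#' @examples
#' pop <- standardized_population(0.1, 0.7, 0.2, 0.15)
#' cfg <- study_config(pop, n = 5, J_grid = 20, reps = 200, seed = 1,
#'                     specs = list(estimator_spec("ml"),
#'                                  estimator_spec("indirect",
#'                                    iprior = indirect_prior(1, 1))))
#' run_study(cfg)
run_study <- function(config, keep_estimates = TRUE) {
  stopifnot(inherits(config, "study_config"))
  pop <- config$pop
  beta_b <- pop$beta_b
  labels <- vapply(config$specs, `[[`, character(1), "label")
  rows <- list()
  estimates <- list()
  for (ci in seq_along(config$J_grid)) {
    J <- config$J_grid[ci]
    est <- matrix(NA_real_, nrow = config$reps, ncol = length(config$specs),
                  dimnames = list(NULL, labels))
    for (r in seq_len(config$reps)) {
      set.seed(config$seed + 100000L * ci + r)
      m <- .draw_mlc(pop, J, config$n)
      stats <- .suffstats_from_matrices(m$x, m$y)
      for (si in seq_along(config$specs))
        est[r, si] <- .apply_spec(config$specs[[si]], stats)
    }
    estimates[[as.character(J)]] <- est
    for (si in seq_along(config$specs)) {
      e <- est[, si]
      keep <- !is.na(e)
      e <- e[keep]
      m_inc <- length(e)
      bias <- mean(e) - beta_b
      if (m_inc >= 2) {
        variance <- stats::var(e)
        mse <- bias^2 + variance
        rmse <- sqrt(mse)
        rmse_se <- if (rmse > 0)
          stats::sd((e - beta_b)^2) / (2 * rmse * sqrt(m_inc))
        else 0
      } else {
        variance <- NA_real_
        mse <- NA_real_
        rmse <- NA_real_
        rmse_se <- NA_real_
      }
      excl <- config$reps - m_inc
      rows[[length(rows) + 1L]] <- data.frame(
        label = labels[si], J = J, method = config$specs[[si]]$method,
        source = "monte_carlo", bias = bias, variance = variance,
        mse = mse, rmse = rmse, rmse_se = rmse_se,
        reps = config$reps, included = m_inc, excluded = excl,
        flagged = excl > 0.05 * config$reps)
    }
  }
  structure(list(results = do.call(rbind, rows), config = config,
                 estimates = if (keep_estimates) estimates else NULL),
            class = "mlc_study")
}

#' Paired RMSE comparison of two estimators in a study cell
#'
#' Because a study applies all estimators to the same simulated datasets,
#' two estimators are compared on their common included replicates, and the
#' Monte Carlo uncertainty of the comparison is the standard error of the
#' *paired* squared-error difference — much smaller than combining two
#' independent RMSE standard errors when the estimators are correlated.
#'
#' @param study An `"mlc_study"` run with `keep_estimates = TRUE`.
#' @param label_a,label_b Estimator labels; positive `diff` means `a` has
#'   the larger RMSE.
#' @param J Cell to compare in.
#' @return A list: `rmse_a`, `rmse_b` (on the common replicate set),
#'   `diff` (rmse_a - rmse_b), `mse_diff`, `mse_diff_se` (paired SE),
#'   `z` (mse_diff / mse_diff_se), `n_common`.
#' @export
rmse_difference <- function(study, label_a, label_b, J) {
  stopifnot(inherits(study, "mlc_study"))
  if (is.null(study$estimates))
    stop("study was run with keep_estimates = FALSE", call. = FALSE)
  est <- study$estimates[[as.character(J)]]
  if (is.null(est)) stop("no cell with J = ", J, call. = FALSE)
  for (lab in c(label_a, label_b))
    if (!lab %in% colnames(est))
      stop("no estimator labelled '", lab, "'", call. = FALSE)
  beta_b <- study$config$pop$beta_b
  keep <- !is.na(est[, label_a]) & !is.na(est[, label_b])
  a <- est[keep, label_a]
  b <- est[keep, label_b]
  sq_a <- (a - beta_b)^2
  sq_b <- (b - beta_b)^2
  d <- sq_a - sq_b
  list(rmse_a = sqrt(mean(sq_a)), rmse_b = sqrt(mean(sq_b)),
       diff = sqrt(mean(sq_a)) - sqrt(mean(sq_b)),
       mse_diff = mean(d),
       mse_diff_se = stats::sd(d) / sqrt(length(d)),
       z = mean(d) / (stats::sd(d) / sqrt(length(d))),
       n_common = length(d))
}

#' @export
print.mlc_study <- function(x, ...) {
  cat(sprintf("Monte Carlo accuracy study: %d cell(s) x %d estimator(s), %d reps\n",
              length(x$config$J_grid), length(x$config$specs),
              x$config$reps))
  print(x$results, row.names = FALSE, digits = 4)
  invisible(x)
}

# Default study population: standardized variables, between-group slope 0.7,
# predictor ICC 0.1, within-group slope 0.2, group-level residual variance
# 0.15 of the outcome.
default_population <- function() {
  standardized_population(icc_x = 0.1, beta_b = 0.7, beta_w = 0.2,
                          tau2_y = 0.15)
}

#' Comparative RMSE study of the five single-prior estimators
#'
#' Evaluates, over a grid of group counts, the ML estimator and four
#' Bayesian estimators — direct with a correct prior guess
#' (`beta0 = beta_b`), direct with an incorrect guess (`beta0 = 0`),
#' indirect with a correct guess (`tau0_sq = tau2_x`), and indirect with an
#' incorrect guess (`tau0_sq = 1`, the standardization upper bound) — both
#' analytically (first-order approximations) and by Monte Carlo on common
#' random numbers.
#'
#' @param nu0 Prior sample size shared by all four priors.
#' @param pop Population; defaults to standardized variables with
#'   `beta_b = 0.7`, predictor ICC 0.1, `beta_w = 0.2`, `tau2_y = 0.15`.
#' @param n Persons per group (default 5).
#' @param J_grid Group counts (default 20 to 60 in steps of 10).
#' @param reps Monte Carlo replications per cell (default 20000).
#' @param seed Base seed.
#' @return A list of class `"mlc_figure_study"`: `mc` (the `"mlc_study"`),
#'   `analytic` (long data frame of analytic reports per label and `J`),
#'   `nu0`, and `labels`.
#' @export
figure1_study <- function(nu0 = 1, pop = default_population(), n = 5,
                          J_grid = seq(20, 60, by = 10), reps = 20000,
                          seed = 1) {
  d_cor <- direct_prior(beta0 = pop$beta_b, nu0 = nu0)
  d_inc <- direct_prior(beta0 = 0, nu0 = nu0)
  i_cor <- indirect_prior(tau0_sq = pop$tau2_x, nu0 = nu0)
  i_inc <- indirect_prior(tau0_sq = 1, nu0 = nu0)
  specs <- list(
    estimator_spec("ml", "ml"),
    estimator_spec("direct", "direct-correct", dprior = d_cor),
    estimator_spec("direct", "direct-incorrect", dprior = d_inc),
    estimator_spec("indirect", "indirect-correct", iprior = i_cor),
    estimator_spec("indirect", "indirect-incorrect", iprior = i_inc))
  mc <- run_study(study_config(pop, n, J_grid, reps, seed, specs))
  arows <- list()
  for (J in J_grid) {
    reports <- list(
      `ml` = accuracy_report("ml", pop, J, n),
      `direct-correct` = accuracy_report("direct", pop, J, n, dprior = d_cor),
      `direct-incorrect` = accuracy_report("direct", pop, J, n,
                                           dprior = d_inc),
      `indirect-correct` = accuracy_report("indirect", pop, J, n,
                                           iprior = i_cor),
      `indirect-incorrect` = accuracy_report("indirect", pop, J, n,
                                             iprior = i_inc))
    for (lab in names(reports)) {
      rp <- reports[[lab]]
      arows[[length(arows) + 1L]] <- data.frame(
        label = lab, J = J, method = rp$method, source = "analytic",
        bias = rp$bias, variance = rp$variance, mse = rp$mse,
        rmse = rp$rmse)
    }
  }
  structure(list(mc = mc, analytic = do.call(rbind, arows), nu0 = nu0,
                 labels = vapply(specs, `[[`, character(1), "label")),
            class = "mlc_figure_study")
}

#' Monte Carlo study of the combined estimator
#'
#' Evaluates ML plus the four combined estimators that cross a correct or
#' incorrect direct prior guess (`beta0` equal to `beta_b` or 0) with a
#' correct or incorrect indirect prior guess (`tau0_sq` equal to `tau2_x`
#' or 1). Monte Carlo only: no analytic accuracy form exists for the
#' combined estimator.
#'
#' @inheritParams figure1_study
#' @return An `"mlc_figure_study"` (with an empty `analytic` component).
#' @export
figure2_study <- function(nu0 = 1, pop = default_population(), n = 5,
                          J_grid = seq(20, 60, by = 10), reps = 20000,
                          seed = 1) {
  d_cor <- direct_prior(beta0 = pop$beta_b, nu0 = nu0)
  d_inc <- direct_prior(beta0 = 0, nu0 = nu0)
  i_cor <- indirect_prior(tau0_sq = pop$tau2_x, nu0 = nu0)
  i_inc <- indirect_prior(tau0_sq = 1, nu0 = nu0)
  specs <- list(
    estimator_spec("ml", "ml"),
    estimator_spec("combined", "correct/correct", dprior = d_cor,
                   iprior = i_cor),
    estimator_spec("combined", "correct/incorrect", dprior = d_cor,
                   iprior = i_inc),
    estimator_spec("combined", "incorrect/correct", dprior = d_inc,
                   iprior = i_cor),
    estimator_spec("combined", "incorrect/incorrect", dprior = d_inc,
                   iprior = i_inc))
  mc <- run_study(study_config(pop, n, J_grid, reps, seed, specs))
  structure(list(mc = mc, analytic = NULL, nu0 = nu0,
                 labels = vapply(specs, `[[`, character(1), "label")),
            class = "mlc_figure_study")
}

#' @export
print.mlc_figure_study <- function(x, ...) {
  cat(sprintf("Comparative RMSE study (nu0 = %g)\n", x$nu0))
  print(x$mc)
  if (!is.null(x$analytic)) {
    cat("Analytic overlay:\n")
    print(x$analytic, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Write study results to a long-format CSV
#'
#' Columns: `label`, `J`, `nu0`, `source`, `bias`, `variance`, `mse`,
#' `rmse`, `rmse_se`, `reps`, `excluded`.
#'
#' @param study An `"mlc_study"` or `"mlc_figure_study"`.
#' @param path Output file.
#' @param nu0 Prior sample size recorded in the file (taken from a figure
#'   study automatically).
#' @return Invisibly, the written data frame.
#' @export
write_study_results <- function(study, path, nu0 = NA_real_) {
  if (inherits(study, "mlc_figure_study")) {
    nu0 <- study$nu0
    mc <- study$mc$results
    res <- mc[, c("label", "J", "source", "bias", "variance", "mse", "rmse",
                  "rmse_se", "reps", "excluded")]
    if (!is.null(study$analytic)) {
      an <- study$analytic
      an$rmse_se <- NA_real_
      an$reps <- NA_integer_
      an$excluded <- NA_integer_
      res <- rbind(res, an[, names(res)])
    }
  } else {
    stopifnot(inherits(study, "mlc_study"))
    res <- study$results[, c("label", "J", "source", "bias", "variance",
                             "mse", "rmse", "rmse_se", "reps", "excluded")]
  }
  res <- cbind(res[, c("label", "J")], nu0 = nu0,
               res[, setdiff(names(res), c("label", "J"))])
  utils::write.csv(res, path, row.names = FALSE)
  invisible(res)
}

#' Plot RMSE against the number of groups
#'
#' One line per estimator; Monte Carlo results solid, the analytic overlay
#' (when present) dashed. Facet over multiple studies (e.g., different
#' `nu0` values) by passing a named list.
#'
#' @param studies A single `"mlc_figure_study"` or a named list of them
#'   (names used as panel labels).
#' @return A `ggplot` object.
#' @export
plot_study <- function(studies) {
  if (inherits(studies, "mlc_figure_study")) studies <- list(studies)
  if (is.null(names(studies)))
    names(studies) <- vapply(studies,
                             function(s) sprintf("nu0 = %g", s$nu0),
                             character(1))
  frames <- lapply(names(studies), function(nm) {
    s <- studies[[nm]]
    mc <- s$mc$results[, c("label", "J", "source", "rmse")]
    if (!is.null(s$analytic))
      mc <- rbind(mc, s$analytic[, c("label", "J", "source", "rmse")])
    mc$panel <- nm
    mc
  })
  df <- do.call(rbind, frames)
  ggplot2::ggplot(df, ggplot2::aes(x = J, y = rmse, colour = label,
                                   linetype = source)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = "number of groups (J)", y = "RMSE",
                  colour = "estimator", linetype = "source") +
    ggplot2::theme_minimal()
}
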