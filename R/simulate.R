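# Random draws for one balanced dataset, as n x J matrices (column = group).
# Draw order is fixed (group-level first, then individual-level) so that a
# given seed always yields the same dataset regardless of the consumer.
.draw_mlc <- function(pop, J, n) {
  x_b <- stats::rnorm(J, pop$mu_x, sqrt(pop$tau2_x))
  delta <- stats::rnorm(J, 0, sqrt(pop$tau2_y))
  x_w <- matrix(stats::rnorm(J * n, 0, sqrt(pop$sigma2_x)), nrow = n)
  eps <- matrix(stats::rnorm(J * n, 0, sqrt(pop$sigma2_y)), nrow = n)
  x <- sweep(x_w, 2, x_b, "+")
  y <- sweep(pop$beta_w * x_w + eps, 2,
             pop$alpha + pop$beta_b * x_b + delta, "+")
  list(x = x, y = y)
}

#' Simulate a balanced two-level dataset
#'
#' Draws one dataset of `J` groups with `n` persons each from a multilevel
#' latent covariate population: latent group means, group-level residuals,
#' individual deviations, and individual residuals are independent normal
#' draws, combined per the two-level regression (see [mlc_population()]).
#'
#' @param pop An `"mlc_population"`.
#' @param J Number of groups (>= 2).
#' @param n Persons per group (>= 2).
#' @param seed Optional integer seed; for a fixed seed the dataset is
#'   bit-reproducible.
#'
#' @return A `data.frame` of class `"mlc_dataset"` with `J * n` rows and
#'   columns `group_id` (consecutive integers from 1), `x`, `y`.
#' @export
#' @examples
#' pop <- standardized_population(0.1, 0.7, 0.2, 0.15)
#' d <- simulate_mlc(pop, J = 20, n = 5, seed = 1)
#' head(d)
simulate_mlc <- function(pop, J, n, seed = NULL) {
  stopifnot(inherits(pop, "mlc_population"))
  .check_design(J, n)
  if (!is.null(seed)) set.seed(seed)
  m <- .draw_mlc(pop, J, n)
  out <- data.frame(
    group_id = rep.int(seq_len(J), rep.int(n, J)),
    x = as.vector(m$x),
    y = as.vector(m$y)
  )
  class(out) <- c("mlc_dataset", "data.frame")
  out
}

.check_design <- function(J, n) {
  if (!is.numeric(J) || length(J) != 1L || J < 2 || J != round(J))
    stop("'J' must be an integer >= 2", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n))
    stop("'n' must be an integer >= 2", call. = FALSE)
  invisible(TRUE)
}

#' Read or write a two-level dataset as delimited text
#'
#' The on-disk dialect is a headered CSV with columns `group_id,x,y`;
#' group ids are consecutive integers starting at 1.
#'
#' @param data An `"mlc_dataset"` (or compatible data frame).
#' @param path File path.
#' @return `read_mlc_data()` returns an `"mlc_dataset"`;
#'   `write_mlc_data()` invisibly returns `path`.
#' @export
write_mlc_data <- function(data, path) {
  stopifnot(is.data.frame(data))
  if (!all(c("group_id", "x", "y") %in% names(data)))
    stop("dataset must have columns 'group_id', 'x', 'y'", call. = FALSE)
  utils::write.csv(data[, c("group_id", "x", "y")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mlc_data
#' @export
read_mlc_data <- function(path) {
  d <- utils::read.csv(path)
  missing <- setdiff(c("group_id", "x", "y"), names(d))
  if (length(missing) > 0)
    stop("dataset file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  d <- d[, c("group_id", "x", "y")]
  class(d) <- c("mlc_dataset", "data.frame")
  d
}
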