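# Shared fixtures, all generated in code.

# Study-condition population: standardized variables, beta_b = 0.7,
# predictor ICC 0.1, beta_w = 0.2, group-level residual variance 0.15.
default_pop <- function() {
  standardized_population(icc_x = 0.1, beta_b = 0.7, beta_w = 0.2,
                          tau2_y = 0.15)
}

# Balanced dataset with *exact* between-group variance components and zero
# within-group variance: every group's members share the group mean, and
# group means are a standardized sequence rescaled to hit the targets.
# Yields tau2_x_hat = t2x, tau2_y_hat = t2y, tau_yx_hat = sqrt(t2x * t2y)
# exactly.
crafted_dataset <- function(J = 20, n = 5, t2x = 0.1, t2y = 0.15) {
  z <- seq_len(J)
  z <- (z - mean(z)) / stats::sd(z)
  d <- data.frame(
    group_id = rep(seq_len(J), each = n),
    x = rep(sqrt(t2x) * z, each = n),
    y = rep(sqrt(t2y) * z, each = n)
  )
  class(d) <- c("mlc_dataset", "data.frame")
  d
}

# Sufficient statistics matching the worked prior-translation example.
worked_stats <- function(J = 20, n = 5) {
  suffstats(tau2_x_hat = 0.1, tau_yx_hat = 0.07, tau2_y_hat = 0.15,
            sigma2_x_hat = 0.9, J = J, n = n)
}

# Small pool of simulated sufficient statistics under the default
# population (fixed seeds), for property-style loops.
simulated_stats_pool <- function(k = 100, J = 20, n = 5, seed0 = 2000) {
  lapply(seq_len(k), function(i)
    compute_suffstats(simulate_mlc(default_pop(), J, n, seed = seed0 + i)))
}
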