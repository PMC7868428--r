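# Random but reproducible grid of populations/designs on which the
# flat-prior reductions must hold identically.
param_grid <- function(k = 50, seed = 400) {
  set.seed(seed)
  lapply(seq_len(k), function(i) {
    repeat {
      icc <- runif(1, 0.05, 0.6)
      bb <- runif(1, 0.1, 0.9)
      bw <- runif(1, -0.4, 0.4)
      t2y <- runif(1, 0.05, 0.4)
      pop <- tryCatch(standardized_population(icc, bb, bw, t2y),
                      error = function(e) NULL)
      if (!is.null(pop)) break
    }
    list(pop = pop, J = sample(5:80, 1), n = sample(2:30, 1))
  })
}

test_that("ML bias formula evaluates as printed", {
  pop <- default_pop()
  # hand evaluation: c = (1-0.1)/(5*0.1) = 1.8;
  # -(2/20) * (-2*1.8 + 1.8*(1 + 0.2/0.7)) * 0.7 = 0.09
  expect_equal(ml_bias(pop, J = 21, n = 5), 0.09)
  # vanishing unreliability: perfectly reliable group means, no bias
  reliable <- standardized_population(1 - 1e-9, 0.7, 0.2, 0.15)
  expect_lt(abs(ml_bias(reliable, 21, 5)), 1e-8)
  # beta_w/beta_b undefined when only the between-slope is zero
  flat_b <- mlc_population(beta_b = 0, beta_w = 0.2, tau2_x = 0.1,
                           sigma2_x = 0.9, tau2_y = 0.15, sigma2_y = 0.765)
  expect_error(ml_bias(flat_b, 21, 5), "beta_w/beta_b")
  # but fine when both slopes are zero (ratio conventionally 0)
  null_pop <- standardized_population(0.5, 0, 0, 0.5)
  expect_equal(ml_bias(null_pop, 21, 5), 0)
})

test_that("flat-prior reductions hold to machine precision on a grid", {
  flat_d <- direct_prior(beta0 = 0.3, nu0 = 0)
  near <- function(a, b) expect_lt(abs(a - b), 1e-14 + 1e-10 * abs(b))
  for (g in param_grid()) {
    pop <- g$pop
    flat_i <- indirect_prior(tau0_sq = runif(1, 0.05, 1), nu0 = 0)
    near(direct_bias(pop, g$J, g$n, flat_d), ml_bias(pop, g$J, g$n))
    near(direct_variance(pop, g$J, g$n, flat_d), ml_variance(pop, g$J, g$n))
    near(indirect_bias(pop, g$J, g$n, flat_i), ml_bias(pop, g$J, g$n))
    # the indirect variance at w = f = 1 is algebraically identical to the
    # ML variance: its slope bracket 2wf(wf(1+2c) - 2(1+c(1+r))) + 1 + 2cr
    # collapses to -1 - 2cr
    near(indirect_variance(pop, g$J, g$n, flat_i), ml_variance(pop, g$J, g$n))
  }
})

test_that("a correct variance guess kills the leading indirect bias", {
  pop <- default_pop()
  correct <- indirect_prior(tau0_sq = pop$tau2_x, nu0 = 3)
  expect_equal(f_ratio(pop, correct, J = 20), 1)
  # with f = 1 only the 1/(J-1) term remains
  lead <- (f_ratio(pop, correct, 20) - 1) * pop$beta_b
  expect_equal(lead, 0)
  # over-guessing attenuates: f < 1 and the leading term is negative
  over <- indirect_prior(tau0_sq = 1, nu0 = 1)
  f <- f_ratio(pop, over, J = 20)
  expect_lt(f, 1)
  expect_lt((f - 1) * pop$beta_b, 0)
})

test_that("direct-prior limiting biases behave as expected", {
  pop <- default_pop()
  # large nu0 with a correct guess: bias cancels to the 1/(J-1) remnant
  strong_correct <- direct_prior(beta0 = pop$beta_b, nu0 = 1e8)
  b <- direct_bias(pop, 20, 5, strong_correct)
  expect_lt(abs(b), 1e-6)
  # variance ratio to ML is exactly w^2
  for (nu0 in c(0.1, 1, 5)) {
    w <- shrinkage_weight(20, nu0)
    expect_equal(direct_variance(pop, 20, 5, direct_prior(0, nu0)) /
                   ml_variance(pop, 20, 5), w^2)
  }
})

test_that("accuracy vanishes at rate 1/(J-1)", {
  pop <- default_pop()
  dp <- direct_prior(0, 1)
  ip <- indirect_prior(1, 1)
  Js <- c(100, 1000, 10000)
  bias_ml <- sapply(Js, function(J) ml_bias(pop, J, 5))
  var_ml <- sapply(Js, function(J) ml_variance(pop, J, 5))
  expect_equal(bias_ml * (Js - 1), rep(bias_ml[1] * 99, 3))
  expect_equal(var_ml * (Js - 1), rep(var_ml[1] * 99, 3))
  # Bayesian estimators: rate 1/(J-1) up to the w, f factors that tend to 1
  b_dir <- sapply(Js, function(J) direct_bias(pop, J, 5, dp))
  b_ind <- sapply(Js, function(J) indirect_bias(pop, J, 5, ip))
  expect_lt(abs(b_dir[3]), abs(b_dir[1]) / 50)
  expect_lt(abs(b_ind[3]), abs(b_ind[1]) / 50)
  # exact 1/(J-1) proportionality of the ML variance
  expect_equal(ml_variance(pop, 41, 5), ml_variance(pop, 21, 5) * 20 / 40)
})

test_that("accuracy reports assemble MSE and RMSE correctly", {
  rp <- mlcprior:::new_accuracy_report(bias = 0.3, variance = 0.16,
                                       method = "ml", source = "analytic")
  expect_equal(rp$mse, 0.25)
  expect_equal(rp$rmse, 0.5)
  pop <- default_pop()
  for (m in c("ml", "direct", "indirect")) {
    rp <- accuracy_report(m, pop, 20, 5, dprior = direct_prior(0, 1),
                          iprior = indirect_prior(1, 1))
    expect_gte(rp$rmse, abs(rp$bias))
    expect_gte(rp$rmse, sqrt(rp$variance))
    expect_equal(rp$mse, rp$bias^2 + rp$variance)
  }
  # more groups, better accuracy
  expect_gt(accuracy_report("ml", pop, 20, 5)$rmse,
            accuracy_report("ml", pop, 60, 5)$rmse)
  expect_error(accuracy_report("combined", pop, 20, 5), "combined")
})

test_that("approximations match simulation where the expansion is accurate", {
  # In a benign regime (large J, large n, mid ICC) the dropped higher-order
  # terms are small, so the closed forms must track an independent Monte
  # Carlo: bias within 3 MC standard errors, RMSE within 15% (the residual
  # O(c^2) terms).
  pop <- standardized_population(icc_x = 0.4, beta_b = 0.5, beta_w = 0.2,
                                 tau2_y = 0.2)
  dp <- direct_prior(0, 5)
  ip <- indirect_prior(0.8, 5)
  cfg <- study_config(pop, n = 20, J_grid = 200, reps = 3000, seed = 61,
                      specs = list(
                        estimator_spec("ml"),
                        estimator_spec("direct", dprior = dp),
                        estimator_spec("indirect", iprior = ip)))
  st <- run_study(cfg)
  res <- st$results
  an <- list(
    ml = accuracy_report("ml", pop, 200, 20),
    direct = accuracy_report("direct", pop, 200, 20, dprior = dp),
    indirect = accuracy_report("indirect", pop, 200, 20, iprior = ip))
  for (m in names(an)) {
    row <- res[res$label == m, ]
    bias_se <- sqrt(row$variance / row$included)
    expect_lt(abs(an[[m]]$bias - row$bias), 3 * bias_se)
    expect_lt(abs(an[[m]]$rmse - row$rmse) / row$rmse, 0.15)
  }
})
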