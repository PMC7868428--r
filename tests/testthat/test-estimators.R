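test_that("shrinkage weight is J/(nu0+J)", {
  expect_equal(shrinkage_weight(20, 0), 1)
  expect_equal(shrinkage_weight(20, 5), 0.8)
  expect_equal(shrinkage_weight(20, 20), 0.5)
  expect_error(shrinkage_weight(20, -1), "nu0")
})

test_that("ML slope is the between-covariance/between-variance ratio", {
  expect_equal(ml_slope(worked_stats())$value, 0.7)
  s0 <- suffstats(0.2, 0, 0.1, 0.9, 20, 5)
  expect_equal(ml_slope(s0)$value, 0)
  neg <- suffstats(-0.01, 0.07, 0.15, 0.9, 20, 5)
  e <- ml_slope(neg)
  expect_equal(e$value, -7)
  expect_true("degenerate" %in% e$flags)
  expect_error(ml_slope(suffstats(0, 0.07, 0.15, 0.9, 20, 5)), "undefined")
})

test_that("direct posterior is the conjugate normal update", {
  s <- worked_stats()  # beta_hat = 0.7, J = 20
  # flat prior: ML limiting case
  p0 <- direct_posterior(s, direct_prior(beta0 = 3, nu0 = 0))
  expect_equal(p0$mean, 0.7)
  expect_equal(p0$variance, 0.15 / (20 * 0.1))
  # nu0 = J: half shrinkage
  expect_equal(direct_posterior(s, direct_prior(0, 20))$mean, 0.35)
  # agreeing prior is a fixed point
  expect_equal(direct_posterior(s, direct_prior(0.7, 7))$mean, 0.7)
  # posterior variance is w * likelihood variance
  p <- direct_posterior(s, direct_prior(0, 5))
  expect_equal(p$variance, 0.8 * 0.15 / (20 * 0.1))
  expect_error(direct_posterior(suffstats(-0.1, 0.07, 0.15, 0.9, 20, 5),
                                direct_prior(0, 1)), "tau2_x_hat")
})

test_that("direct EAP is the weighted average of guess and ML estimate", {
  s <- suffstats(0.1, 0.05, 0.15, 0.9, 20, 5)  # beta_hat = 0.5
  e <- direct_eap(s, direct_prior(0, 5))       # w = 0.8
  expect_equal(e$value, 0.4)
  expect_equal(e$weight_w, 0.8)
  expect_equal(direct_eap(s, direct_prior(0, 0))$value, 0.5)
  s2 <- suffstats(0.1, 0.105, 0.15, 0.9, 20, 5)  # beta_hat = 1.05
  expect_equal(direct_eap(s2, direct_prior(0, 1))$value, (20 / 21) * 1.05)
})

test_that("indirect posterior is the conjugate gamma update", {
  s <- worked_stats()
  g <- indirect_posterior(s, indirect_prior(1, 1))
  expect_equal(g$shape, 10.5)
  expect_equal(g$rate, 1.5)
  # pure likelihood
  g0 <- indirect_posterior(s, indirect_prior(1, 0))
  expect_equal(g0$shape, 10)
  expect_equal(g0$rate, 20 * 0.1 / 2)
  # prior-only limit (no data)
  gp <- indirect_posterior(NULL, indirect_prior(0.5, 4))
  expect_equal(gp$shape, 2)
  expect_equal(gp$rate, 1)
  expect_error(indirect_posterior(suffstats(-0.2, 0, 0.1, 0.9, 20, 5),
                                  indirect_prior(1, 0)), "rate")
})

test_that("stabilized variance is the weighted average, positive under truncation", {
  s <- worked_stats()
  expect_equal(indirect_variance_eap(s, indirect_prior(2, 0)), 0.1)
  s19 <- suffstats(0.1, 0.07, 0.15, 0.9, 19, 5)
  expect_equal(indirect_variance_eap(s19, indirect_prior(1, 1)), 0.145)
  neg <- suffstats(-0.3, 0.07, 0.15, 0.9, 20, 5)
  v <- indirect_variance_eap(neg, indirect_prior(1, 1))
  expect_equal(v, 1 / 21)
  expect_gt(v, 0)
})

test_that("weighted average tracks the exact inverse-gamma mean", {
  pr <- indirect_prior(1, 1)
  # relative error is bounded by 2/(nu0 + J - 2) exactly
  for (J in c(20, 40, 60)) {
    s <- suffstats(0.1, 0.07, 0.15, 0.9, J, 5)
    approx <- indirect_variance_eap(s, pr)
    exact <- indirect_variance_exact(s, pr)
    expect_equal(exact, (1 * 1 + J * 0.1) / (1 + J - 2))
    expect_lt(abs(approx - exact) / exact, 2 / (1 + J - 2) + 1e-12)
  }
  # the discrepancy shrinks as J grows
  gap <- sapply(c(20, 40, 60), function(J) {
    s <- suffstats(0.1, 0.07, 0.15, 0.9, J, 5)
    abs(indirect_variance_eap(s, pr) - indirect_variance_exact(s, pr))
  })
  expect_true(all(diff(gap) < 0))
})

test_that("indirect slope divides by the stabilized variance", {
  s19 <- suffstats(0.1, 0.07, 0.15, 0.9, 19, 5)
  expect_equal(indirect_slope(s19, indirect_prior(1, 1))$value, 0.07 / 0.145)
  # flat prior: ML limiting case
  expect_equal(indirect_slope(worked_stats(), indirect_prior(1, 0))$value,
               0.7)
  # truncated variance stays finite thanks to the prior mass
  zero <- suffstats(0, 0.07, 0.15, 0.9, 20, 5)
  e <- indirect_slope(zero, indirect_prior(1, 1))
  expect_equal(e$value, 0.07 / (1 / 21))
  expect_error(indirect_slope(zero, indirect_prior(1, 0)), "not positive")
})

test_that("combined estimator reduces to each component in the flat limits", {
  pool <- simulated_stats_pool(k = 30)
  dp <- direct_prior(0, 1)
  ip <- indirect_prior(1, 1)
  flat_d <- direct_prior(0, 0)
  flat_i <- indirect_prior(1, 0)
  for (s in pool) {
    if (s$tau2_x_hat <= 0) next
    ml <- ml_slope(s)$value
    expect_identical(combined_slope(s, flat_d, flat_i)$value, ml)
    expect_identical(combined_slope(s, flat_d, ip)$value,
                     indirect_slope(s, ip)$value)
    expect_identical(combined_slope(s, dp, flat_i)$value,
                     direct_eap(s, dp)$value)
  }
})

test_that("shrinkage is bounded and monotone in the prior sample size", {
  pool <- simulated_stats_pool(k = 30)
  beta0 <- 0.2
  for (s in pool) {
    if (s$tau2_x_hat <= 0) next
    ml <- ml_slope(s)$value
    prev <- ml
    for (nu0 in c(0.5, 1, 2, 5, 20, 100)) {
      e <- direct_eap(s, direct_prior(beta0, nu0))$value
      # always between the prior guess and the ML estimate
      expect_lte(abs(e - beta0), abs(ml - beta0))
      # monotone approach toward beta0
      expect_lte(abs(e - beta0), abs(prev - beta0) + 1e-12)
      prev <- e
    }
  }
})

test_that("an over-guessed prior variance attenuates the slope", {
  pool <- simulated_stats_pool(k = 30)
  for (s in pool) {
    if (s$tau2_x_hat <= 0) next
    ip <- indirect_prior(tau0_sq = max(1, 2 * s$tau2_x_hat), nu0 = 1)
    expect_lte(abs(indirect_slope(s, ip)$value),
               abs(ml_slope(s)$value) + 1e-12)
  }
})

test_that("Mplus hyperparameter translation matches the closed forms", {
  expect_equal(direct_prior_to_mplus(direct_prior(0, 1), 0.15, 0.1),
               c(a = 0, b = 1.5))
  expect_equal(direct_prior_to_mplus(direct_prior(0.7, 1), 0.2, 0.2),
               c(a = 0.7, b = 1))
  expect_equal(direct_prior_to_mplus(direct_prior(0, 3), 0.15, 0.1),
               c(a = 0, b = 0.5))
  expect_equal(indirect_prior_to_mplus(indirect_prior(1, 1)),
               c(a = 0.5, b = 0.5))
  expect_equal(indirect_prior_to_mplus(indirect_prior(0.1, 2)),
               c(a = 1, b = 0.1))
  expect_equal(indirect_prior_to_mplus(indirect_prior(1, 4)),
               c(a = 2, b = 2))
  expect_error(direct_prior_to_mplus(direct_prior(0, 0), 0.15, 0.1), "flat")
  expect_error(indirect_prior_to_mplus(indirect_prior(1, 0)), "flat")
})

test_that("the MODEL PRIORS block renders with minimal decimals", {
  expect_identical(
    mplus_priors(direct = direct_prior(0, 1), tau2_y = 0.15, tau2_x = 0.1),
    "MODEL PRIORS:\n   slope ~ N(0, 1.5);")
  expect_identical(
    mplus_priors(indirect = indirect_prior(1, 1)),
    "MODEL PRIORS:\n   variance ~ IG(0.5, 0.5);")
  both <- mplus_priors(direct = direct_prior(0, 1),
                       indirect = indirect_prior(1, 1),
                       tau2_y = 0.15, tau2_x = 0.1,
                       slope_label = "s1", variance_label = "v1")
  expect_identical(both,
    "MODEL PRIORS:\n   s1 ~ N(0, 1.5);\n   v1 ~ IG(0.5, 0.5);")
  expect_error(mplus_priors(direct = direct_prior(0, 1)), "tau2_y")
})
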