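test_that("exponential model evaluates its closed form", {
  expect_equal(exp_model(0, 0.3, 12), 1)
  expect_equal(exp_model(1e6 * 20, 0.25, 20), 0.75, tolerance = 1e-9)
  expect_equal(exp_model(15, 0.25, 15), 1 - 0.25 * (1 - exp(-1)),
               tolerance = 1e-12)
  # the algebraic variant approaches alpha instead of 1 - alpha
  expect_equal(exp_model(1e6 * 20, 0.25, 20, form = "printed"), 0.25,
               tolerance = 1e-9)
  expect_equal(exp_model(0, 0.25, 20, form = "printed"), 1)
  expect_error(exp_model(1, 0.2, 0))
})

test_that("exponential fit recovers noiseless parameters to high precision", {
  t <- 0:95
  y <- exp_model(t, 0.2, 15)
  f <- fit_exponential(t, y)
  expect_lt(abs(f$alpha - 0.2), 1e-6)
  expect_lt(abs(f$beta - 15), 1e-4)
  expect_true(f$converged)
  # negative alpha (gain-up) works the same way
  f2 <- fit_exponential(t, exp_model(t, -0.33, 25))
  expect_lt(abs(f2$alpha + 0.33), 1e-6)
  expect_lt(abs(f2$beta - 25), 1e-3)
})

test_that("exponential fit is invariant to a trial-index offset", {
  t <- 0:95
  y <- exp_model(t, 0.2, 15)
  f1 <- fit_exponential(t, y)
  f2 <- fit_exponential(t + 1234, y)
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-10)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
})

test_that("constant series yield a flagged, unidentifiable timescale", {
  f <- fit_exponential(0:20, rep(1, 21))
  expect_equal(f$alpha, 0)
  expect_false(f$converged)
  expect_error(fit_exponential(0:3, rep(1, 4)))
  expect_error(fit_exponential(c(0:5), c(1, NA, NA, NA, 1, 1)))
})

test_that("alpha is recovered with small bias from noisy series", {
  set.seed(5)
  t <- 0:95
  alphas <- replicate(60, {
    y <- exp_model(t, 0.2, 15) + rnorm(96, 0, 0.05)
    fit_exponential(t, y)$alpha
  })
  expect_lt(abs(mean(alphas) - 0.2), 0.02)
})

test_that("paired bootstrap is deterministic and gives p = 1 for identical data", {
  set.seed(8)
  m <- exp_cohort(10, 0.25, 12)
  b1 <- bootstrap_exponential(list(a = m, b = m), n_folds = 500, seed = 3)
  b2 <- bootstrap_exponential(list(a = m, b = m), n_folds = 500, seed = 3)
  expect_identical(b1$folds, b2$folds)
  expect_true(all(b1$comparisons$p == 1))
  expect_true(all(b1$comparisons$median_diff == 0))
  expect_error(bootstrap_exponential(list(a = m[1, , drop = FALSE]),
                                     n_folds = 10))
})

test_that("bootstrap separates fast from slow timescales in a synthetic cohort", {
  set.seed(9)
  fastm <- exp_cohort(12, 0.25, 8)
  slowm <- exp_cohort(12, 0.25, 30)
  b <- bootstrap_exponential(list(reactive = fastm, scanning = slowm),
                             n_folds = 2000, seed = 17)
  beta_row <- b$comparisons[b$comparisons$parameter == "beta", ]
  expect_gt(beta_row$median_diff, 0)
  expect_lt(beta_row$p, 0.05)
})

test_that("dual-state gains are recovered exactly from noiseless data", {
  p <- rep(-0.25, 96)
  truth <- dual_state_params(gamma_fast = 0.5, gamma_slow = 0.7)
  y <- 1 + simulate_dual_state(p, truth)$adaptation
  f <- fit_dual_state_gains(y, p)
  expect_lt(abs(f$gamma_fast - 0.5), 1e-6)
  expect_lt(abs(f$gamma_slow - 0.7), 1e-6)
  # the fixed rates are echoed in the result
  expect_equal(unlist(f$rates[c("alpha_fast", "beta_fast",
                                "alpha_slow", "beta_slow")]),
               c(alpha_fast = 0.21, beta_fast = 0.59,
                 alpha_slow = 0.02, beta_slow = 0.992))
  # fitted trace obeys the recursion at the optimum
  refit <- simulate_dual_state(
    p, dual_state_params(gamma_fast = f$gamma_fast,
                         gamma_slow = f$gamma_slow))
  expect_equal(f$fitted$adaptation, refit$adaptation)
})

test_that("missing trials are excluded from the loss but not the recursion", {
  p <- rep(-0.25, 96)
  truth <- dual_state_params(gamma_fast = 0.4, gamma_slow = 0.9)
  y <- 1 + simulate_dual_state(p, truth)$adaptation
  y[sample.int(96, 20)] <- NA
  f <- fit_dual_state_gains(y, p)
  expect_lt(abs(f$gamma_fast - 0.4), 1e-5)
  expect_lt(abs(f$gamma_slow - 0.9), 1e-5)
  expect_equal(f$n_valid, 76)
})

test_that("unadapted data give near-zero gains; degenerate inputs error", {
  p <- rep(-0.25, 96)
  f <- fit_dual_state_gains(rep(1, 96), p)
  expect_lt(f$gamma_fast, 1e-6)
  expect_lt(f$gamma_slow, 1e-6)
  expect_error(fit_dual_state_gains(rep(1, 96), rep(0, 96)))
  expect_error(fit_dual_state_gains(c(rep(1, 5), rep(NA, 91)), p))
})

test_that("slow ratio behaves at its boundaries", {
  expect_equal(slow_ratio(0.3, 0.3), 0.5)
  expect_equal(slow_ratio(0, 0.4), 1)
  expect_equal(slow_ratio(0.4, 0), 0)
  expect_warning(r <- slow_ratio(0, 0), "undefined")
  expect_true(is.na(r))
})

test_that("fast and slow basis traces are jointly identifiable", {
  id <- dual_state_identifiability(rep(-0.25, 96))
  expect_true(id$identifiable)
  expect_true(is.finite(id$condition_number))
  expect_gt(id$condition_number, 1)
})
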