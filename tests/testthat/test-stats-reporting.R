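test_that("one-sample t matches hand computation and the analytic oracle", {
  r <- one_sample_t(c(0.6, 0.7, 0.8), 0.5)
  expect_equal(r$t, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$dof, 2)
  # degenerate but exactly-null data
  r0 <- one_sample_t(rep(0.5, 5), 0.5)
  expect_equal(c(r0$t, r0$p, r0$d), c(0, 1, 0))
  expect_error(one_sample_t(rep(0.4, 5), 0.5))
  expect_error(one_sample_t(0.4))
  set.seed(10)
  for (i in 1:200) {
    v <- rnorm(sample(3:20, 1), sd = runif(1, 0.5, 2))
    mu <- rnorm(1)
    mine <- one_sample_t(v, mu)
    ref <- t.test(v, mu = mu)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("paired t equals the one-sample t on differences", {
  set.seed(11)
  a <- rnorm(12)
  b <- rnorm(12)
  expect_equal(unclass(paired_t(a, b)), unclass(one_sample_t(a - b, 0)),
               tolerance = 1e-12)
  a[3] <- NA
  ref <- t.test(a, b, paired = TRUE)
  mine <- paired_t(a, b)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$dof, unname(ref$parameter))
  expect_error(paired_t(c(1, 2), c(1, 2, 3)))
  expect_error(paired_t(c(2, 2, 2), c(1, 1, 1)))
  eq <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(eq$t, eq$p), c(0, 1))
})

cohort_fixture <- function(n = 6, seed = 20, ...) {
  trials <- simulate_cohort(n_participants = n, seed = seed, ...)
  trials <- reject_trials(trials)
  normalize_gain(trials)
}

test_that("latency summaries recover the generator's condition means", {
  trials <- cohort_fixture(n = 8, seed = 22, blink_rate = 0,
                           outlier_rate = 0)
  ls <- latency_summary(trials, block = 2)
  re <- ls$conditions[ls$conditions$saccade_type == "reactive", ]
  sc <- ls$conditions[ls$conditions$saccade_type == "scanning", ]
  # between-participant sd 15 and trial sd 30 -> generous 2-SEM style bound
  expect_true(all(abs(re$mean - 193) < 2 * 16 / sqrt(8)))
  expect_true(all(abs(sc$mean - 307) < 2 * 16 / sqrt(8)))
  expect_true(all(sc$mean - re$mean > 80))
  expect_true(all(ls$conditions$n == 8))
})

test_that("latency summaries are invariant to participant relabeling", {
  trials <- cohort_fixture(n = 5, seed = 23)
  shuffled <- trials[sample.int(nrow(trials)), ]
  a <- latency_summary(trials)$conditions
  b <- latency_summary(shuffled)$conditions
  ord <- function(d) d[order(d$saccade_type, d$gain_direction), ]
  expect_equal(ord(a)$mean, ord(b)$mean)
})

test_that("degenerate latency data give zero-width intervals", {
  s <- condition_summary(rep(200, 6))
  expect_equal(s$mean, 200)
  expect_equal(s$ci_halfwidth, 0)
  expect_equal(s$n, 6)
})

test_that("identical dual-state fits in all conditions give null contrasts", {
  fits <- expand.grid(participant = 1:6,
                      saccade_type = c("reactive", "scanning"),
                      direction_order = c("down-up", "up-down"),
                      stringsAsFactors = FALSE)
  fits$gain_direction <- ifelse(fits$direction_order == "down-up", "down", "up")
  fits$gamma_fast <- 0.5
  fits$gamma_slow <- 0.5
  fits$sse <- 0
  fits$n_valid <- 90
  ct <- process_gain_contrasts(fits)
  expect_equal(ct$slow_ratio$reactive$test$t, 0)
  expect_equal(ct$slow_ratio$reactive$test$p, 1)
  expect_equal(ct$process_difference$fast$test$t, 0)
  expect_equal(ct$process_difference$fast$summary$mean, 0)
})

test_that("contrast direction matches the generating process gains", {
  trials <- cohort_fixture(n = 12, seed = 25,
                           gamma_reactive = c(0.5, 0.5),
                           gamma_scanning = c(0.2, 0.65),
                           gamma_sd = 0.1)
  fits <- fit_cohort_dual_state(trials)
  ct <- process_gain_contrasts(fits)
  expect_gt(ct$slow_ratio$scanning$summary$mean,
            ct$slow_ratio$reactive$summary$mean)
  # reactive minus scanning fast gain positive; slow gain negative
  expect_gt(ct$process_difference$fast$summary$mean, 0)
  expect_lt(ct$process_difference$slow$summary$mean, 0)
})

test_that("kinematic change is zero in an unadapted noiseless session", {
  ses <- clean_session(seed = 4)
  ses$participant <- 1
  ses <- reject_trials(ses)
  ses <- normalize_gain(ses)
  kin <- kinematic_change_summary(ses)
  expect_true(all(abs(kin$per_participant$change) < 1e-12))
})

test_that("velocity-driven gain-down shows up in the kinematic ordering", {
  proto <- build_protocol("reactive", "down-up")
  ses <- simulate_session(proto,
                          dual_state_params(gamma_fast = 0.6,
                                            gamma_slow = 0.8),
                          noise_sd = 0.02, vel_share_down = 1,
                          blink_rate = 0, outlier_rate = 0, seed = 6)
  ses$participant <- 1
  ses <- reject_trials(ses)
  ses <- normalize_gain(ses)
  kin <- kinematic_change_summary(ses)
  pp <- kin$per_participant
  amp <- pp$change[pp$measure == "amplitude"]
  vel <- pp$change[pp$measure == "velocity"]
  dur <- pp$change[pp$measure == "duration"]
  expect_lt(amp, -0.05)
  expect_equal(vel, amp, tolerance = 0.15)
  expect_lt(abs(dur), abs(vel))
})

test_that("awareness proportions count seen over scored responses", {
  tr <- data.frame(saccade_type = "reactive", gain_direction = "down",
                   block = 2,
                   seen_response = c(rep("seen", 24), rep("unseen", 72)))
  aw <- awareness_summary(tr)
  expect_equal(aw$proportions$prop_seen, 0.25)
  expect_equal(aw$proportions$n, 96)
  tr$seen_response[1:10] <- "missing"
  aw2 <- awareness_summary(tr)
  expect_equal(aw2$proportions$n, 86)
  expect_equal(aw2$proportions$prop_seen, 14 / 86)
  tr$seen_response <- "unseen"
  expect_equal(awareness_summary(tr)$proportions$prop_seen, 0)
})

test_that("baseline blocks of a simulated cohort are rarely reported seen", {
  trials <- cohort_fixture(n = 4, seed = 28)
  aw <- awareness_summary(trials)
  base <- aw$proportions[aw$proportions$gain_direction == "baseline", ]
  expect_true(all(base$prop_seen < 0.10))
  adapt2 <- aw$proportions[aw$proportions$block == 2, ]
  expect_true(all(adapt2$prop_seen > base$prop_seen[1]))
})

test_that("rm-ANOVA pass-through reports within-participant effects", {
  trials <- cohort_fixture(n = 8, seed = 22, blink_rate = 0,
                           outlier_rate = 0)
  ls <- latency_summary(trials, block = 2)
  an <- rm_anova(ls$per_participant, dv = "value", id = "participant",
                 within = c("saccade_type", "gain_direction"))
  st <- an[an$term == "saccade_type", ]
  expect_equal(st$df1, 1)
  expect_equal(st$df2, 7)
  expect_lt(st$p, 0.01)
  expect_true(st$eta_p_sq > 0 && st$eta_p_sq <= 1)
})
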