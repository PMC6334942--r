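make_trace <- function(x, y = NULL, sr = 1000) {
  n <- length(x)
  if (is.null(y)) y <- rep(0, n)
  df <- data.frame(t_ms = seq(0, by = 1000 / sr, length.out = n),
                   x_dva = x, y_dva = y, valid = TRUE)
  attr(df, "sample_rate") <- sr
  class(df) <- c("gaze_recording", "data.frame")
  df
}

test_that("five-point differentiator is exact on constants and ramps", {
  tr <- make_trace(rep(2.5, 50))
  v <- compute_velocity(tr)
  expect_true(all(v$vx == 0))
  # ramp x(t) = k t, k = 30 dva/s
  k <- 30
  t_s <- seq(0, 0.2, by = 0.001)
  tr <- make_trace(k * t_s)
  v <- compute_velocity(tr)
  expect_equal(v$vx[3:(length(t_s) - 2)], rep(k, length(t_s) - 4),
               tolerance = 1e-9)
  expect_error(compute_velocity(make_trace(1:4)))
})

test_that("a single-sample spike has a finite, local, symmetric response", {
  x <- rep(0, 41)
  x[21] <- 1
  v <- compute_velocity(make_trace(x))$vx
  expect_true(all(is.finite(v)))
  expect_true(all(v[c(1:18, 24:41)] == 0))
  # stencil response is odd-symmetric around the spike
  expect_equal(v[19], -v[23])
  expect_equal(v[20], -v[22])
  expect_equal(v[21], 0)
})

test_that("robust velocity spread matches hand values and Gaussian theory", {
  expect_equal(robust_velocity_std(rep(0, 10)), 0)
  expect_equal(robust_velocity_std(c(-1, 0, 1)), 1)
  expect_error(robust_velocity_std(3))
  set.seed(2)
  s <- 7
  v <- rnorm(1e5, 0, s)
  # median(v^2) -> qchisq(0.5, 1) * s^2, median(v) -> 0
  expect_lt(abs(robust_velocity_std(v) / (s * sqrt(qchisq(0.5, 1))) - 1),
            0.05)
})

test_that("detector finds nothing in fixation noise and errors on flat traces", {
  set.seed(4)
  n <- 600
  tr <- make_trace(rnorm(n, 0, 0.02), rnorm(n, 0, 0.02))
  expect_equal(nrow(detect_saccades(tr)), 0)
  expect_error(detect_saccades(make_trace(rep(1, 100))), "degenerate")
})

test_that("detector recovers a generated saccade's onset and amplitude", {
  g <- synthesize_gaze_trial(c(0, 0), c(10, 0), 10, latency_ms = 200,
                             noise_sd_pos = 0.01, seed = 9)
  ev <- detect_saccades(g)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$onset_ms - 200), 6)
  expect_lt(abs(ev$amplitude - 10) / 10, 0.05)
  expect_gte(ev$peak_velocity, ev$amplitude / ev$duration_ms * 1000)
})

test_that("two well-separated saccades give two ordered events", {
  g1 <- synthesize_gaze_trial(c(0, 0), c(10, 0), 10, latency_ms = 150,
                              tail_ms = 500, noise_sd_pos = 0.01, seed = 2)
  # second saccade back toward the origin, spliced 500 ms later
  g2 <- synthesize_gaze_trial(c(10, 0), c(0, 0), 10, latency_ms = 100,
                              noise_sd_pos = 0.01, seed = 3)
  g2$t_ms <- g2$t_ms + max(g1$t_ms) + 1
  both <- rbind(as.data.frame(g1), as.data.frame(g2))
  attr(both, "sample_rate") <- 1000
  class(both) <- c("gaze_recording", "data.frame")
  ev <- detect_saccades(both)
  expect_equal(nrow(ev), 2)
  expect_true(ev$onset_ms[1] < ev$onset_ms[2])
  expect_gt(ev$onset_ms[2] - ev$offset_ms[1], 400)
})

test_that("detection is invariant under rotation of the trace", {
  g <- synthesize_gaze_trial(c(0, 0), c(8, 0), 8, latency_ms = 180,
                             noise_sd_pos = 0.015, seed = 21)
  base <- detect_saccades(g)
  for (ang in c(0.4, 1.1, 2.9, 4.4)) {
    rot <- g
    rot$x_dva <- cos(ang) * g$x_dva - sin(ang) * g$y_dva
    rot$y_dva <- sin(ang) * g$x_dva + cos(ang) * g$y_dva
    ev <- detect_saccades(rot)
    expect_equal(nrow(ev), nrow(base))
    # thresholds are re-estimated per rotated component, so the crossing
    # sample may shift by at most one sample either side
    expect_lte(max(abs(ev$duration_ms - base$duration_ms)), 2)
  }
})

test_that("detector agrees exactly with the brute-force reference", {
  for (seed in 1:25) {
    tr <- random_saccade_trace(seed)
    got <- detect_saccades(tr)
    ref <- oracle_detect(tr)
    if (is.null(ref)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$onset_ms, ref$onset_ms)
      expect_equal(got$offset_ms, ref$offset_ms)
    }
  }
})

test_that("latency is onset minus flash, with anticipatory flagging", {
  expect_equal(saccade_latency(450, 250)$latency_ms, 200)
  a <- saccade_latency(240, 250)
  expect_equal(a$latency_ms, -10)
  expect_true(a$anticipatory)
  expect_error(saccade_latency(450, NA))
  expect_error(saccade_latency(450))
})

test_that("detected latencies recover the generator's latency distribution", {
  set.seed(31)
  lat_true <- rnorm(40, 195, 20)
  lats <- vapply(seq_along(lat_true), function(i) {
    g <- synthesize_gaze_trial(c(0, 0), c(10, 0), 10,
                               latency_ms = lat_true[i],
                               noise_sd_pos = 0.01, seed = 100 + i)
    ev <- detect_saccades(g)
    saccade_latency(ev$onset_ms[1], 0)$latency_ms
  }, numeric(1))
  expect_lt(abs(mean(lats) - 195), 2 * 20 / sqrt(40) + 6)
})
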