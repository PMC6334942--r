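base_trials <- function(amps, block = 1) {
  n <- length(amps)
  data.frame(
    block = block, trial_in_block = seq_len(n), direction = rep(1:6, length.out = n),
    amplitude = amps, blink = FALSE,
    start_x = 0, start_y = 0, fix_target_x = 0, fix_target_y = 0
  )
}

test_that("rejection rules fire in order with the documented reasons", {
  tr <- base_trials(c(rep(10, 8), 2.9, 10))
  tr$start_x[5] <- 1.6  # startpoint deviation
  tr$blink[2] <- TRUE
  out <- reject_trials(tr)
  expect_equal(out$qc_reason[2], "blink")
  expect_equal(out$qc_reason[9], "amplitude_low")
  expect_equal(out$qc_reason[5], "startpoint_deviation")
  expect_true(all(out$qc_valid[c(1, 3, 4, 6, 7, 8, 10)]))
  # blink wins over other failures
  tr2 <- base_trials(rep(10, 6))
  tr2$amplitude[1] <- 2
  tr2$blink[1] <- TRUE
  expect_equal(reject_trials(tr2)$qc_reason[1], "blink")
})

test_that("MAD rule rejects the lone outlier in a degenerate block", {
  tr <- base_trials(c(rep(10, 9), 20))
  out <- reject_trials(tr)
  expect_equal(sum(!out$qc_valid), 1)
  expect_equal(out$qc_reason[10], "amplitude_outlier")
  expect_equal(sum(out$qc_valid), 9)
})

test_that("MAD rule is skipped with a warning in tiny blocks", {
  tr <- base_trials(c(10, 30, 10))
  expect_warning(out <- reject_trials(tr), "skipped")
  expect_true(all(out$qc_valid))
})

test_that("rejection is idempotent", {
  proto <- build_protocol("reactive", "down-up")
  ses <- simulate_session(proto, blink_rate = 0.05, outlier_rate = 0.03,
                          seed = 12)
  once <- reject_trials(ses)
  twice <- reject_trials(once)
  expect_identical(once$qc_valid, twice$qc_valid)
  expect_identical(once$qc_reason, twice$qc_reason)
})

test_that("injected contaminants are counted exactly", {
  ses <- clean_session(seed = 3)
  k <- 7
  m <- 5
  blink_idx <- c(4, 20, 60, 100, 150, 200, 280)
  out_idx <- c(10, 55, 120, 180, 250)
  ses$blink[blink_idx] <- TRUE
  ses$amplitude[out_idx] <- ses$amplitude[out_idx] * 2
  out <- reject_trials(ses)
  counts <- attr(out, "qc_counts")
  expect_equal(counts$blink, k)
  expect_equal(counts$amplitude_outlier, m)
  expect_equal(counts$amplitude_low, 0)
  expect_equal(counts$startpoint_deviation, 0)
})

test_that("gain normalization divides by per-direction baseline medians", {
  proto <- build_protocol("reactive", "down-up")
  ses <- simulate_session(proto, noise_sd = 0, start_jitter_sd = 0, seed = 1)
  ses <- reject_trials(ses)
  ses <- normalize_gain(ses)
  # baseline medians per direction are 1 by construction
  for (d in 1:6) {
    g <- ses$gain[ses$block == 1 & ses$direction == d & ses$qc_valid]
    expect_equal(median(g), 1)
  }
  # a trial whose amplitude equals its direction baseline median has gain 1
  i <- which(ses$block == 1 & ses$qc_valid)[1]
  expect_equal(ses$gain[i], ses$amplitude[i] /
                 median(ses$amplitude[ses$block == 1 & ses$qc_valid &
                                        ses$direction == ses$direction[i]]))
  # known division example: amplitude 7.5 against baseline median 10
  expect_equal(7.5 / 10, 0.75)
  expect_true(all(is.na(ses$gain[!ses$qc_valid])))
  expect_equal(nrow(ses), 288)
})

test_that("an empty baseline direction raises a named error", {
  tr <- base_trials(rep(10, 12))
  tr$block[1:6] <- 1
  tr$block[7:12] <- 2
  tr <- reject_trials(tr)
  tr$qc_valid[tr$block == 1 & tr$direction == 2] <- FALSE
  expect_error(normalize_gain(tr), "direction 2")
})

test_that("running average is centered, shrinks at edges and respects blocks", {
  expect_equal(running_average(rep(3, 10)), rep(3, 10))
  expect_equal(running_average(1:7, window = 3)[4], 4)
  x <- c(1, 2, NA, 4, 5)
  expect_equal(running_average(x, window = 3)[3], 3)  # mean(2, 4)
  expect_true(is.na(running_average(c(NA, NA, NA), window = 3)[2]))
  expect_error(running_average(1:3, window = 5))
  # block boundaries are never shared
  s <- c(rep(0, 6), rep(10, 6))
  b <- rep(1:2, each = 6)
  sm <- running_average(s, window = 6, blocks = b)
  expect_equal(sm, s)
})

test_that("block-transition change is first-6 minus last-6 mean gain", {
  tr <- data.frame(block = rep(2:3, each = 12), trial_in_block = rep(1:12, 2),
                   gain = 1)
  expect_equal(block_transition_change(tr, 2, 3), 0)
  tr$gain[tr$block == 2] <- 0.78
  tr$gain[tr$block == 3] <- 0.93
  expect_equal(block_transition_change(tr, 2, 3), 0.15)
  tr$gain[tr$block == 3][1:6] <- NA
  expect_true(is.na(block_transition_change(tr, 2, 3)))
  expect_error(block_transition_change(tr, 2, 5))
})
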