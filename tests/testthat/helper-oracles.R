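# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths: plain loops, no vectorised shortcuts.

# hand-unrolled dual-state recursion (closed loop)
oracle_dual_state <- function(p, af, bf, as_, bs, gf, gs) {
  xf <- 0; xs <- 0; adapt_prev <- 0
  out <- data.frame(error = numeric(length(p)), state_fast = 0,
                    state_slow = 0, adaptation = 0)
  for (i in seq_along(p)) {
    eps <- p[i] - adapt_prev
    xf <- af * eps + bf * xf
    xs <- as_ * eps + bs * xs
    adapt_prev <- gf * xf + gs * xs
    out$error[i] <- eps
    out$state_fast[i] <- xf
    out$state_slow[i] <- xs
    out$adaptation[i] <- adapt_prev
  }
  out
}

# brute-force saccade detector: direct scan of the threshold inequality
oracle_detect <- function(trace, lambda = 6, min_dur = 6, merge_gap = 20) {
  n <- nrow(trace)
  sr <- attr(trace, "sample_rate")
  if (is.null(sr)) sr <- 1000 / stats::median(diff(trace$t_ms))
  dt <- 1 / sr
  vx <- rep(NA_real_, n)
  vy <- rep(NA_real_, n)
  for (i in 3:(n - 2)) {
    vx[i] <- (trace$x_dva[i + 2] + trace$x_dva[i + 1] -
                trace$x_dva[i - 1] - trace$x_dva[i - 2]) / (6 * dt)
    vy[i] <- (trace$y_dva[i + 2] + trace$y_dva[i + 1] -
                trace$y_dva[i - 1] - trace$y_dva[i - 2]) / (6 * dt)
  }
  vx[1:2] <- vx[3]; vx[(n - 1):n] <- vx[n - 2]
  vy[1:2] <- vy[3]; vy[(n - 1):n] <- vy[n - 2]
  rmed <- function(z) stats::median(z[is.finite(z)])
  sx <- sqrt(max(rmed(vx^2) - rmed(vx)^2, 0))
  sy <- sqrt(max(rmed(vy^2) - rmed(vy)^2, 0))
  stopifnot(sx > 0, sy > 0)
  over <- logical(n)
  for (i in seq_len(n)) {
    crit <- (vx[i] / (lambda * sx))^2 + (vy[i] / (lambda * sy))^2
    over[i] <- isTRUE(crit > 1) && isTRUE(trace$valid[i])
  }
  # maximal runs
  runs <- NULL
  i <- 1
  while (i <= n) {
    if (over[i]) {
      j <- i
      while (j < n && over[j + 1]) j <- j + 1
      runs <- rbind(runs, c(i, j))
      i <- j + 1
    } else i <- i + 1
  }
  if (is.null(runs)) return(NULL)
  # iterative pairwise merging
  repeat {
    if (nrow(runs) < 2) break
    merged_any <- FALSE
    for (k in 1:(nrow(runs) - 1)) {
      gap_ms <- trace$t_ms[runs[k + 1, 1]] - trace$t_ms[runs[k, 2]]
      gap_valid <- all(trace$valid[(runs[k, 2] + 1):(runs[k + 1, 1] - 1)])
      if (gap_ms < merge_gap && gap_valid) {
        runs[k, 2] <- runs[k + 1, 2]
        runs <- runs[-(k + 1), , drop = FALSE]
        merged_any <- TRUE
        break
      }
    }
    if (!merged_any) break
  }
  keep <- (trace$t_ms[runs[, 2]] - trace$t_ms[runs[, 1]]) >= min_dur
  runs <- runs[keep, , drop = FALSE]
  if (nrow(runs) == 0) return(NULL)
  data.frame(onset_ms = trace$t_ms[runs[, 1]],
             offset_ms = trace$t_ms[runs[, 2]])
}

# random single-saccade trace for detector stress tests
random_saccade_trace <- function(seed) {
  set.seed(seed)
  amp <- runif(1, 3, 13)
  ang <- runif(1, 0, 2 * pi)
  lat <- runif(1, 100, 300)
  noise <- runif(1, 0, 0.03)
  blink <- runif(1) < 0.15
  synthesize_gaze_trial(
    start_pos = c(0, 0),
    target_pos = amp * c(cos(ang), sin(ang)),
    executed_amplitude = amp,
    latency_ms = lat,
    noise_sd_pos = noise,
    blink_ms = if (blink) c(20, 60) else NULL,
    seed = seed + 1
  )
}

# small clean session for QC tests: no displacement, no noise, no jitter
clean_session <- function(seed = 1) {
  proto <- build_protocol("reactive", "down-up",
                          displacement_forward = 0,
                          displacement_backward = 0)
  simulate_session(proto, noise_sd = 0, start_jitter_sd = 0,
                   blink_rate = 0, outlier_rate = 0, seed = seed)
}

# cohort of per-participant gain series following the exponential model
exp_cohort <- function(n_participants, alpha, beta, noise_sd = 0.05,
                       n_trials = 96) {
  t <- 0:(n_trials - 1)
  m <- matrix(NA_real_, n_participants, n_trials)
  for (i in seq_len(n_participants))
    m[i, ] <- exp_model(t, alpha, beta) + rnorm(n_trials, 0, noise_sd)
  m
}
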