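#' Awareness-model parameters for the synthetic generator
#'
#' Probability of reporting the intrasaccadic displacement as seen follows a
#' logistic model driven by the residual error `|p(i) - adaptation(i-1)|`
#' (in relative gain units, scaled to dva): awareness is high early in an
#' adaptation block and declines as adaptation absorbs the displacement.
#' Backward (gain-down) jumps cross the fovea and are weighted more heavily
#' than forward jumps; scanning blocks add a logit bonus for the extra visual
#' references of the always-present targets. Baseline blocks fall back to the
#' false-alarm base rate.
#'
#' @param base_rate seen-rate with no displacement (false alarms).
#' @param coef_down,coef_up logit slope per dva of residual displacement for
#'   gain-down and gain-up blocks.
#' @param scanning_bonus logit offset added in scanning sessions on
#'   displacement trials.
#' @param missing_rate probability of no response within the window.
#' @return named list.
#' @export
awareness_params <- function(base_rate = 0.02, coef_down = 1.7,
                             coef_up = 0.9, scanning_bonus = 0.8,
                             missing_rate = 0.02) {
  list(base_rate = base_rate, coef_down = coef_down, coef_up = coef_up,
       scanning_bonus = scanning_bonus, missing_rate = missing_rate)
}

#' Simulate one experimental session
#'
#' Generates a full trial table for one session of the hexagonal
#' global-adaptation protocol: trial-by-trial gains follow the dual-state
#' model (closed loop) with additive Gaussian observation noise, saccade
#' amplitude is gain times the inter-target distance, and peak velocity and
#' duration are split from the amplitude according to a velocity share (see
#' below). Latencies are Gaussian, truncated at 80 ms. Blinks and amplitude
#' outliers can be injected at given rates for QC testing; injected
#' contaminants are flagged in truth columns.
#'
#' Kinematic split: the relative amplitude `rel = A / A0` is carried by
#' peak velocity as `rel^vel_share` and by duration as `rel^(1 - vel_share)`,
#' consistent with the minimum-jerk relation `A = (8/15) V D`. Gain-down
#' adaptation is predominantly velocity-driven (`vel_share_down = 0.8`)
#' while gain-up is balanced (`vel_share_up = 0.5`); baseline blocks use the
#' local main-sequence slope (~0.69 at 10 dva).
#'
#' @param protocol a `protocol_spec` from [build_protocol()].
#' @param params a [dual_state_params()] object (process gains included).
#' @param noise_sd observation noise sd in gain units (default 0.05).
#' @param latency_mean_ms,latency_sd_ms latency distribution; the default
#'   mean is 193 ms for reactive and 307 ms for scanning sessions.
#' @param start_jitter_sd fixation scatter around the pre-saccadic target
#'   (dva per component).
#' @param blink_rate,outlier_rate injection probabilities per trial
#'   (mutually exclusive; blink wins).
#' @param outlier_factor multiplicative amplitude inflation for injected
#'   outliers.
#' @param vel_share_down,vel_share_up,vel_share_baseline velocity share of
#'   amplitude change per block type.
#' @param awareness list from [awareness_params()].
#' @param error_mode error signal mode passed to [simulate_dual_state()].
#' @param gaze if `TRUE`, attach synthesized gaze traces (attribute
#'   `"gaze"`, one `gaze_recording` per trial; slow for full sessions).
#' @param seed integer seed; identical seed and arguments give identical
#'   output.
#' @return data.frame with one row per trial: design columns, true dynamics
#'   (`true_adaptation`, `true_gain`), observed metrics (`amplitude`,
#'   `peak_velocity`, `duration_ms`, `latency_ms`, `onset_ms`, `start_x/y`),
#'   contamination truth (`blink`, `injected_outlier`) and `seen_response`.
#' @export
simulate_session <- function(protocol,
                             params = dual_state_params(),
                             noise_sd = 0.05,
                             latency_mean_ms = NULL,
                             latency_sd_ms = 30,
                             start_jitter_sd = 0.2,
                             blink_rate = 0,
                             outlier_rate = 0,
                             outlier_factor = 2,
                             vel_share_down = 0.8,
                             vel_share_up = 0.5,
                             vel_share_baseline = 0.69,
                             awareness = awareness_params(),
                             error_mode = "closed",
                             gaze = FALSE,
                             seed = 1) {
  stopifnot(inherits(protocol, "protocol_spec"))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (is.null(latency_mean_ms))
    latency_mean_ms <- if (protocol$saccade_type == "reactive") 193 else 307

  design <- protocol_trials(protocol)
  n <- nrow(design)
  trace <- simulate_dual_state(design$perturbation, params,
                               error_mode = error_mode)
  A0 <- protocol$inter_target_distance

  with_seed_(seed, {
    gain <- 1 + trace$adaptation + if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
    gain <- pmax(gain, 0.05)
    amplitude <- gain * A0

    blink <- runif(n) < blink_rate
    injected_outlier <- !blink & runif(n) < outlier_rate
    amplitude[injected_outlier] <- amplitude[injected_outlier] * outlier_factor

    latency <- pmax(rnorm(n, latency_mean_ms, latency_sd_ms), 80)

    start_x <- design$fix_target_x +
      if (start_jitter_sd > 0) rnorm(n, 0, start_jitter_sd) else 0
    start_y <- design$fix_target_y +
      if (start_jitter_sd > 0) rnorm(n, 0, start_jitter_sd) else 0

    # kinematic split of amplitude change into velocity and duration
    w <- ifelse(design$perturbation < 0, vel_share_down,
                ifelse(design$perturbation > 0, vel_share_up,
                       vel_share_baseline))
    vpk0 <- main_sequence_velocity(A0)
    dur0 <- 1000 * 15 * A0 / (8 * vpk0)
    rel <- amplitude / A0
    peak_velocity <- vpk0 * rel^w
    duration_ms <- dur0 * rel^(1 - w)

    # awareness probe
    resid_dva <- abs(trace$error) * A0
    coef <- ifelse(design$perturbation < 0, awareness$coef_down,
                   ifelse(design$perturbation > 0, awareness$coef_up, 0))
    bonus <- ifelse(design$perturbation != 0 &
                      protocol$saccade_type == "scanning",
                    awareness$scanning_bonus, 0)
    p_seen <- plogis(qlogis(awareness$base_rate) + coef * resid_dva + bonus)
    seen <- ifelse(runif(n) < p_seen, "seen", "unseen")
    seen[runif(n) < awareness$missing_rate] <- "missing"

    out <- data.frame(
      design,
      saccade_type = protocol$saccade_type,
      direction_order = protocol$direction_order,
      gain_direction = ifelse(design$perturbation < 0, "down",
                              ifelse(design$perturbation > 0, "up",
                                     "baseline")),
      true_adaptation = trace$adaptation,
      true_gain = gain,
      amplitude = amplitude,
      peak_velocity = peak_velocity,
      duration_ms = duration_ms,
      latency_ms = latency,
      onset_ms = latency,
      start_x = start_x, start_y = start_y,
      blink = blink,
      injected_outlier = injected_outlier,
      seen_response = seen,
      stringsAsFactors = FALSE
    )

    if (gaze) {
      traces <- lapply(seq_len(n), function(i) {
        blink_ms <- if (blink[i]) c(latency[i] - 50, latency[i] + 20) else NULL
        synthesize_gaze_trial(
          start_pos = c(start_x[i], start_y[i]),
          target_pos = c(design$pre_target_x[i], design$pre_target_y[i]),
          executed_amplitude = max(amplitude[i], 0.5),
          latency_ms = latency[i],
          noise_sd_pos = 0.01,
          blink_ms = blink_ms,
          seed = seed + i
        )
      })
      attr(out, "gaze") <- traces
    }
    attr(out, "protocol") <- protocol
    attr(out, "seed") <- seed
    out
  })
}

#' Simulate a cohort across all four conditions
#'
#' Generates the full factorial study: each participant completes four
#' sessions (reactive/scanning crossed with down-up/up-down block order).
#' Participant-level process gains are drawn around condition means
#' (truncated at 0.02), and participant latency offsets add between-subject
#' variability. The default condition means for the process gains are the
#' package's calibration of a cohort in which reactive saccade adaptation is
#' carried about equally by both processes while scanning adaptation is
#' dominated by the slow process.
#'
#' @param n_participants number of participants (default 12).
#' @param gamma_reactive,gamma_scanning condition means `c(gamma_fast,
#'   gamma_slow)`.
#' @param gamma_sd between-participant sd of each process gain.
#' @param noise_sd observation noise sd (gain units).
#' @param latency_mean_ms named vector `c(reactive =, scanning =)` in ms.
#' @param latency_between_sd between-participant sd of mean latency (ms).
#' @param blink_rate,outlier_rate contamination rates per trial.
#' @param seed integer master seed.
#' @param ... passed on to [simulate_session()].
#' @return long data.frame of all trials with `participant` and `session`
#'   columns prepended; participant gains are attached as attribute
#'   `"participants"`.
#' @export
simulate_cohort <- function(n_participants = 12,
                            gamma_reactive = c(0.522, 0.630),
                            gamma_scanning = c(0.256, 0.762),
                            gamma_sd = 0.15,
                            noise_sd = 0.05,
                            latency_mean_ms = c(reactive = 193, scanning = 307),
                            latency_between_sd = 15,
                            blink_rate = 0.02,
                            outlier_rate = 0.01,
                            seed = 1,
                            ...) {
  conditions <- expand.grid(
    saccade_type = c("reactive", "scanning"),
    direction_order = c("down-up", "up-down"),
    stringsAsFactors = FALSE
  )
  draws <- with_seed_(seed, {
    list(
      gf_re = pmax(rnorm(n_participants, gamma_reactive[1], gamma_sd), 0.02),
      gs_re = pmax(rnorm(n_participants, gamma_reactive[2], gamma_sd), 0.02),
      gf_sc = pmax(rnorm(n_participants, gamma_scanning[1], gamma_sd), 0.02),
      gs_sc = pmax(rnorm(n_participants, gamma_scanning[2], gamma_sd), 0.02),
      lat_off = rnorm(n_participants, 0, latency_between_sd),
      session_seeds = sample.int(2^30, n_participants * nrow(conditions))
    )
  })
  sessions <- list()
  k <- 0
  for (p in seq_len(n_participants)) {
    for (ci in seq_len(nrow(conditions))) {
      k <- k + 1
      st <- conditions$saccade_type[ci]
      gf <- if (st == "reactive") draws$gf_re[p] else draws$gf_sc[p]
      gs <- if (st == "reactive") draws$gs_re[p] else draws$gs_sc[p]
      proto <- build_protocol(st, conditions$direction_order[ci])
      ses <- simulate_session(
        proto,
        params = dual_state_params(gamma_fast = gf, gamma_slow = gs),
        noise_sd = noise_sd,
        latency_mean_ms = latency_mean_ms[[st]] + draws$lat_off[p],
        blink_rate = blink_rate,
        outlier_rate = outlier_rate,
        seed = draws$session_seeds[k],
        ...
      )
      ses <- data.frame(participant = p, session = k, ses,
                        stringsAsFactors = FALSE)
      sessions[[k]] <- ses
    }
  }
  out <- do.call(rbind, sessions)
  rownames(out) <- NULL
  attr(out, "participants") <- data.frame(
    participant = seq_len(n_participants),
    gamma_fast_reactive = draws$gf_re, gamma_slow_reactive = draws$gs_re,
    gamma_fast_scanning = draws$gf_sc, gamma_slow_scanning = draws$gs_sc,
    latency_offset_ms = draws$lat_off
  )
  out
}
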