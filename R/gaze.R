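#' Main-sequence peak velocity
#'
#' Saturating amplitude/peak-velocity relation
#' `V(A) = vmax * (1 - exp(-A / c))` with conventional oculomotor defaults
#' (vmax = 500 deg/s, c = 14 deg).
#'
#' @param amplitude saccade amplitude (dva).
#' @param vmax asymptotic peak velocity (deg/s).
#' @param c amplitude constant (deg).
#' @return peak velocity in deg/s.
#' @export
main_sequence_velocity <- function(amplitude, vmax = 500, c = 14) {
  vmax * (1 - exp(-amplitude / c))
}

#' Default main-sequence parameters
#' @return list with `vmax` (deg/s) and `c` (deg).
#' @export
main_sequence_params <- function() list(vmax = 500, c = 14)

#' Synthesize a single-trial gaze recording
#'
#' Produces a uniformly sampled eye-position trace that fixates the start
#' position until `latency_ms`, then executes one saccade toward the target
#' with a minimum-jerk position profile. The saccade's amplitude equals
#' `executed_amplitude` along the start-to-target direction and its duration
#' is chosen so that the analytic peak velocity `15 A / (8 D)` of the
#' minimum-jerk profile equals the main-sequence value `V(A)`. Optionally a
#' blink (a run of invalid samples) is injected.
#'
#' @param start_pos,target_pos numeric `c(x, y)` in dva.
#' @param executed_amplitude saccade amplitude actually executed (dva, > 0);
#'   may differ from the start-target distance (adapted saccade).
#' @param latency_ms saccade onset relative to trace start (= flash onset).
#' @param main_seq_params list with `vmax` and `c`, see
#'   [main_sequence_params()].
#' @param sample_rate_hz sampling rate (default 1000 Hz).
#' @param noise_sd_pos additive positional noise sd (dva) on every sample.
#' @param tail_ms fixation time recorded after the saccade ends.
#' @param trace_ms optional total trace length (ms); must leave room for
#'   the latency plus the saccade itself.
#' @param blink_ms optional `c(start, end)` in ms marking invalid samples.
#' @param seed integer seed for the positional noise.
#' @return data.frame of class `gaze_recording` with columns `t_ms`,
#'   `x_dva`, `y_dva`, `valid`; attributes `sample_rate`, `onset_ms`,
#'   `offset_ms`, `amplitude`.
#' @export
synthesize_gaze_trial <- function(start_pos, target_pos, executed_amplitude,
                                  latency_ms = 200,
                                  main_seq_params = main_sequence_params(),
                                  sample_rate_hz = 1000,
                                  noise_sd_pos = 0.01,
                                  tail_ms = 200,
                                  trace_ms = NULL,
                                  blink_ms = NULL,
                                  seed = 1) {
  if (executed_amplitude <= 0) stop("executed_amplitude must be > 0")
  dvec <- target_pos - start_pos
  dlen <- sqrt(sum(dvec^2))
  if (dlen <= 0) stop("start and target positions coincide")
  u <- dvec / dlen

  vpk <- main_sequence_velocity(executed_amplitude,
                                main_seq_params$vmax, main_seq_params$c)
  dur_ms <- 1000 * 15 * executed_amplitude / (8 * vpk)
  total_ms <- if (is.null(trace_ms)) latency_ms + dur_ms + tail_ms else trace_ms
  if (latency_ms + dur_ms >= total_ms)
    stop("latency longer than the recorded trace")
  dt <- 1000 / sample_rate_hz
  t <- seq(0, total_ms, by = dt)

  # minimum-jerk displacement along the movement direction
  tau <- pmin(pmax((t - latency_ms) / dur_ms, 0), 1)
  s <- executed_amplitude * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  x <- start_pos[1] + s * u[1]
  y <- start_pos[2] + s * u[2]

  if (noise_sd_pos > 0) {
    noise <- with_seed_(seed, matrix(rnorm(2 * length(t), 0, noise_sd_pos), ncol = 2))
    x <- x + noise[, 1]
    y <- y + noise[, 2]
  }

  valid <- rep(TRUE, length(t))
  if (!is.null(blink_ms)) {
    bad <- t >= blink_ms[1] & t <= blink_ms[2]
    valid[bad] <- FALSE
    x[bad] <- NA_real_
    y[bad] <- NA_real_
  }

  out <- data.frame(t_ms = t, x_dva = x, y_dva = y, valid = valid)
  attr(out, "sample_rate") <- sample_rate_hz
  attr(out, "onset_ms") <- latency_ms
  attr(out, "offset_ms") <- latency_ms + dur_ms
  attr(out, "amplitude") <- executed_amplitude
  class(out) <- c("gaze_recording", "data.frame")
  out
}

#' Read / write a gaze trace in the plain CSV schema
#'
#' Columns: `t_ms, x_dva, y_dva, valid` with `valid = 0` marking blink or
#' otherwise missing samples.
#'
#' @param path file path.
#' @param trace a `gaze_recording`.
#' @param sample_rate_hz sampling rate to attach on read.
#' @return `read_gaze_csv` returns a `gaze_recording`.
#' @export
write_gaze_csv <- function(trace, path) {
  df <- as.data.frame(trace)
  df$valid <- as.integer(df$valid)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gaze_csv
#' @export
read_gaze_csv <- function(path, sample_rate_hz = NULL) {
  df <- read.table(path, sep = ",", header = TRUE)
  df$valid <- as.logical(df$valid)
  if (is.null(sample_rate_hz)) {
    sample_rate_hz <- 1000 / median(diff(df$t_ms))
  }
  attr(df, "sample_rate") <- sample_rate_hz
  class(df) <- c("gaze_recording", "data.frame")
  df
}
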