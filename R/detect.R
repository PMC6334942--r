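#' Smoothed gaze velocity
#'
#' Five-sample moving-window differentiator:
#' `v(i) = (p(i+2) + p(i+1) - p(i-1) - p(i-2)) / (6 * dt)` per component,
#' which both differentiates and low-pass filters the trace. The two edge
#' samples on either side are filled with the nearest interior value.
#' Invalid samples propagate `NA` through the stencil.
#'
#' @param trace a `gaze_recording` (>= 5 samples).
#' @return data.frame with columns `vx`, `vy` (deg/s per component) and `v`
#'   (Euclidean magnitude).
#' @export
compute_velocity <- function(trace) {
  n <- nrow(trace)
  if (n < 5) stop("need at least 5 samples to differentiate")
  sr <- attr(trace, "sample_rate")
  if (is.null(sr)) sr <- 1000 / median(diff(trace$t_ms))
  dt <- 1 / sr  # seconds

  five_point <- function(p) {
    v <- rep(NA_real_, n)
    i <- 3:(n - 2)
    v[i] <- (p[i + 2] + p[i + 1] - p[i - 1] - p[i - 2]) / (6 * dt)
    v[1:2] <- v[3]
    v[(n - 1):n] <- v[n - 2]
    v
  }
  vx <- five_point(trace$x_dva)
  vy <- five_point(trace$y_dva)
  data.frame(vx = vx, vy = vy, v = sqrt(vx^2 + vy^2))
}

#' Median-based robust velocity spread
#'
#' The median-estimator of the velocity standard deviation used to set
#' detection thresholds: `sigma = sqrt(median(v^2) - median(v)^2)`, computed
#' per component over finite samples. Insensitive to the saccades themselves,
#' which occupy a small minority of samples.
#'
#' @param v numeric velocity component (>= 2 finite samples).
#' @return the robust spread (deg/s); 0 for an all-identical input.
#' @export
robust_velocity_std <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) < 2) stop("need at least 2 finite samples")
  s2 <- median(v^2) - median(v)^2
  sqrt(max(s2, 0))
}

#' Detect saccades with the median velocity-threshold algorithm
#'
#' Computes component velocities with [compute_velocity()], sets elliptic
#' thresholds `eta = lambda * sigma` from the robust per-component spread,
#' and marks samples with `(vx/eta_x)^2 + (vy/eta_y)^2 > 1` as candidate
#' saccade samples. Maximal suprathreshold runs separated by less than
#' `merge_gap_ms` are merged, and runs shorter than `min_duration_ms` are
#' discarded. Runs never extend across invalid (blink) samples.
#'
#' @param trace a `gaze_recording`.
#' @param lambda_thresh threshold multiplier (default 6).
#' @param min_duration_ms minimum event duration (default 6 ms).
#' @param merge_gap_ms runs closer than this are merged (default 20 ms).
#' @return data.frame with one row per saccade: `onset_ms`, `offset_ms`,
#'   `duration_ms`, `amplitude` (Euclidean start-to-end, dva),
#'   `peak_velocity` (deg/s), `start_x`, `start_y`, `end_x`, `end_y`,
#'   sorted by onset. Zero rows when nothing crosses threshold.
#' @export
detect_saccades <- function(trace, lambda_thresh = 6,
                            min_duration_ms = 6, merge_gap_ms = 20) {
  vel <- compute_velocity(trace)
  sx <- robust_velocity_std(vel$vx)
  sy <- robust_velocity_std(vel$vy)
  if (sx == 0 || sy == 0)
    stop("degenerate trace: zero velocity spread, threshold undefined")
  eta_x <- lambda_thresh * sx
  eta_y <- lambda_thresh * sy

  crit <- (vel$vx / eta_x)^2 + (vel$vy / eta_y)^2 > 1
  crit[!is.finite(vel$vx) | !is.finite(vel$vy)] <- FALSE
  crit[!trace$valid] <- FALSE

  runs <- run_bounds_(crit)
  if (nrow(runs) == 0) return(empty_saccade_table_())

  # merge runs separated by a short subthreshold gap, never across a blink
  t <- trace$t_ms
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (k in 2:nrow(runs)) {
      last <- nrow(merged)
      gap_idx <- (merged$end[last] + 1):(runs$start[k] - 1)
      gap_ms <- t[runs$start[k]] - t[merged$end[last]]
      if (gap_ms < merge_gap_ms && all(trace$valid[gap_idx])) {
        merged$end[last] <- runs$end[k]
      } else {
        merged <- rbind(merged, runs[k, ])
      }
    }
  }

  dur <- t[merged$end] - t[merged$start]
  keep <- dur >= min_duration_ms
  merged <- merged[keep, , drop = FALSE]
  if (nrow(merged) == 0) return(empty_saccade_table_())

  out <- do.call(rbind, lapply(seq_len(nrow(merged)), function(k) {
    i0 <- merged$start[k]
    i1 <- merged$end[k]
    data.frame(
      onset_ms = t[i0], offset_ms = t[i1], duration_ms = t[i1] - t[i0],
      amplitude = sqrt((trace$x_dva[i1] - trace$x_dva[i0])^2 +
                         (trace$y_dva[i1] - trace$y_dva[i0])^2),
      peak_velocity = max(vel$v[i0:i1], na.rm = TRUE),
      start_x = trace$x_dva[i0], start_y = trace$y_dva[i0],
      end_x = trace$x_dva[i1], end_y = trace$y_dva[i1]
    )
  }))
  out[order(out$onset_ms), , drop = FALSE]
}

empty_saccade_table_ <- function() {
  data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
             duration_ms = numeric(0), amplitude = numeric(0),
             peak_velocity = numeric(0), start_x = numeric(0),
             start_y = numeric(0), end_x = numeric(0), end_y = numeric(0))
}

# start/end indices of maximal TRUE runs
run_bounds_ <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Saccade latency relative to the go signal
#'
#' Latency is onset minus the flash (go-signal) time. Negative latencies are
#' kept but flagged anticipatory.
#'
#' @param onset_ms saccade onset (ms), or a detection row with `onset_ms`.
#' @param go_signal_ms flash onset time (ms).
#' @return data.frame with `latency_ms` and logical `anticipatory`.
#' @export
saccade_latency <- function(onset_ms, go_signal_ms) {
  if (is.data.frame(onset_ms)) onset_ms <- onset_ms$onset_ms
  if (missing(go_signal_ms) || is.null(go_signal_ms) || any(is.na(go_signal_ms)))
    stop("missing go-signal time")
  lat <- onset_ms - go_signal_ms
  data.frame(latency_ms = lat, anticipatory = lat < 0)
}
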