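#' Trial rejection rules
#'
#' Flags invalid trials, testing the rules in a fixed order and recording
#' the first failing rule as the reason: (1) blink during the trial,
#' (2) saccade amplitude below `min_amplitude` (3 dva) or missing,
#' (3) amplitude more than `mad_crit` two-sided median absolute deviations
#' from the block median, (4) saccade start point more than `startpoint_max`
#' (1.5 dva) from the pre-saccadic target. The MAD is raw (unscaled) by
#' default; when it degenerates to 0 (more than half the block identical)
#' any nonzero deviation from the median is rejected. Blocks contributing
#' fewer than `min_block_n` amplitudes skip the MAD rule with a warning.
#'
#' Block statistics are computed per session and block over trials that
#' survive rules 1-2, so rejection is idempotent.
#'
#' @param trials trial table from [simulate_session()], [simulate_cohort()]
#'   or equivalent: needs `amplitude`, `blink`, `block`, `start_x/y`,
#'   `fix_target_x/y` (plus `session` for multi-session tables).
#' @param min_amplitude minimum amplitude (dva).
#' @param mad_crit MAD multiplier (default 3).
#' @param mad_constant scale factor applied to the MAD (1 = raw; 1.4826
#'   makes it a normal-consistent sigma estimate).
#' @param startpoint_max maximum start-point deviation (dva).
#' @param min_block_n minimum amplitudes per block for the MAD rule.
#' @return `trials` with logical `qc_valid` and character `qc_reason`
#'   (`NA` for valid trials); per-reason counts in attribute
#'   `"qc_counts"`.
#' @export
reject_trials <- function(trials, min_amplitude = 3, mad_crit = 3,
                          mad_constant = 1, startpoint_max = 1.5,
                          min_block_n = 4) {
  n <- nrow(trials)
  reason <- rep(NA_character_, n)

  if (!is.null(trials$blink)) reason[trials$blink] <- "blink"

  amp <- trials$amplitude
  low <- is.na(reason) & (!is.finite(amp) | amp < min_amplitude)
  reason[low] <- "amplitude_low"

  grp <- if ("session" %in% names(trials)) {
    interaction(trials$session, trials$block, drop = TRUE)
  } else {
    factor(trials$block)
  }
  for (g in levels(grp)) {
    idx <- which(grp == g & is.na(reason))
    if (length(idx) < min_block_n) {
      if (length(idx) > 0)
        warning("block ", g, " has fewer than ", min_block_n,
                " amplitudes; MAD rule skipped", call. = FALSE)
      next
    }
    a <- amp[idx]
    med <- median(a)
    madv <- mad_constant * median(abs(a - med))
    out <- abs(a - med) > mad_crit * madv
    reason[idx[out]] <- "amplitude_outlier"
  }

  if (all(c("start_x", "start_y", "fix_target_x", "fix_target_y") %in%
            names(trials))) {
    dev <- sqrt((trials$start_x - trials$fix_target_x)^2 +
                  (trials$start_y - trials$fix_target_y)^2)
    far <- is.na(reason) & is.finite(dev) & dev > startpoint_max
    reason[far] <- "startpoint_deviation"
  }

  trials$qc_valid <- is.na(reason)
  trials$qc_reason <- reason
  counts <- table(factor(reason, levels = c("blink", "amplitude_low",
                                            "amplitude_outlier",
                                            "startpoint_deviation")))
  attr(trials, "qc_counts") <- as.list(counts)
  trials
}

#' Convert amplitudes to gains normalized per hexagon direction
#'
#' Divides each trial's saccade amplitude by the median amplitude of the
#' valid first-block trials in the same hexagonal direction (per session).
#' Peak velocity and duration are normalized the same way by their own
#' block-1 per-direction medians. Invalid trials keep their row but get
#' `NA` gain; they are never dropped silently.
#'
#' @param trials QC'd trial table from [reject_trials()].
#' @return `trials` with added columns `gain`, `vel_gain`, `dur_gain`
#'   (`NA` on invalid trials).
#' @export
normalize_gain <- function(trials) {
  if (is.null(trials$qc_valid)) stop("run reject_trials() first")
  ses <- if ("session" %in% names(trials)) trials$session else rep(1L, nrow(trials))

  norm_one <- function(values, out_name) {
    res <- rep(NA_real_, nrow(trials))
    for (s in unique(ses)) {
      in_s <- ses == s
      for (d in sort(unique(trials$direction[in_s]))) {
        sel <- in_s & trials$direction == d
        base <- values[sel & trials$block == 1 & trials$qc_valid]
        if (length(base) == 0)
          stop("no valid baseline trials for direction ", d,
               if (length(unique(ses)) > 1) paste0(" in session ", s) else "")
        res[sel & trials$qc_valid] <- values[sel & trials$qc_valid] / median(base)
      }
    }
    res
  }
  trials$gain <- norm_one(trials$amplitude)
  if (!is.null(trials$peak_velocity))
    trials$vel_gain <- norm_one(trials$peak_velocity)
  if (!is.null(trials$duration_ms))
    trials$dur_gain <- norm_one(trials$duration_ms)
  trials
}

#' Running average over valid trials
#'
#' Centered moving mean with the window shrinking at the edges; invalid
#' (`NA`) entries are excluded from each window's mean, and if `blocks` is
#' supplied the window never crosses a block boundary (each block is
#' smoothed on its own). The default window of 6 matches the hexagonal
#' period, removing direction-specific amplitude differences.
#'
#' @param series numeric vector (invalid trials `NA`).
#' @param window window length (>= 1).
#' @param blocks optional block label per entry.
#' @return smoothed numeric vector, `NA` where a window holds no valid
#'   trial.
#' @export
running_average <- function(series, window = 6, blocks = NULL) {
  if (window < 1) stop("window must be >= 1")
  if (window > length(series)) stop("window longer than series")
  smooth_one <- function(x) {
    n <- length(x)
    lo <- floor((window - 1) / 2)
    hi <- ceiling((window - 1) / 2)
    vapply(seq_len(n), function(i) {
      w <- x[max(1, i - lo):min(n, i + hi)]
      w <- w[!is.na(w)]
      if (length(w) == 0) NA_real_ else mean(w)
    }, numeric(1))
  }
  if (is.null(blocks)) return(smooth_one(series))
  out <- rep(NA_real_, length(series))
  for (b in unique(blocks)) {
    sel <- blocks == b
    out[sel] <- smooth_one(series[sel])
  }
  out
}

#' Gain change across a block transition
#'
#' Mean gain over the first 6 trials of `to_block` minus the mean over the
#' last 6 trials of `from_block`, each computed over the valid trials among
#' those 6. Returns `NA` when either window contains no valid trial (the
#' participant is then excluded from the group statistic rather than
#' imputed).
#'
#' @param trials normalized trial table (single session) with `gain`,
#'   `block`, `trial_in_block`.
#' @param from_block,to_block block numbers (default 2 to 3).
#' @param window trials per side (default 6).
#' @return the change score (gain units) or `NA`.
#' @export
block_transition_change <- function(trials, from_block = 2, to_block = 3,
                                    window = 6) {
  if (is.null(trials$gain)) stop("run normalize_gain() first")
  if (!all(c(from_block, to_block) %in% trials$block))
    stop("both blocks must be present")
  a <- trials[trials$block == from_block, ]
  b <- trials[trials$block == to_block, ]
  a <- a[order(a$trial_in_block), ]
  b <- b[order(b$trial_in_block), ]
  last6 <- a$gain[a$trial_in_block > max(a$trial_in_block) - window]
  first6 <- b$gain[b$trial_in_block <= window]
  last6 <- last6[!is.na(last6)]
  first6 <- first6[!is.na(first6)]
  if (length(last6) == 0 || length(first6) == 0) return(NA_real_)
  mean(first6) - mean(last6)
}
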