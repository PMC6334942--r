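#' One-sample t-test
#'
#' `t = (mean - mu0) / (sd / sqrt(n))` with `n - 1` degrees of freedom,
#' two-tailed p, and Cohen's d = `(mean - mu0) / sd`.
#'
#' @param values numeric vector (n >= 2, finite).
#' @param mu0 null value (default 0).
#' @return object of class `test_result`: `t`, `dof`, `p`, `d`, `n`,
#'   `mean`, `sd`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 finite values")
  s <- sd(values)
  m <- mean(values)
  if (s == 0) {
    # no variance: t is 0/0 unless every value equals the null exactly
    if (m == mu0)
      return(structure(list(t = 0, dof = n - 1, p = 1, d = 0, n = n,
                            mean = m, sd = s), class = "test_result"))
    stop("zero variance; t undefined")
  }
  tval <- (m - mu0) / (s / sqrt(n))
  structure(list(t = tval, dof = n - 1, p = 2 * pt(-abs(tval), n - 1),
                 d = (m - mu0) / s, n = n, mean = m, sd = s),
            class = "test_result")
}

#' Paired t-test
#'
#' One-sample t-test on the paired differences `a - b` against zero;
#' incomplete pairs are dropped listwise.
#'
#' @param a,b paired numeric vectors of equal length.
#' @return a `test_result` (see [one_sample_t()]).
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 2) stop("need at least 2 complete pairs")
  one_sample_t(a[ok] - b[ok], 0)
}

#' Condition summary with t-based 95% CI
#'
#' @param values per-participant values (NA = missing).
#' @return list with `mean`, `ci_halfwidth` (`t_{0.975, n-1} * SEM`), `n`,
#'   `values`.
#' @export
condition_summary <- function(values) {
  v <- values[is.finite(values)]
  n <- length(v)
  hw <- if (n >= 2) qt(0.975, n - 1) * sd(v) / sqrt(n) else NA_real_
  list(mean = if (n > 0) mean(v) else NA_real_, ci_halfwidth = hw, n = n,
       values = values)
}

# per-participant mean of `value` within subsets, returned as a wide
# data.frame participant x cell
participant_cell_means_ <- function(trials, value, cells) {
  agg <- aggregate(trials[[value]],
                   by = c(list(participant = trials$participant),
                          lapply(cells, function(cn) trials[[cn]])),
                   FUN = mean, na.rm = TRUE)
  names(agg) <- c("participant", cells, "value")
  agg$value[is.nan(agg$value)] <- NA_real_
  agg
}

#' Latency summary per condition
#'
#' Mean saccade latency per participant in the given block (valid trials
#' only), summarised per saccade type x gain direction with t-based 95%
#' CIs.
#'
#' @param trials QC'd cohort trial table (needs `participant`,
#'   `saccade_type`, `gain_direction`, `latency_ms`, `qc_valid`, `block`).
#' @param block block to summarise (default 2, the first adaptation block).
#' @return list with `per_participant` (long data.frame) and `conditions`
#'   (data.frame with mean, CI half-width, n per cell).
#' @export
latency_summary <- function(trials, block = 2) {
  sub <- trials[trials$block == block & trials$qc_valid, ]
  if (nrow(sub) == 0) stop("no valid trials in block ", block)
  pp <- participant_cell_means_(sub, "latency_ms",
                                c("saccade_type", "gain_direction"))
  cells <- unique(pp[, c("saccade_type", "gain_direction")])
  conds <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- pp$saccade_type == cells$saccade_type[i] &
      pp$gain_direction == cells$gain_direction[i]
    s <- condition_summary(pp$value[sel])
    data.frame(cells[i, ], mean = s$mean, ci_halfwidth = s$ci_halfwidth,
               n = s$n)
  }))
  rownames(conds) <- NULL
  list(per_participant = pp, conditions = conds)
}

#' Fit dual-state gains per participant and condition
#'
#' Runs [fit_dual_state_gains()] on the second block (first adaptation
#' block) of every participant x saccade type x direction order cell of a
#' normalized cohort table.
#'
#' @param trials cohort table after [reject_trials()] and
#'   [normalize_gain()].
#' @param rates fixed rates ([dual_state_params()]).
#' @param block fitted block (default 2).
#' @param ... passed to [fit_dual_state_gains()].
#' @return data.frame with one row per fit: `participant`, `saccade_type`,
#'   `direction_order`, `gain_direction`, `gamma_fast`, `gamma_slow`,
#'   `sse`, `n_valid`; failed fits (too few valid trials) are dropped with
#'   a message.
#' @export
fit_cohort_dual_state <- function(trials, rates = dual_state_params(),
                                  block = 2, ...) {
  cells <- unique(trials[, c("participant", "saccade_type",
                             "direction_order")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- trials$participant == cells$participant[i] &
      trials$saccade_type == cells$saccade_type[i] &
      trials$direction_order == cells$direction_order[i] &
      trials$block == block
    sub <- trials[sel, ]
    sub <- sub[order(sub$trial_in_block), ]
    fit <- tryCatch(
      fit_dual_state_gains(sub$gain, sub$perturbation, rates = rates, ...),
      error = function(e) {
        message("dual-state fit skipped (participant ",
                cells$participant[i], ", ", cells$saccade_type[i], " ",
                cells$direction_order[i], "): ", conditionMessage(e))
        NULL
      })
    if (is.null(fit)) next
    rows[[length(rows) + 1]] <- data.frame(
      cells[i, ],
      gain_direction = sub$gain_direction[1],
      gamma_fast = fit$gamma_fast, gamma_slow = fit$gamma_slow,
      sse = fit$sse, n_valid = fit$n_valid
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fast/slow process-gain contrasts
#'
#' From per-participant dual-state fits in all four conditions: averages
#' the two gain-direction conditions within each saccade type (ratios are
#' averaged per participant), then computes (a) one-sample t-tests of the
#' slow ratio against 0.5 per saccade type and (b) paired t-tests of the
#' reactive - scanning difference per process gain. Participants missing a
#' condition are dropped from the affected contrast with a message.
#'
#' @param fits data.frame from [fit_cohort_dual_state()].
#' @return list with `per_participant` (wide data.frame), `slow_ratio`
#'   (summary + test per saccade type) and `process_difference` (summary +
#'   test per process, reactive minus scanning).
#' @export
process_gain_contrasts <- function(fits) {
  fits$slow_ratio <- slow_ratio(fits$gamma_fast, fits$gamma_slow)
  avg <- aggregate(fits[, c("gamma_fast", "gamma_slow", "slow_ratio")],
                   by = list(participant = fits$participant,
                             saccade_type = fits$saccade_type),
                   FUN = mean, na.rm = TRUE)
  n_cond <- aggregate(list(n = fits$gamma_fast),
                      by = list(participant = fits$participant,
                                saccade_type = fits$saccade_type),
                      FUN = length)
  avg <- merge(avg, n_cond)
  incomplete <- avg$participant[avg$n < 2]
  if (length(incomplete) > 0)
    message("participant(s) ", paste(unique(incomplete), collapse = ", "),
            " missing a gain-direction condition; averages use the ",
            "available condition")

  wide <- reshape(avg[, c("participant", "saccade_type", "gamma_fast",
                          "gamma_slow", "slow_ratio")],
                  idvar = "participant", timevar = "saccade_type",
                  direction = "wide")

  slow_ratio_tests <- lapply(c("reactive", "scanning"), function(st) {
    v <- wide[[paste0("slow_ratio.", st)]]
    list(saccade_type = st, summary = condition_summary(v),
         test = one_sample_t(v[is.finite(v)], 0.5))
  })
  names(slow_ratio_tests) <- c("reactive", "scanning")

  proc_diff <- lapply(c("gamma_fast", "gamma_slow"), function(pr) {
    a <- wide[[paste0(pr, ".reactive")]]
    b <- wide[[paste0(pr, ".scanning")]]
    d <- a - b
    list(process = pr, summary = condition_summary(d),
         test = paired_t(a, b))
  })
  names(proc_diff) <- c("fast", "slow")

  list(per_participant = wide, slow_ratio = slow_ratio_tests,
       process_difference = proc_diff)
}

#' Kinematic change over the end of the first adaptation block
#'
#' Per participant and condition, the median normalized amplitude, peak
#' velocity and duration (each a ratio to its per-direction block-1
#' median) minus 1 over the last `window` trials of the given block;
#' summarised per saccade type x gain direction.
#'
#' @param trials normalized cohort table (needs `gain`, `vel_gain`,
#'   `dur_gain`).
#' @param block block analysed (default 2).
#' @param window trailing trials used (default 16).
#' @param min_valid minimum valid trials in the window (default 3).
#' @return list with `per_participant` (long) and `conditions` (summary
#'   per cell and measure).
#' @export
kinematic_change_summary <- function(trials, block = 2, window = 16,
                                     min_valid = 3) {
  measures <- c(amplitude = "gain", velocity = "vel_gain",
                duration = "dur_gain")
  cells <- unique(trials[, c("participant", "saccade_type",
                             "direction_order")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- trials$participant == cells$participant[i] &
      trials$saccade_type == cells$saccade_type[i] &
      trials$direction_order == cells$direction_order[i] &
      trials$block == block
    sub <- trials[sel, ]
    sub <- sub[sub$trial_in_block > max(sub$trial_in_block) - window, ]
    for (m in names(measures)) {
      v <- sub[[measures[[m]]]]
      v <- v[is.finite(v)]
      rows[[length(rows) + 1]] <- data.frame(
        cells[i, ], gain_direction = sub$gain_direction[1], measure = m,
        change = if (length(v) >= min_valid) median(v) - 1 else NA_real_
      )
    }
  }
  pp <- do.call(rbind, rows)
  rownames(pp) <- NULL
  cellsum <- unique(pp[, c("saccade_type", "gain_direction", "measure")])
  conds <- do.call(rbind, lapply(seq_len(nrow(cellsum)), function(i) {
    sel <- pp$saccade_type == cellsum$saccade_type[i] &
      pp$gain_direction == cellsum$gain_direction[i] &
      pp$measure == cellsum$measure[i]
    s <- condition_summary(pp$change[sel])
    data.frame(cellsum[i, ], mean = s$mean, ci_halfwidth = s$ci_halfwidth,
               n = s$n)
  }))
  rownames(conds) <- NULL
  list(per_participant = pp, conditions = conds)
}

#' Displacement-awareness summary
#'
#' Proportion of trials reported as seen, per block and condition, with
#' no-response trials excluded from the denominator, plus a 6-trial
#' running-average seen series per session for plotting.
#'
#' @param trials cohort trial table with `seen_response`.
#' @return list with `proportions` (data.frame per saccade type x gain
#'   direction x block) and `series` (list per session of the smoothed
#'   binary series).
#' @export
awareness_summary <- function(trials) {
  resp <- trials$seen_response
  known <- resp %in% c("seen", "unseen")
  cells <- unique(trials[, c("saccade_type", "gain_direction", "block")])
  cells <- cells[order(cells$saccade_type, cells$gain_direction,
                       cells$block), ]
  props <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- trials$saccade_type == cells$saccade_type[i] &
      trials$gain_direction == cells$gain_direction[i] &
      trials$block == cells$block[i] & known
    n <- sum(sel)
    if (n == 0)
      warning("no scored responses for ", cells$saccade_type[i], "/",
              cells$gain_direction[i], " block ", cells$block[i])
    data.frame(cells[i, ],
               prop_seen = if (n > 0) mean(resp[sel] == "seen") else NA_real_,
               n = n)
  }))
  rownames(props) <- NULL

  series <- NULL
  if ("session" %in% names(trials)) {
    series <- lapply(split(trials, trials$session), function(s) {
      x <- ifelse(s$seen_response == "seen", 1,
                  ifelse(s$seen_response == "unseen", 0, NA_real_))
      running_average(x, window = 6, blocks = s$block)
    })
  }
  list(proportions = props, series = series)
}

#' Repeated-measures ANOVA pass-through
#'
#' Delegates a fully within-participant two-factor design to [stats::aov()]
#' with an `Error(participant/(f1*f2))` stratum and reports F, p and
#' partial eta squared per term.
#'
#' @param data long data.frame of one value per participant x cell.
#' @param dv,id column names of the value and participant id.
#' @param within character vector of one or two within-factor column names.
#' @return data.frame with `term`, `df1`, `df2`, `F`, `p`, `eta_p_sq`.
#' @export
rm_anova <- function(data, dv, id, within) {
  data[[id]] <- factor(data[[id]])
  for (w in within) data[[w]] <- factor(data[[w]])
  rhs <- paste(within, collapse = "*")
  form <- stats::as.formula(
    paste0(dv, " ~ ", rhs, " + Error(", id, "/(", rhs, "))"))
  fit <- aov(form, data = data)
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    terms <- rownames(tab)
    res_i <- grep("Residuals", terms)
    if (length(res_i) == 0) next
    ss_err <- tab[res_i, "Sum Sq"]
    df_err <- tab[res_i, "Df"]
    for (k in seq_along(terms)) {
      if (k %in% res_i) next
      rows[[length(rows) + 1]] <- data.frame(
        term = trimws(terms[k]), df1 = tab[k, "Df"], df2 = df_err,
        F = tab[k, "F value"], p = tab[k, "Pr(>F)"],
        eta_p_sq = tab[k, "Sum Sq"] / (tab[k, "Sum Sq"] + ss_err)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
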