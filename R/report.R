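#' Per-participant gain series for one condition
#'
#' Extracts the participants x trials gain matrix of one block for a given
#' saccade type and gain direction, as needed by
#' [bootstrap_exponential()]. Rows follow sorted participant ids.
#'
#' @param trials normalized cohort table.
#' @param saccade_type,gain_direction condition selectors.
#' @param block block to extract (default 2).
#' @return numeric matrix, participants x trials, `NA` for invalid trials.
#' @export
condition_gain_matrix <- function(trials, saccade_type, gain_direction,
                                  block = 2) {
  sel <- trials$saccade_type == saccade_type &
    trials$gain_direction == gain_direction & trials$block == block
  sub <- trials[sel, ]
  if (nrow(sub) == 0) stop("no trials for that condition")
  parts <- sort(unique(trials$participant))
  Tn <- max(sub$trial_in_block)
  m <- matrix(NA_real_, length(parts), Tn)
  for (i in seq_along(parts)) {
    s <- sub[sub$participant == parts[i], ]
    m[i, s$trial_in_block] <- s$gain
  }
  rownames(m) <- parts
  m
}

#' Block-transition change per participant
#'
#' Applies [block_transition_change()] to every participant x condition
#' session of a cohort table and tests the reactive - scanning difference
#' per direction order with a paired t-test.
#'
#' @param trials normalized cohort table.
#' @param from_block,to_block transition analysed (default 2 to 3).
#' @return list with `per_participant` (long data.frame of change scores)
#'   and `tests` (one paired `test_result` per direction order, reactive
#'   vs scanning).
#' @export
cohort_block_transitions <- function(trials, from_block = 2, to_block = 3) {
  cells <- unique(trials[, c("participant", "saccade_type",
                             "direction_order")])
  cells$change <- vapply(seq_len(nrow(cells)), function(i) {
    sel <- trials$participant == cells$participant[i] &
      trials$saccade_type == cells$saccade_type[i] &
      trials$direction_order == cells$direction_order[i]
    block_transition_change(trials[sel, ], from_block, to_block)
  }, numeric(1))
  tests <- lapply(unique(cells$direction_order), function(ord) {
    w <- reshape(cells[cells$direction_order == ord,
                       c("participant", "saccade_type", "change")],
                 idvar = "participant", timevar = "saccade_type",
                 direction = "wide")
    paired_t(w$change.reactive, w$change.scanning)
  })
  names(tests) <- unique(cells$direction_order)
  list(per_participant = cells, tests = tests)
}

#' Timescale bootstrap per gain direction
#'
#' For each gain direction, compares the exponential timescale of reactive
#' vs scanning adaptation in the given block with the paired participant
#' bootstrap.
#'
#' @param trials normalized cohort table.
#' @param n_folds bootstrap folds.
#' @param seed integer seed.
#' @param block fitted block (default 2).
#' @return named list (`down`, `up`) of `bootstrap_result` objects.
#' @export
cohort_timescale_bootstrap <- function(trials, n_folds = 2000, seed = 1,
                                       block = 2) {
  out <- list()
  for (gd in c("down", "up")) {
    mats <- list(
      reactive = condition_gain_matrix(trials, "reactive", gd, block),
      scanning = condition_gain_matrix(trials, "scanning", gd, block)
    )
    out[[gd]] <- bootstrap_exponential(mats, n_folds = n_folds,
                                       seed = seed + match(gd, c("down", "up")))
  }
  out
}

test_result_list_ <- function(tr) {
  list(t = tr$t, dof = tr$dof, p = tr$p, cohens_d = tr$d, n = tr$n,
       mean = tr$mean)
}

#' Assemble the full analysis report
#'
#' Runs every summary stage on a QC'd, normalized cohort table and returns
#' one machine-readable bundle: latencies (with rm-ANOVA pass-through),
#' block-transition changes, timescale bootstrap comparisons, dual-state
#' process-gain contrasts, kinematic changes and awareness proportions.
#' Identical inputs give byte-identical JSON output.
#'
#' @param trials cohort table after [reject_trials()] and
#'   [normalize_gain()].
#' @param n_folds bootstrap folds for the timescale comparison.
#' @param seed integer seed (bootstrap resampling).
#' @param out_dir optional directory; when given, writes `report.json` and
#'   per-section TSV tables there.
#' @return the report as a nested list (invisibly when `out_dir` is set).
#' @export
build_report <- function(trials, n_folds = 2000, seed = 1, out_dir = NULL) {
  needed <- c("participant", "saccade_type", "direction_order", "block",
              "trial_in_block", "gain", "qc_valid", "latency_ms")
  miss <- setdiff(needed, names(trials))
  if (length(miss) > 0)
    stop("input table is missing columns: ", paste(miss, collapse = ", "))

  lat <- latency_summary(trials, block = 2)
  lat_anova <- rm_anova(lat$per_participant, dv = "value",
                        id = "participant",
                        within = c("saccade_type", "gain_direction"))

  trans <- cohort_block_transitions(trials)
  boots <- cohort_timescale_bootstrap(trials, n_folds = n_folds, seed = seed)
  fits <- fit_cohort_dual_state(trials)
  contrasts <- process_gain_contrasts(fits)
  kin <- kinematic_change_summary(trials)
  aware <- awareness_summary(trials)

  qc_counts <- attr(trials, "qc_counts")
  if (is.null(qc_counts)) {
    tab <- table(factor(trials$qc_reason,
                        levels = c("blink", "amplitude_low",
                                   "amplitude_outlier",
                                   "startpoint_deviation")))
    qc_counts <- as.list(tab)
  }

  report <- list(
    n_participants = length(unique(trials$participant)),
    n_trials = nrow(trials),
    qc = list(counts = qc_counts,
              prop_valid = mean(trials$qc_valid)),
    latency = list(
      conditions = lat$conditions,
      anova = lat_anova
    ),
    block_transition = list(
      per_participant = trans$per_participant,
      tests = lapply(trans$tests, test_result_list_)
    ),
    timescale_bootstrap = lapply(boots, function(b) {
      list(n_folds = b$n_folds,
           comparisons = b$comparisons)
    }),
    dual_state = list(
      fits = fits,
      slow_ratio = lapply(contrasts$slow_ratio, function(x) {
        list(saccade_type = x$saccade_type, mean = x$summary$mean,
             ci_halfwidth = x$summary$ci_halfwidth, n = x$summary$n,
             test_vs_0.5 = test_result_list_(x$test))
      }),
      process_difference = lapply(contrasts$process_difference, function(x) {
        list(process = x$process, mean = x$summary$mean,
             ci_halfwidth = x$summary$ci_halfwidth, n = x$summary$n,
             test = test_result_list_(x$test))
      })
    ),
    kinematics = kin$conditions,
    awareness = aware$proportions
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    write_tsv_ <- function(df, name) {
      write.table(df, file.path(out_dir, name), sep = "\t",
                  row.names = FALSE, quote = FALSE)
    }
    write_tsv_(lat$conditions, "latency_conditions.tsv")
    write_tsv_(trans$per_participant, "block_transitions.tsv")
    write_tsv_(fits, "dual_state_fits.tsv")
    write_tsv_(kin$conditions, "kinematic_changes.tsv")
    write_tsv_(aware$proportions, "awareness_proportions.tsv")
    return(invisible(report))
  }
  report
}
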