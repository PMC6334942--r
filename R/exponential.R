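#' Exponential adaptation time-course model
#'
#' Predicted gain at trial `t`:
#' `fit(t) = 1 - alpha * (1 - exp(-t / beta))`, which starts at 1 for
#' `t = 0` and approaches `1 - alpha` asymptotically; `alpha` is the
#' asymptotic gain-change magnitude (negative for gain-up adaptation) and
#' `beta` the timescale in trials. Separating magnitude and timescale keeps
#' the `beta` estimate unaffected by how much adaptation occurred.
#' `form = "printed"` selects the algebraic variant
#' `(1 - alpha) * (exp(-t / beta) - 1) + 1`, which instead approaches
#' `alpha`.
#'
#' @param t trial index (0 = first trial of the fitted block).
#' @param alpha gain-change magnitude (unitless).
#' @param beta timescale in trials (> 0).
#' @param form `"text"` (default) or `"printed"`.
#' @return predicted gain.
#' @export
exp_model <- function(t, alpha, beta, form = c("text", "printed")) {
  form <- match.arg(form)
  if (beta <= 0) stop("beta must be > 0")
  g <- 1 - exp(-t / beta)
  if (form == "text") 1 - alpha * g else 1 - g + alpha * g
}

#' Least-squares exponential timescale fit
#'
#' Fits [exp_model()] to per-trial gains. `alpha` is linear in the model
#' given `beta` and is profiled out in closed form; `beta` is searched over
#' a log-spaced grid on `(beta_min, 10 N]` and refined by golden-section
#' search (SSE tolerance ~1e-10), which makes the fit deterministic and
#' robust to initialisation. Trial indices are shifted so the first fitted
#' trial sits at `t = 0`, making the fit invariant to a constant index
#' offset.
#'
#' @param trial_indices trial indices (any constant offset allowed).
#' @param gains observed gains; `NA` = invalid trial, dropped.
#' @param form model variant, see [exp_model()].
#' @param beta_min,beta_max search bounds for `beta` (trials); default upper
#'   bound is 10 times the number of trials.
#' @return object of class `exp_fit`: `alpha`, `beta`, `sse`, `n_trials`,
#'   `converged` (FALSE when the optimum sits on the search boundary or the
#'   data are constant so `beta` is unidentifiable), `form`.
#' @export
fit_exponential <- function(trial_indices, gains, form = c("text", "printed"),
                            beta_min = 1e-2, beta_max = NULL) {
  form <- match.arg(form)
  ok <- is.finite(trial_indices) & is.finite(gains)
  if (sum(ok) < 5) stop("need at least 5 valid points")
  t <- trial_indices[ok] - min(trial_indices[ok])
  y <- gains[ok]
  if (is.null(beta_max)) beta_max <- 10 * length(y)

  fit <- cpp_fit_exp(t, y, beta_min, beta_max, if (form == "text") 0L else 1L,
                     40L)
  if (fit$degenerate) {
    return(structure(list(alpha = 0, beta = NA_real_, sse = fit$sse,
                          n_trials = fit$n, converged = FALSE, form = form),
                     class = "exp_fit"))
  }
  structure(list(alpha = fit$alpha, beta = fit$beta, sse = fit$sse,
                 n_trials = fit$n, converged = !fit$edge, form = form),
            class = "exp_fit")
}

#' Paired participant bootstrap for exponential fits
#'
#' Within each fold, participants are resampled with replacement and the
#' same resample is applied to every condition; each condition's resampled
#' series are averaged across participants and [fit_exponential()] is run
#' on the average. Per-fold parameter differences between conditions give
#' two-tailed bootstrap p-values: twice the smaller of the fractions of
#' differences below and above zero, floored at `2 / n_folds`.
#'
#' @param series_by_condition named list of numeric matrices, one per
#'   condition, participants in rows (same order everywhere) and trials in
#'   columns; `NA` = invalid trial.
#' @param n_folds number of bootstrap folds (default 1e5 for inference;
#'   desk-scale analyses use 1e3-2e3).
#' @param seed integer seed for the resampling.
#' @param form model variant, see [exp_model()].
#' @param beta_min,beta_max passed to the fit.
#' @return object of class `bootstrap_result`: `folds` (data.frame of
#'   per-fold `alpha_<cond>`, `beta_<cond>`), `comparisons` (data.frame per
#'   condition pair and parameter with median difference and two-tailed
#'   `p`), `n_folds`, `seed`.
#' @export
bootstrap_exponential <- function(series_by_condition, n_folds = 1e5,
                                  seed = 1, form = c("text", "printed"),
                                  beta_min = 1e-2, beta_max = NULL) {
  form <- match.arg(form)
  stopifnot(is.list(series_by_condition), length(series_by_condition) >= 1)
  mats <- lapply(series_by_condition, as.matrix)
  P <- nrow(mats[[1]])
  if (P < 2) stop("need at least 2 participants")
  if (any(vapply(mats, nrow, 1L) != P))
    stop("all conditions must have the same participants")
  Tn <- ncol(mats[[1]])
  if (is.null(beta_max)) beta_max <- 10 * Tn
  cnames <- names(mats)
  if (is.null(cnames)) cnames <- paste0("cond", seq_along(mats))

  idx <- with_seed_(seed,
                    matrix(sample.int(P, n_folds * P, replace = TRUE),
                           nrow = n_folds))
  est <- cpp_boot_exp(mats, idx, 0:(Tn - 1), beta_min, beta_max,
                      if (form == "text") 0L else 1L, 40L)
  folds <- as.data.frame(est)
  names(folds) <- as.vector(rbind(paste0("alpha_", cnames),
                                  paste0("beta_", cnames)))

  comparisons <- NULL
  if (length(mats) >= 2) {
    pairs <- utils::combn(seq_along(mats), 2)
    rows <- list()
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      for (par in c("alpha", "beta")) {
        d <- folds[[paste0(par, "_", cnames[b])]] -
          folds[[paste0(par, "_", cnames[a])]]
        rows[[length(rows) + 1]] <- data.frame(
          parameter = par,
          comparison = paste0(cnames[b], " - ", cnames[a]),
          median_diff = median(d),
          p = boot_p_(d, n_folds)
        )
      }
    }
    comparisons <- do.call(rbind, rows)
  }
  structure(list(folds = folds, comparisons = comparisons,
                 n_folds = n_folds, seed = seed, form = form),
            class = "bootstrap_result")
}

# two-tailed bootstrap p from a vector of paired differences; exact ties
# count half to each side so identical conditions give p = 1
boot_p_ <- function(d, n_folds) {
  below <- mean(d < 0) + 0.5 * mean(d == 0)
  above <- mean(d > 0) + 0.5 * mean(d == 0)
  p <- 2 * min(below, above)
  max(min(p, 1), 2 / n_folds)
}
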