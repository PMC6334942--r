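#' Dual-state model parameters
#'
#' Learning and retention rates of the fast and slow adaptation processes,
#' plus the process gains scaling each process's contribution to output.
#' Defaults are the canonical fixed rates used for fitting: fast learning
#' 0.21, fast retention 0.59, slow learning 0.02, slow retention 0.992.
#'
#' @param alpha_fast,alpha_slow learning rates (per trial, in (0, 1]).
#' @param beta_fast,beta_slow retention rates (in (0, 1)).
#' @param gamma_fast,gamma_slow process gains (unitless, finite).
#' @return object of class `dual_state_params`.
#' @export
dual_state_params <- function(alpha_fast = 0.21, beta_fast = 0.59,
                              alpha_slow = 0.02, beta_slow = 0.992,
                              gamma_fast = 1, gamma_slow = 1) {
  if (!(alpha_fast > 0 && alpha_fast <= 1) || !(alpha_slow > 0 && alpha_slow <= 1))
    stop("learning rates must lie in (0, 1]")
  if (!(beta_fast > 0 && beta_fast < 1) || !(beta_slow > 0 && beta_slow < 1))
    stop("retention rates must lie in (0, 1)")
  if (alpha_fast <= alpha_slow)
    stop("the fast process must learn faster than the slow process")
  if (beta_fast >= beta_slow)
    stop("the fast process must retain less than the slow process")
  if (!is.finite(gamma_fast) || !is.finite(gamma_slow))
    stop("process gains must be finite")
  structure(
    list(alpha_fast = alpha_fast, beta_fast = beta_fast,
         alpha_slow = alpha_slow, beta_slow = beta_slow,
         gamma_fast = gamma_fast, gamma_slow = gamma_slow),
    class = "dual_state_params"
  )
}

#' Simulate the dual-state adaptation model
#'
#' Runs the two-process recursion over a perturbation schedule. On each
#' trial the error drives both processes,
#' `state(i) = alpha * error(i) + beta * state(i-1)`, and the output is the
#' gain-weighted sum `adaptation(i) = gamma_fast * state_fast(i) +
#' gamma_slow * state_slow(i)`. All quantities are in relative-gain deviation
#' units (baseline gain = 1), so a gain-down perturbation is negative.
#'
#' In the default closed-loop mode the error is
#' `error(i) = p(i) - adaptation(i-1)`: the model corrects its own output.
#' With `error_mode = "observed"` the previous trial's measured gain
#' deviation (`observed_gains - 1`) is used instead, falling back to the
#' model output on trials with missing observations.
#'
#' @param perturbations numeric vector of per-trial perturbations `p(i)`
#'   (relative post-displacement gain minus 1).
#' @param params a [dual_state_params()] object.
#' @param error_mode `"closed"` (default) or `"observed"`.
#' @param observed_gains observed per-trial gains, required for
#'   `error_mode = "observed"`; `NA` marks invalid trials.
#' @return data.frame of class `dual_state_trace` with columns `trial`,
#'   `perturbation`, `error`, `state_fast`, `state_slow`, `adaptation`; the
#'   parameters are attached as attribute `"params"`.
#' @export
simulate_dual_state <- function(perturbations,
                                params = dual_state_params(),
                                error_mode = c("closed", "observed"),
                                observed_gains = NULL) {
  error_mode <- match.arg(error_mode)
  if (length(perturbations) == 0) stop("empty perturbation sequence")
  stopifnot(inherits(params, "dual_state_params"))
  obs_dev <- numeric(0)
  if (error_mode == "observed") {
    if (is.null(observed_gains) || length(observed_gains) != length(perturbations))
      stop("error_mode = \"observed\" needs observed_gains of matching length")
    obs_dev <- observed_gains - 1
  }
  m <- cpp_dual_state(as.numeric(perturbations),
                      params$alpha_fast, params$beta_fast,
                      params$alpha_slow, params$beta_slow,
                      params$gamma_fast, params$gamma_slow,
                      error_mode == "closed", obs_dev)
  out <- data.frame(
    trial = seq_along(perturbations),
    perturbation = as.numeric(perturbations),
    error = m[, 1], state_fast = m[, 2], state_slow = m[, 3],
    adaptation = m[, 4]
  )
  attr(out, "params") <- params
  class(out) <- c("dual_state_trace", "data.frame")
  out
}

#' Steady state of the dual-state recursion under constant perturbation
#'
#' Analytic fixed point of the closed-loop coupled recursion for a constant
#' perturbation `p`: solving `xf = af (p - y) + bf xf`,
#' `xs = as (p - y) + bs xs`, `y = gf xf + gs xs` gives
#' `y* = p * S / (1 + S)` with
#' `S = gf af / (1 - bf) + gs as / (1 - bs)`.
#'
#' @param p constant perturbation (gain units).
#' @param params a [dual_state_params()] object.
#' @return the asymptotic adaptation level (gain units).
#' @export
dual_state_fixed_point <- function(p, params = dual_state_params()) {
  stopifnot(inherits(params, "dual_state_params"))
  S <- params$gamma_fast * params$alpha_fast / (1 - params$beta_fast) +
    params$gamma_slow * params$alpha_slow / (1 - params$beta_slow)
  p * S / (1 + S)
}

#' Add observation noise to a simulated adaptation trace
#'
#' Observed gain on trial `i` is `1 + adaptation(i) + e(i)` with
#' `e(i) ~ N(0, noise_sd)` i.i.d. The draw is seeded and leaves the caller's
#' RNG state untouched.
#'
#' @param trace a `dual_state_trace` from [simulate_dual_state()].
#' @param noise_sd observation noise standard deviation (gain units, >= 0).
#' @param seed integer seed.
#' @return numeric vector of observed gains.
#' @export
simulate_observed_gains <- function(trace, noise_sd = 0.05, seed = 1) {
  stopifnot(inherits(trace, "dual_state_trace"))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  n <- nrow(trace)
  noise <- if (noise_sd > 0) {
    with_seed_(seed, rnorm(n, 0, noise_sd))
  } else {
    numeric(n)
  }
  1 + trace$adaptation + noise
}
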