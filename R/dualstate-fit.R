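#' Fit dual-state process gains to an adaptation block
#'
#' With the learning and retention rates fixed (defaults 0.21/0.59 fast,
#' 0.02/0.992 slow), finds the non-negative process gains
#' `(gamma_fast, gamma_slow)` minimising the sum of squared differences
#' between the model output and the observed gain deviations
#' (`gains - 1`). Invalid trials (`NA`) are excluded from the loss but the
#' state recursion still advances on every trial. The objective is
#' minimised by bounded quasi-Newton search from several starts, then
#' polished with projected Gauss-Newton steps.
#'
#' @param gains observed per-trial gains of the fitted block (`NA` =
#'   invalid trial).
#' @param perturbation per-trial perturbation `p(i)` (gain units), same
#'   length; must not be all zero.
#' @param rates a [dual_state_params()] object supplying the fixed rates
#'   (its gamma entries are ignored).
#' @param error_mode `"closed"` (default) or `"observed"`, see
#'   [simulate_dual_state()].
#' @param min_valid minimum number of valid trials (default 10).
#' @return object of class `dual_state_fit`: `gamma_fast`, `gamma_slow`,
#'   `rates`, `sse`, `n_valid`, `fitted` (the model trace at the optimum),
#'   `error_mode`.
#' @export
fit_dual_state_gains <- function(gains, perturbation,
                                 rates = dual_state_params(),
                                 error_mode = c("closed", "observed"),
                                 min_valid = 10) {
  error_mode <- match.arg(error_mode)
  stopifnot(inherits(rates, "dual_state_params"))
  if (length(gains) != length(perturbation))
    stop("gains and perturbation must have the same length")
  if (all(perturbation == 0)) stop("perturbation is all zero")
  ydev <- gains - 1
  n_valid <- sum(is.finite(ydev))
  if (n_valid < min_valid)
    stop("need at least ", min_valid, " valid trials")
  ydev[!is.finite(ydev)] <- NA_real_
  closed <- error_mode == "closed"

  obj <- function(g) {
    cpp_dual_state_sse(perturbation, ydev,
                       rates$alpha_fast, rates$beta_fast,
                       rates$alpha_slow, rates$beta_slow,
                       g[1], g[2], closed)
  }

  starts <- list(c(0.5, 0.5), c(1, 1), c(0.1, 1), c(1, 0.1), c(0.25, 0.75))
  best <- NULL
  for (s in starts) {
    fit <- optim(s, obj, method = "L-BFGS-B", lower = c(0, 0),
                 upper = c(20, 20),
                 control = list(factr = 10, pgtol = 1e-12, maxit = 500))
    if (is.null(best) || fit$value < best$value) best <- fit
  }

  g <- gauss_newton_polish_(best$par, perturbation, ydev, rates, closed)
  sse <- obj(g)
  if (sse > best$value) {  # polish should never hurt; keep the better one
    g <- best$par
    sse <- best$value
  }

  params <- dual_state_params(rates$alpha_fast, rates$beta_fast,
                              rates$alpha_slow, rates$beta_slow,
                              gamma_fast = g[1], gamma_slow = g[2])
  fitted <- simulate_dual_state(perturbation, params,
                                error_mode = if (closed) "closed" else "observed",
                                observed_gains = if (closed) NULL else gains)
  structure(list(gamma_fast = g[1], gamma_slow = g[2], rates = rates,
                 sse = sse, n_valid = n_valid, fitted = fitted,
                 error_mode = error_mode),
            class = "dual_state_fit")
}

# a few projected Gauss-Newton steps with central-difference Jacobian; the
# residual is nearly linear in the gains so this converges in 2-3 steps
gauss_newton_polish_ <- function(g, p, ydev, rates, closed, steps = 6,
                                 h = 1e-6) {
  ok <- is.finite(ydev)
  predict <- function(g) {
    m <- cpp_dual_state(p, rates$alpha_fast, rates$beta_fast,
                        rates$alpha_slow, rates$beta_slow,
                        g[1], g[2], closed,
                        if (closed) numeric(0) else ifelse(ok, ydev, NA_real_))
    m[ok, 4]
  }
  y <- ydev[ok]
  for (it in seq_len(steps)) {
    r <- y - predict(g)
    J <- cbind(
      (predict(g + c(h, 0)) - predict(g - c(h, 0))) / (2 * h),
      (predict(g + c(0, h)) - predict(g - c(0, h))) / (2 * h)
    )
    step <- tryCatch(solve(crossprod(J), crossprod(J, r)),
                     error = function(e) NULL)
    if (is.null(step)) break
    g_new <- pmax(g + as.vector(step), 0)
    if (max(abs(g_new - g)) < 1e-12) { g <- g_new; break }
    g <- g_new
  }
  g
}

#' Slow-process share of total fitted gain
#'
#' `gamma_slow / (gamma_fast + gamma_slow)`, in `[0, 1]`: 0.5 means both
#' processes contribute equally, 1 means adaptation is carried entirely by
#' the slow process.
#'
#' @param fit a `dual_state_fit`, or a numeric `gamma_fast` with
#'   `gamma_slow` given separately.
#' @param gamma_slow slow gain when `fit` is numeric.
#' @return the ratio, or `NA` (with a warning) when both gains are 0.
#' @export
slow_ratio <- function(fit, gamma_slow = NULL) {
  if (inherits(fit, "dual_state_fit")) {
    gf <- fit$gamma_fast
    gs <- fit$gamma_slow
  } else {
    gf <- fit
    gs <- gamma_slow
  }
  tot <- gf + gs
  out <- ifelse(tot > 0, gs / tot, NA_real_)
  if (anyNA(out)) warning("both process gains are zero; ratio undefined")
  out
}

#' Identifiability of the two process gains
#'
#' Reports how distinguishable the fast and slow contributions are for a
#' given perturbation schedule: the basis traces generated with gains
#' (1, 0) and (0, 1) are assembled into a two-column design and its
#' condition number returned. A modest condition number means the two
#' gains are jointly identifiable from that schedule.
#'
#' @param perturbation per-trial perturbation schedule.
#' @param rates fixed rates, a [dual_state_params()] object.
#' @return list with `condition_number` and logical `identifiable`
#'   (condition number finite and below 1e6).
#' @export
dual_state_identifiability <- function(perturbation,
                                       rates = dual_state_params()) {
  f <- simulate_dual_state(perturbation,
                           dual_state_params(rates$alpha_fast, rates$beta_fast,
                                             rates$alpha_slow, rates$beta_slow,
                                             1, 0))$adaptation
  s <- simulate_dual_state(perturbation,
                           dual_state_params(rates$alpha_fast, rates$beta_fast,
                                             rates$alpha_slow, rates$beta_slow,
                                             0, 1))$adaptation
  sv <- svd(cbind(f, s))$d
  kappa <- if (sv[2] > 0) sv[1] / sv[2] else Inf
  list(condition_number = kappa, identifiable = is.finite(kappa) && kappa < 1e6)
}
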