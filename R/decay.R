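#' Exponential-decay model parameters
#'
#' Parameters of the saturating-exponential ("rate of change") model: the
#' per-trial rate `L` (fraction of the remaining gap to asymptote closed on
#' each trial, in \[0, 1\]) and the asymptote `A` in degrees. When the data
#' the model is meant for are supplied, `A` is checked against its bound
#' \[0, 2 max(|data|)\].
#'
#' @param L Rate of change per trial.
#' @param A Asymptote in degrees.
#' @param data Optional data vector used to bound `A`.
#' @return Named numeric vector of class `decay_params`.
#' @export
decay_params <- function(L, A, data = NULL) {
  if (!is.finite(L) || L < 0 || L > 1)
    stop("rate of change L must lie in [0, 1]")
  if (!is.finite(A) || A < 0)
    stop("asymptote A must be finite and nonnegative")
  if (!is.null(data)) {
    amax <- 2 * max(abs(data), na.rm = TRUE)
    if (A > amax)
      stop("asymptote A exceeds its bound 2*max(|data|) = ", amax)
  }
  structure(c(L = L, A = A), class = "decay_params")
}

#' Simulate the exponential-decay process
#'
#' Iterates `P_{t+1} = P_t + L (A - P_t)` from `p0` and returns the first
#' `n_trials` values after the start, i.e. `P_1 .. P_n` with
#' `P_t = A - (A - p0) (1 - L)^t` (the closed form is used, which is exact).
#' The process moves monotonically from `p0` toward the asymptote `A`.
#'
#' @param params A [decay_params()] object (or numeric `c(L, A)`).
#' @param n_trials Number of values to return (>= 1).
#' @param p0 Starting value in degrees (not itself returned).
#' @return Numeric vector of length `n_trials`.
#' @examples
#' simulate_decay(decay_params(0.5, 10), 3)   # 5, 7.5, 8.75
#' @export
simulate_decay <- function(params, n_trials, p0 = 0) {
  if (!inherits(params, "decay_params"))
    params <- decay_params(params[[1]], params[[2]])
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 1)
    stop("n_trials must be a positive count")
  L <- params[["L"]]; A <- params[["A"]]
  A - (A - p0) * (1 - L)^seq_len(as.integer(n_trials))
}

#' Fit the exponential-decay model to a trial series
#'
#' Least-squares fit of [simulate_decay()] (started at `p0 = 0`) to a
#' per-trial series, under the bounds `L` in \[0, 1\] and `A` in
#' \[0, 2 max(|series|)\]. Multi-start bounded optimization (`L-BFGS-B`
#' from a grid of starting values) guards against local minima.
#'
#' The fitted value at series index j is the model's state after j learning
#' updates, `A (1 - (1-L)^j)`. For test-trial channels (no-cursor reaches,
#' hand localizations) a zero is prepended to the series before fitting
#' (`prepend_zero = TRUE`): those responses have already changed through the
#' preceding training trial, so the series is anchored at the pre-training
#' value of zero. The prepended zero occupies index 0 of the fitted axis,
#' where the model's starting state sits, and cannot be returned as a trial
#' index.
#'
#' @param series Numeric per-trial vector (degrees); `NA` allowed.
#' @param prepend_zero Prepend a zero before fitting (test-trial channels).
#' @param n_starts Minimum number of optimization starts (default 15).
#' @param extra_starts Optional matrix of additional `(L, A)` starting
#'   values, one row each.
#' @return Object of class `decay_fit`: list with `params`
#'   ([decay_params()]), `mse`, `n`, `prepend_zero`, `series`.
#' @examples
#' y <- simulate_decay(decay_params(0.3, 20), 50)
#' coef(fit_decay(y))
#' @export
fit_decay <- function(series, prepend_zero = FALSE, n_starts = 15,
                      extra_starts = NULL) {
  keep <- is.finite(series)
  if (sum(keep) < 3L) stop("need at least 3 finite values to fit the decay model")
  amax <- 2 * max(abs(series), na.rm = TRUE)
  y <- if (prepend_zero) c(0, series) else series
  obs <- !is.na(y)
  # index j of the fitted axis carries the state after j updates; the
  # prepended zero is index 0 and meets the model's origin exactly
  tt <- if (prepend_zero) 0:(length(y) - 1L) else seq_along(y)
  if (amax == 0) {
    warning("all-zero series: asymptote bound degenerate, A fixed to 0")
    params <- structure(c(L = 0, A = 0), class = "decay_params")
    return(structure(list(params = params, mse = 0, n = length(series),
                          prepend_zero = prepend_zero, series = series),
                     class = "decay_fit"))
  }
  objective <- function(par) {
    pred <- par[2] - par[2] * (1 - par[1])^tt
    mean((pred[obs] - y[obs])^2)
  }
  Ls <- c(0.02, 0.1, 0.3, 0.6, 0.9)
  As <- amax * c(0.25, 0.5, 0.75)
  starts <- as.matrix(expand.grid(L = Ls, A = As))
  if (nrow(starts) > n_starts)
    starts <- starts[seq(1L, nrow(starts), length.out = n_starts), , drop = FALSE]
  if (!is.null(extra_starts)) starts <- rbind(starts, extra_starts)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- stats::optim(as.numeric(starts[i, ]), objective,
                        method = "L-BFGS-B",
                        lower = c(0, 0), upper = c(1, amax),
                        control = list(maxit = 2000, factr = 1e2,
                                       ndeps = c(1e-8, 1e-8 * max(1, amax))))
    if (is.null(best) || res$value < best$value) best <- res
  }
  params <- structure(c(L = best$par[1], A = best$par[2]),
                      class = "decay_params")
  structure(list(params = params, mse = best$value, n = length(series),
                 prepend_zero = prepend_zero, series = series),
            class = "decay_fit")
}

#' @export
coef.decay_fit <- function(object, ...) {
  stats::setNames(as.numeric(object$params), names(object$params))
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Exponential-decay fit: rate of change %.1f%% per trial, asymptote %.2f deg\n",
              100 * x$params[["L"]], x$params[["A"]]))
  if (!is.null(x$ci_L))
    cat(sprintf("  95%% CI  L: %.1f-%.1f%%   A: %.2f-%.2f deg  (%d bootstrap resamples)\n",
                100 * x$ci_L[1], 100 * x$ci_L[2], x$ci_A[1], x$ci_A[2],
                x$n_boot))
  cat(sprintf("  MSE %.4g over %d trials%s\n", x$mse, x$n,
              if (x$prepend_zero) " (zero prepended)" else ""))
  invisible(x)
}

#' Predicted decay curve of a fit
#'
#' @param object A `decay_fit`.
#' @param n_trials Horizon; defaults to the fitted series length.
#' @param ... Unused.
#' @return Numeric vector of modelled values on the returnable trial axis
#'   (trial t carries the state after t updates; the prepended zero, when
#'   used, is index 0 and not included).
#' @export
predict.decay_fit <- function(object, n_trials = object$n, ...) {
  simulate_decay(object$params, n_trials)
}

#' @export
plot.decay_fit <- function(x, ...) {
  graphics::plot(seq_len(x$n), x$series, col = "grey50", pch = 16, cex = 0.6,
                 xlab = "trial", ylab = "value (deg)", ...)
  graphics::lines(seq_len(x$n), predict(x), lwd = 2)
  graphics::abline(h = x$params[["A"]], lty = 3)
  if (!is.null(x$ci_A)) graphics::abline(h = x$ci_A, lty = 3, col = "grey60")
  invisible(x)
}

#' Bootstrap the decay fit across participants
#'
#' Resamples participants with replacement `n_boot` times; each resample's
#' cross-participant mean series is refit and percentile 95% confidence
#' intervals (2.5th/97.5th) are formed for both parameters. The point
#' estimate comes from the full-cohort mean series. Deterministic for a
#' given `seed`.
#'
#' @param cohort Numeric matrix, participants in rows, trials in columns.
#' @param n_boot Number of resamples (default 1000).
#' @param seed Optional integer seed.
#' @param prepend_zero Passed to [fit_decay()].
#' @return A `decay_fit` augmented with `ci_L`, `ci_A`, `n_boot`, `seed`
#'   and the bootstrap draws in `boot`.
#' @export
bootstrap_decay <- function(cohort, n_boot = 1000, seed = NULL,
                            prepend_zero = FALSE) {
  if (!is.matrix(cohort)) cohort <- as.matrix(cohort)
  n_sub <- nrow(cohort)
  if (n_sub < 2L) stop("bootstrap across participants needs at least 2 participants")
  if (!is.numeric(n_boot) || n_boot < 1) stop("n_boot must be at least 1")
  n_boot <- as.integer(n_boot)
  if (!is.null(seed)) set.seed(seed)
  mean_series <- colMeans(cohort, na.rm = TRUE)
  point <- fit_decay(mean_series, prepend_zero = prepend_zero)
  est <- coef(point)
  draws <- matrix(NA_real_, nrow = n_boot, ncol = 2,
                  dimnames = list(NULL, c("L", "A")))
  for (b in seq_len(n_boot)) {
    rows <- sample.int(n_sub, n_sub, replace = TRUE)
    ms <- colMeans(cohort[rows, , drop = FALSE], na.rm = TRUE)
    draws[b, ] <- coef(fit_decay(ms, prepend_zero = prepend_zero,
                                 n_starts = 6,
                                 extra_starts = matrix(est, nrow = 1)))
  }
  point$ci_L <- unname(stats::quantile(draws[, "L"], c(0.025, 0.975)))
  point$ci_A <- unname(stats::quantile(draws[, "A"], c(0.025, 0.975)))
  point$n_boot <- n_boot
  point$seed <- seed
  point$boot <- draws
  point
}

#' Saturation trial of a fitted decay process
#'
#' First trial at which the modelled group-average process (the decay curve
#' simulated from the fitted parameters) falls inside the bootstrapped 95%
#' confidence interval of the asymptote. Trials are counted on the axis of
#' the fitted series: when a zero was prepended for fitting it sits at index
#' 0 and cannot be returned.
#'
#' @param fit A `decay_fit` with bootstrap CIs (see [bootstrap_decay()]),
#'   or any `decay_fit` plus an explicit `ci_A`.
#' @param horizon Number of trials to scan; defaults to the fitted series
#'   length.
#' @param ci_A Optional confidence interval for the asymptote, overriding
#'   the one stored in `fit`.
#' @return Integer trial index (>= 1), or `NA` with a warning when the
#'   modelled process never enters the interval within the horizon.
#' @export
saturation_trial <- function(fit, horizon = fit$n, ci_A = fit$ci_A) {
  stopifnot(inherits(fit, "decay_fit"))
  if (is.null(ci_A) || length(ci_A) != 2L)
    stop("saturation_trial needs a bootstrapped ci_A (see bootstrap_decay)")
  ci_A <- sort(ci_A)
  modelled <- predict(fit, n_trials = horizon)
  hit <- which(modelled >= ci_A[1] & modelled <= ci_A[2])
  if (!length(hit)) {
    warning("modelled process never enters the asymptote CI within ",
            horizon, " trials")
    return(NA_integer_)
  }
  hit[1]
}

#' First-rotation fitting window
#'
#' Trial indices of the 160-trial first-rotation window used for decay fits
#' to the reach data or to the model's slow process. With
#' `align = "post_error"` (default) the window holds the 160 states produced
#' by the 160 first-rotation errors — the state on the first rotated trial
#' is still the (zero) baseline, which coincides with the decay model's
#' starting value `p0 = 0`, so the k-th windowed value and the decay model's
#' k-th value both reflect k learning updates. `align = "on_trial"` returns
#' the rotation trials themselves.
#'
#' @param schedule A `perturbation_schedule` with a `rotation1` phase.
#' @param align `"post_error"` or `"on_trial"`.
#' @return Integer vector of trial indices.
#' @export
first_rotation_window <- function(schedule,
                                  align = c("post_error", "on_trial")) {
  align <- match.arg(align)
  stopifnot(inherits(schedule, "perturbation_schedule"))
  r1 <- which(schedule$phase == "rotation1")
  if (!length(r1)) stop("schedule has no rotation1 phase")
  ix <- if (align == "post_error") r1 + 1L else r1
  ix[ix <= nrow(schedule)]
}
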