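#' Two-rate state-space model parameters
#'
#' Constructs and validates the four parameters of the two-rate model of
#' trial-by-trial adaptation: a slow process with a high retention rate `Rs`
#' and a low learning rate `Ls`, and a fast process with a lower retention
#' rate `Rf` and a higher learning rate `Lf`. All parameters lie in
#' \[0, 1\] inclusive, with `Ls < Lf` and `Rs > Rf` so the processes keep
#' their slow/fast identity.
#'
#' @param Rs,Ls,Rf,Lf Retention and learning rates (unitless).
#' @param relax If `TRUE`, the `Ls < Lf` and `Rs > Rf` inequalities are not
#'   enforced (useful for degenerate test settings such as zero learning).
#' @return Named numeric vector of class `two_rate_params`.
#' @examples
#' two_rate_params(Rs = 0.99, Ls = 0.05, Rf = 0.8, Lf = 0.2)
#' @export
two_rate_params <- function(Rs, Ls, Rf, Lf, relax = FALSE) {
  p <- c(Rs = Rs, Ls = Ls, Rf = Rf, Lf = Lf)
  if (any(!is.finite(p))) stop("two-rate parameters must be finite")
  if (any(p < 0 | p > 1))
    stop("two-rate parameters must lie in [0, 1]; got ",
         paste(sprintf("%s=%g", names(p), p), collapse = ", "))
  if (!relax) {
    if (!(Ls < Lf)) stop("slow learning rate must be below the fast one (Ls < Lf)")
    if (!(Rs > Rf)) stop("slow retention rate must exceed the fast one (Rs > Rf)")
  }
  structure(p, class = "two_rate_params")
}

#' One-rate state-space model parameters
#'
#' @param R Retention rate in \[0, 1\].
#' @param L Learning rate in \[0, 1\].
#' @return Named numeric vector of class `one_rate_params`.
#' @export
one_rate_params <- function(R, L) {
  p <- c(R = R, L = L)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("one-rate parameters must lie in [0, 1]")
  structure(p, class = "one_rate_params")
}

#' Simulate the two-rate model over a schedule
#'
#' Runs the closed-loop state-space recurrence over a perturbation schedule.
#' The value reported for trial t is the model's motor output on that trial,
#' i.e. the state accumulated from errors on trials 1..t-1; the error
#' experienced on trial t, `e_t = p_t - x_total_t`, then updates the states
#' used on trial t+1:
#' \deqn{x_{s,t+1} = L_s e_t + R_s x_{s,t}, \quad x_{f,t+1} = L_f e_t + R_f x_{f,t}}
#' with `x_total = x_slow + x_fast`. On error-clamp trials the error is
#' forced to zero: neither process learns, each only retains.
#'
#' @param params A [two_rate_params()] object.
#' @param schedule A [build_schedule()] result.
#' @param x0_slow,x0_fast Initial states in degrees.
#' @return Object of class `two_rate_trajectory`: data frame with columns
#'   `trial`, `x_slow`, `x_fast`, `x_total`, `error` (all in degrees).
#' @examples
#' tr <- simulate_two_rate(two_rate_params(0.99, 0.05, 0.8, 0.2),
#'                         build_schedule())
#' @export
simulate_two_rate <- function(params, schedule, x0_slow = 0, x0_fast = 0) {
  if (!inherits(params, "two_rate_params"))
    params <- do.call(two_rate_params, as.list(params))
  stopifnot(inherits(schedule, "perturbation_schedule"))
  p <- schedule$perturbation
  clamp <- schedule$is_clamp
  n <- length(p)
  xs <- xf <- err <- numeric(n)
  s <- x0_slow; f <- x0_fast
  Rs <- params[["Rs"]]; Ls <- params[["Ls"]]
  Rf <- params[["Rf"]]; Lf <- params[["Lf"]]
  for (t in seq_len(n)) {
    xs[t] <- s; xf[t] <- f
    e <- if (clamp[t]) 0 else p[t] - (s + f)
    err[t] <- e
    s <- Ls * e + Rs * s
    f <- Lf * e + Rf * f
  }
  structure(data.frame(trial = seq_len(n), x_slow = xs, x_fast = xf,
                       x_total = xs + xf, error = err),
            class = c("two_rate_trajectory", "data.frame"),
            params = params, x_final = c(slow = s, fast = f))
}

#' Simulate the one-rate model over a schedule
#'
#' Single-process counterpart of [simulate_two_rate()]:
#' `x_{t+1} = L e_t + R x_t` with `e_t = p_t - x_t`, forced to zero on
#' error-clamp trials. As in the two-rate simulator, the value reported for
#' trial t is the pre-error state (the output on that trial).
#'
#' @param params A [one_rate_params()] object.
#' @param schedule A [build_schedule()] result.
#' @param x0 Initial state in degrees.
#' @return Data frame of class `one_rate_trajectory` with columns `trial`,
#'   `x_total`, `error`.
#' @export
simulate_one_rate <- function(params, schedule, x0 = 0) {
  if (!inherits(params, "one_rate_params"))
    params <- do.call(one_rate_params, as.list(params))
  stopifnot(inherits(schedule, "perturbation_schedule"))
  p <- schedule$perturbation
  clamp <- schedule$is_clamp
  n <- length(p)
  x <- err <- numeric(n)
  st <- x0
  R <- params[["R"]]; L <- params[["L"]]
  for (t in seq_len(n)) {
    x[t] <- st
    e <- if (clamp[t]) 0 else p[t] - st
    err[t] <- e
    st <- L * e + R * st
  }
  structure(data.frame(trial = seq_len(n), x_total = x, error = err),
            class = c("one_rate_trajectory", "data.frame"),
            params = params, x_final = st)
}

#' Steady-state output under a constant perturbation
#'
#' Closed-form fixed point of the two-rate recurrence under a constant
#' perturbation P (retention rates strictly below 1):
#' \deqn{x^* = P \frac{G}{1 + G}, \qquad G = \frac{L_s}{1-R_s} + \frac{L_f}{1-R_f}}
#'
#' @param params A [two_rate_params()] object with `Rs < 1` and `Rf < 1`.
#' @param P Constant perturbation in degrees.
#' @return Steady-state total output in degrees.
#' @export
two_rate_steady_state <- function(params, P) {
  Rs <- params[["Rs"]]; Rf <- params[["Rf"]]
  if (Rs >= 1 || Rf >= 1)
    stop("steady state requires retention rates strictly below 1")
  G <- params[["Ls"]] / (1 - Rs) + params[["Lf"]] / (1 - Rf)
  P * G / (1 + G)
}

#' @export
print.two_rate_trajectory <- function(x, ...) {
  p <- attr(x, "params")
  cat("Two-rate trajectory over", nrow(x), "trials\n")
  cat(sprintf("  params: Rs=%.4g Ls=%.4g Rf=%.4g Lf=%.4g\n",
              p[["Rs"]], p[["Ls"]], p[["Rf"]], p[["Lf"]]))
  cat(sprintf("  final output %.3f deg (slow %.3f, fast %.3f)\n",
              x$x_total[nrow(x)], x$x_slow[nrow(x)], x$x_fast[nrow(x)]))
  invisible(x)
}

#' Plot a simulated two-rate trajectory
#'
#' @param x A `two_rate_trajectory`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.two_rate_trajectory <- function(x, ...) {
  graphics::plot(x$trial, x$x_total, type = "l", lwd = 2,
                 xlab = "trial", ylab = "deviation (deg)", ...)
  graphics::lines(x$trial, x$x_slow, col = "blue", lty = 2)
  graphics::lines(x$trial, x$x_fast, col = "red", lty = 3)
  graphics::legend("topleft", legend = c("total", "slow", "fast"),
                   col = c("black", "blue", "red"), lty = 1:3, bty = "n")
  invisible(x)
}

#' Export a trajectory to CSV
#'
#' Writes columns `trial,x_slow,x_fast,x_total,error` (one-rate trajectories
#' lack the slow/fast split and carry `trial,x_total,error`).
#'
#' @param trajectory A `two_rate_trajectory` or `one_rate_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
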