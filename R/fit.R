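#' Grid-search starting points for multi-start optimization
#'
#' Evaluates an objective on a regular grid over a box, skips infeasible
#' nodes, and returns the `n_best` feasible nodes with the lowest objective
#' values, sorted ascending. Used to seed local refinement in
#' [fit_state_space()] and available as a generic utility.
#'
#' @param objective Function taking a parameter vector, returning a scalar.
#' @param lower,upper Numeric vectors defining the box.
#' @param grid_n Grid points per dimension (default 6).
#' @param n_best Number of starting points to return (default 6).
#' @param feasible Optional predicate on a parameter vector; grid nodes for
#'   which it returns `FALSE` are skipped.
#' @return List of parameter vectors, best first; attribute `objective`
#'   carries their objective values.
#' @export
grid_search_starts <- function(objective, lower, upper, grid_n = 6,
                               n_best = 6, feasible = NULL) {
  stopifnot(length(lower) == length(upper), all(upper >= lower), grid_n >= 2)
  axes <- lapply(seq_along(lower), function(i)
    seq(lower[i], upper[i], length.out = grid_n))
  grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- names(lower)
  if (!is.null(feasible)) {
    keep <- apply(grid, 1L, function(row) isTRUE(feasible(row)))
    grid <- grid[keep, , drop = FALSE]
  }
  if (nrow(grid) == 0L)
    stop("no feasible grid node; try a finer grid (larger `grid_n`)")
  vals <- apply(grid, 1L, objective)
  ord <- order(vals)[seq_len(min(n_best, nrow(grid)))]
  out <- lapply(ord, function(i) grid[i, ])
  attr(out, "objective") <- vals[ord]
  out
}

# Smoothly penalized objective used during gradient-based refinement:
# box bounds are handled by L-BFGS-B, the strict orderings Ls < Lf and
# Rs > Rf by a quadratic penalty that vanishes on the feasible side.
two_rate_penalty <- function(par) {
  1e6 * (max(0, par[["Ls"]] - par[["Lf"]])^2 +
         max(0, par[["Rf"]] - par[["Rs"]])^2)
}

#' Fit a state-space model of adaptation to a trial series
#'
#' Fits the two-rate (or one-rate) model to per-trial angular deviations by
#' least squares: a grid search over the constrained parameter box provides
#' the six best feasible starting points (infeasible nodes, violating
#' `Ls < Lf` or `Rs > Rf`, are skipped), each refined by bounded local
#' optimization (`L-BFGS-B` with a quadratic penalty for the orderings); the
#' refit with the lowest mean squared error wins. Missing data points are
#' ignored in the MSE.
#'
#' With `fit_target = "slow"` the model's slow process, rather than its
#' total output, is compared to the data — used to ask whether a measured
#' implicit time course (e.g. reach aftereffects) behaves like the slow
#' process.
#'
#' @param data Numeric vector of per-trial deviations (degrees), aligned to
#'   `schedule`; `NA` marks missing trials. Typically a group-mean series.
#' @param schedule A [build_schedule()] result of the same length.
#' @param model_kind `"two_rate"` or `"one_rate"`.
#' @param fit_target `"total"` (default) or `"slow"` (two-rate only).
#' @param grid_n Grid points per dimension for the grid search.
#' @param n_starts Number of grid starts refined locally.
#' @return Object of class `state_space_fit` with elements `params`, `mse`,
#'   `n_points`, `k`, `trajectory`, `model_kind`, `fit_target`, `data`,
#'   `schedule`.
#' @examples
#' sched <- build_schedule()
#' truth <- two_rate_params(0.99, 0.05, 0.8, 0.2)
#' y <- simulate_two_rate(truth, sched)$x_total
#' fit <- fit_state_space(y, sched)
#' coef(fit)
#' @export
fit_state_space <- function(data, schedule,
                            model_kind = c("two_rate", "one_rate"),
                            fit_target = c("total", "slow"),
                            grid_n = 6, n_starts = 6) {
  model_kind <- match.arg(model_kind)
  fit_target <- match.arg(fit_target)
  stopifnot(inherits(schedule, "perturbation_schedule"))
  if (length(data) != nrow(schedule))
    stop("data length (", length(data), ") does not match schedule (",
         nrow(schedule), " trials)")
  obs <- !is.na(data)
  if (!any(obs)) stop("all data values are missing")
  if (fit_target == "slow" && model_kind != "two_rate")
    stop("fit_target = \"slow\" requires the two-rate model")

  if (model_kind == "two_rate") {
    nm <- c("Rs", "Ls", "Rf", "Lf")
    k <- 4L
    predict_fun <- function(par) {
      tr <- simulate_two_rate(structure(par, class = "two_rate_params",
                                        names = nm), schedule)
      if (fit_target == "slow") tr$x_slow else tr$x_total
    }
    feasible <- function(par) par[["Ls"]] < par[["Lf"]] && par[["Rs"]] > par[["Rf"]]
    penalty <- two_rate_penalty
  } else {
    nm <- c("R", "L")
    k <- 2L
    predict_fun <- function(par) {
      simulate_one_rate(structure(par, class = "one_rate_params",
                                  names = nm), schedule)$x_total
    }
    feasible <- NULL
    penalty <- function(par) 0
  }

  mse_of <- function(par) {
    names(par) <- nm
    mean((predict_fun(par)[obs] - data[obs])^2)
  }
  objective <- function(par) {
    names(par) <- nm
    mse_of(par) + penalty(par)
  }

  # endpoints nudged off 0/1 so the grid stays strictly inside the box;
  # refinement may still reach the inclusive bounds
  lower <- stats::setNames(rep(0, k), nm)
  upper <- stats::setNames(rep(1, k), nm)
  starts <- grid_search_starts(objective,
                               lower = lower + 0.001, upper = upper - 0.001,
                               grid_n = grid_n, n_best = n_starts,
                               feasible = feasible)
  best <- NULL
  for (st in starts) {
    res <- stats::optim(st, objective, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = 2000, factr = 1e2,
                                       ndeps = rep(1e-7, k)))
    if (is.null(best) || res$value < best$value) best <- res
  }
  par <- best$par
  names(par) <- nm
  # boundary-equality proposals can survive the penalty at negligible cost;
  # nudge them strictly feasible before constructing the classed params
  if (model_kind == "two_rate") {
    eps <- 1e-9
    if (par[["Ls"]] >= par[["Lf"]]) par[["Ls"]] <- max(0, par[["Lf"]] - eps)
    if (par[["Rf"]] >= par[["Rs"]]) par[["Rf"]] <- max(0, par[["Rs"]] - eps)
    params <- two_rate_params(par[["Rs"]], par[["Ls"]], par[["Rf"]], par[["Lf"]])
    trajectory <- simulate_two_rate(params, schedule)
  } else {
    params <- one_rate_params(par[["R"]], par[["L"]])
    trajectory <- simulate_one_rate(params, schedule)
  }
  structure(list(params = params,
                 mse = mse_of(par),
                 n_points = sum(obs),
                 k = k,
                 trajectory = trajectory,
                 model_kind = model_kind,
                 fit_target = fit_target,
                 data = data,
                 schedule = schedule),
            class = "state_space_fit")
}

#' @export
coef.state_space_fit <- function(object, ...) {
  stats::setNames(as.numeric(object$params), names(object$params))
}

#' @export
print.state_space_fit <- function(x, ...) {
  cat(sprintf("%s state-space fit (target: %s)\n",
              if (x$model_kind == "two_rate") "Two-rate" else "One-rate",
              x$fit_target))
  cat("  ", paste(sprintf("%s = %.4g", names(x$params), x$params),
                  collapse = ", "), "\n", sep = "")
  cat(sprintf("  MSE %.4g deg^2 over %d trials (k = %d)\n",
              x$mse, x$n_points, x$k))
  invisible(x)
}

#' @export
summary.state_space_fit <- function(object, ...) {
  out <- list(params = coef(object), mse = object$mse,
              n_points = object$n_points, k = object$k,
              aic = aic_from_mse(object$mse, object$n_points, object$k),
              model_kind = object$model_kind, fit_target = object$fit_target,
              trial_sets = tryCatch(
                extract_trial_sets(fitted(object), object$schedule),
                error = function(e) NULL))
  class(out) <- "summary.state_space_fit"
  out
}

#' @export
print.summary.state_space_fit <- function(x, ...) {
  cat(sprintf("%s model, fit to %s, %d trials\n", x$model_kind, x$fit_target,
              x$n_points))
  cat("  ", paste(sprintf("%s = %.4g", names(x$params), x$params),
                  collapse = ", "), "\n", sep = "")
  cat(sprintf("  MSE %.4g deg^2, AIC %.3f (n log mse + 2k)\n", x$mse, x$aic))
  if (!is.null(x$trial_sets)) {
    cat(sprintf("  model trial sets: R1 %.2f, R1_Late %.2f, R2 %.2f, EC %.2f deg\n",
                x$trial_sets$R1, x$trial_sets$R1_Late, x$trial_sets$R2,
                x$trial_sets$EC))
  }
  invisible(x)
}

#' @export
fitted.state_space_fit <- function(object, ...) {
  if (object$fit_target == "slow") object$trajectory$x_slow
  else object$trajectory$x_total
}

#' @export
residuals.state_space_fit <- function(object, ...) {
  object$data - fitted(object)
}

#' Predict model output on a (new) schedule
#'
#' @param object A `state_space_fit`.
#' @param schedule Optional new `perturbation_schedule`; defaults to the
#'   fitted one.
#' @param ... Unused.
#' @return Trajectory data frame (see [simulate_two_rate()]).
#' @export
predict.state_space_fit <- function(object, schedule = NULL, ...) {
  if (is.null(schedule)) schedule <- object$schedule
  if (object$model_kind == "two_rate")
    simulate_two_rate(object$params, schedule)
  else simulate_one_rate(object$params, schedule)
}

#' Simulate noisy realizations from a fitted state-space model
#'
#' Adds i.i.d. Gaussian motor noise (SD estimated from the fit residuals
#' unless given) to the deterministic model output.
#'
#' @param object A `state_space_fit`.
#' @param nsim Number of realizations.
#' @param seed Optional seed for reproducibility.
#' @param sd Noise SD in degrees; default is the residual SD.
#' @param ... Unused.
#' @return Matrix with `nsim` columns, one row per trial.
#' @export
simulate.state_space_fit <- function(object, nsim = 1, seed = NULL,
                                     sd = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sd)) sd <- stats::sd(residuals(object), na.rm = TRUE)
  mu <- fitted(object)
  matrix(stats::rnorm(length(mu) * nsim, mean = mu, sd = sd),
         ncol = nsim)
}

#' @export
plot.state_space_fit <- function(x, ...) {
  n <- length(x$data)
  graphics::plot(seq_len(n), x$data, col = "grey50", pch = 16, cex = 0.5,
                 xlab = "trial", ylab = "deviation (deg)", ...)
  graphics::lines(seq_len(n), fitted(x), lwd = 2)
  if (x$model_kind == "two_rate") {
    graphics::lines(seq_len(n), x$trajectory$x_slow, col = "blue", lty = 2)
    graphics::lines(seq_len(n), x$trajectory$x_fast, col = "red", lty = 3)
  }
  invisible(x)
}
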