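#' AIC from a least-squares fit
#'
#' Default information criterion for the state-space fits:
#' `AIC = n * log(mse) + 2k`, the Gaussian-likelihood form up to an additive
#' constant shared by all models fit to the same series. A zero MSE makes
#' the log-based criterion undefined and yields `NA` with a warning rather
#' than silently returning `-Inf`.
#'
#' @param mse Mean squared error (degrees squared).
#' @param n Number of fitted data points.
#' @param k Number of free parameters.
#' @return AIC value (`NA` if `mse` is 0).
#' @export
aic_from_mse <- function(mse, n, k) {
  if (mse < 0) stop("mse must be nonnegative")
  if (mse == 0) {
    warning("AIC undefined for mse = 0 under the log-MSE criterion")
    return(NA_real_)
  }
  n * log(mse) + 2 * k
}

#' Relative likelihoods from AIC values
#'
#' Evidence ratio of each candidate model against the best one:
#' `exp((min(AIC) - AIC) / 2)`. The minimum-AIC model gets exactly 1; all
#' values lie in (0, 1].
#'
#' @param aic Numeric vector of AIC values (names preserved).
#' @return Numeric vector of relative likelihoods.
#' @examples
#' relative_likelihood(c(two_rate = 13.901, one_rate = 19.11))
#' @export
relative_likelihood <- function(aic) {
  if (any(is.na(aic))) stop("cannot form relative likelihoods from NA AICs")
  exp((min(aic) - aic) / 2)
}

#' Compare state-space model fits by AIC
#'
#' Computes an AIC per fit and the relative likelihood of each model against
#' the minimum-AIC model. The AIC formula is configurable; the default is
#' [aic_from_mse()] with `n` taken from the fits (they must agree unless
#' `n_points` is supplied).
#'
#' @param fits Named list of `state_space_fit` objects (at least two).
#' @param n_points Optional common number of data points to use in the AIC.
#' @param aic_fun Function `(mse, n, k) -> AIC`; default [aic_from_mse()].
#' @return Object of class `model_comparison`: data frame with columns
#'   `model`, `k`, `mse`, `aic`, `relative_likelihood`.
#' @examples
#' sched <- build_schedule()
#' y <- simulate_two_rate(two_rate_params(0.99, 0.05, 0.8, 0.2), sched)$x_total +
#'   rnorm(288, sd = 1)
#' fits <- list(two_rate = fit_state_space(y, sched, "two_rate"),
#'              one_rate = fit_state_space(y, sched, "one_rate"))
#' compare_models(fits)
#' @export
compare_models <- function(fits, n_points = NULL, aic_fun = aic_from_mse) {
  if (length(fits) < 2L) stop("need at least two fits to compare")
  if (!all(vapply(fits, inherits, logical(1), "state_space_fit")))
    stop("`fits` must be a list of state_space_fit objects")
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    names(fits) <- vapply(fits, `[[`, character(1), "model_kind")
  n_each <- vapply(fits, `[[`, numeric(1), "n_points")
  if (is.null(n_points)) {
    if (length(unique(n_each)) > 1L)
      stop("fits use different numbers of points; pass `n_points` explicitly")
    n_points <- n_each[1]
  }
  mse <- vapply(fits, `[[`, numeric(1), "mse")
  k <- vapply(fits, `[[`, numeric(1), "k")
  aic <- vapply(seq_along(fits), function(i) aic_fun(mse[i], n_points, k[i]),
                numeric(1))
  out <- data.frame(model = names(fits), k = k, mse = mse, aic = aic,
                    relative_likelihood = relative_likelihood(aic),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' @export
print.model_comparison <- function(x, digits = 4, ...) {
  cat("Model comparison (AIC, relative likelihood vs best model):\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
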