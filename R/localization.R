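#' Per-trial visual-proprioceptive discrepancy
#'
#' The discrepancy between where the cursor went and where the hand went:
#' equal to the imposed perturbation on ordinary training trials (aligned 0,
#' first rotation +30, counter rotation -30 under the default schedule), and
#' equal to the participant's own reach deviation on error-clamp trials,
#' where the cursor goes straight to the target so the discrepancy is
#' whatever the hand did.
#'
#' @param schedule A `perturbation_schedule`.
#' @param reach_series Per-trial reach deviations (degrees) aligned to the
#'   schedule; only its clamp-trial values are used.
#' @return Numeric vector of per-trial discrepancies (degrees).
#' @export
build_discrepancy <- function(schedule, reach_series) {
  stopifnot(inherits(schedule, "perturbation_schedule"))
  if (length(reach_series) != nrow(schedule))
    stop("reach_series length (", length(reach_series),
         ") does not match schedule (", nrow(schedule), " trials)")
  disc <- schedule$perturbation
  disc[schedule$is_clamp] <- reach_series[schedule$is_clamp]
  disc
}

#' Fit the proportional model of localization shift
#'
#' One-parameter model: the localization shift on the test trial following
#' training trial t is a fixed proportion `b` of the visual-proprioceptive
#' discrepancy experienced on training trial t (lag 1 on the interleaved
#' axis). The least-squares slope through the origin has the closed form
#' `b = sum(x y) / sum(x^2)` with `x` the lagged discrepancy. Trials whose
#' lagged discrepancy predates the experiment use 0 (no discrepancy before
#' the first trial). An intercept variant is available but off by default.
#'
#' @param localization Per-trial localization shifts (degrees), on the
#'   training-trial axis; `NA` allowed.
#' @param discrepancy Per-trial discrepancy from [build_discrepancy()].
#' @param lag Number of trials the predictor is lagged by (default 1).
#' @param intercept Include an intercept (default `FALSE`).
#' @return Object of class `proportional_fit`: list with `b`, `intercept`,
#'   `residual_mse`, `lag`, `n`.
#' @export
fit_proportional <- function(localization, discrepancy, lag = 1,
                             intercept = FALSE) {
  if (length(localization) != length(discrepancy))
    stop("localization and discrepancy must have the same length")
  lag <- as.integer(lag)
  n <- length(discrepancy)
  x <- c(rep(0, lag), discrepancy)[seq_len(n)]
  keep <- !is.na(localization) & !is.na(x)
  x <- x[keep]; y <- localization[keep]
  if (!length(x) || all(x == 0))
    stop("slope undefined: lagged discrepancy is zero everywhere observed")
  if (intercept) {
    fit <- stats::lm(y ~ x)
    b <- unname(stats::coef(fit)[2]); a <- unname(stats::coef(fit)[1])
    res <- stats::residuals(fit)
  } else {
    b <- sum(x * y) / sum(x * x)
    a <- 0
    res <- y - b * x
  }
  structure(list(b = b, intercept = a, residual_mse = mean(res^2),
                 lag = lag, n = length(y)),
            class = "proportional_fit")
}

#' @export
coef.proportional_fit <- function(object, ...) {
  c(b = object$b, intercept = object$intercept)
}

#' @export
print.proportional_fit <- function(x, ...) {
  cat(sprintf("Proportional localization model: shift = %.3f x discrepancy (lag %d)\n",
              x$b, x$lag))
  if (x$intercept != 0) cat(sprintf("  intercept %.3f deg\n", x$intercept))
  cat(sprintf("  residual MSE %.4g deg^2 over %d trials\n", x$residual_mse, x$n))
  invisible(x)
}

#' Step-function prediction of the proportional model
#'
#' @param object A `proportional_fit`.
#' @param discrepancy Per-trial discrepancy series.
#' @param ... Unused.
#' @return Predicted localization shifts on the training-trial axis.
#' @export
predict.proportional_fit <- function(object, discrepancy, ...) {
  n <- length(discrepancy)
  x <- c(rep(0, object$lag), discrepancy)[seq_len(n)]
  object$intercept + object$b * x
}

#' Regress localization window means on a discrepancy predictor
#'
#' Ordinary least-squares regression of per-participant localization means
#' (e.g. over the last four aligned, last four first-rotation and last four
#' counter-rotation trials) on a predictor such as the signed discrepancy
#' (0 / 30 / -30), the absolute cumulative change (0 / 30 / 60), or the
#' participant's clamp-phase reach mean.
#'
#' @param localization_means Numeric response vector.
#' @param predictor Numeric predictor of the same length.
#' @param conf_level Confidence level for the slope/intercept intervals.
#' @return List with `slope`, `intercept`, `ci` (matrix from
#'   [stats::confint()]), `r` (Pearson correlation) and the underlying `lm`
#'   fit.
#' @export
regress_localization <- function(localization_means, predictor,
                                 conf_level = 0.95) {
  keep <- !is.na(localization_means) & !is.na(predictor)
  y <- localization_means[keep]; x <- predictor[keep]
  if (length(y) < 3L) stop("need at least 3 points for the regression")
  if (stats::sd(x) == 0) stop("slope undefined: predictor is constant")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       ci = stats::confint(fit, level = conf_level),
       r = stats::cor(x, y),
       fit = fit)
}
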