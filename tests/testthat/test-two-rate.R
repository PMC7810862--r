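test_that("parameter constructors enforce the slow/fast constraints", {
  expect_error(two_rate_params(0.9, 0.3, 0.8, 0.2), "Ls < Lf")
  expect_error(two_rate_params(0.7, 0.05, 0.8, 0.2), "Rs > Rf")
  expect_error(two_rate_params(1.2, 0.05, 0.8, 0.2), "\\[0, 1\\]")
  expect_error(two_rate_params(0.9, -0.1, 0.8, 0.2), "\\[0, 1\\]")
  expect_s3_class(two_rate_params(1, 0.055, 0.825, 0.226), "two_rate_params")
  expect_error(one_rate_params(1.5, 0.2), "\\[0, 1\\]")
})

test_that("no learning means no output", {
  p <- two_rate_params(0.9, 0, 0.5, 0, relax = TRUE)
  tr <- simulate_two_rate(p, default_sched)
  expect_equal(tr$x_total, rep(0, 288))
  o <- simulate_one_rate(one_rate_params(0.9, 0), default_sched)
  expect_equal(o$x_total, rep(0, 288))
})

test_that("one step of the recurrence matches hand evaluation", {
  p <- two_rate_params(1, 0.055, 0.825, 0.226)
  sched <- build_schedule(data.frame(length = c(1, 2), perturbation = c(0, 30),
                                     clamp = FALSE))
  tr <- simulate_two_rate(p, sched)
  expect_equal(tr$x_total[2], 0)             # output before any rotated error
  expect_equal(tr$x_total[3], (0.055 + 0.226) * 30)  # 8.43 after one error
  expect_equal(tr$error[2], 30)

  # one-rate: full correction in one step when R = 0, L = 1
  o <- simulate_one_rate(one_rate_params(0, 1), constant_schedule(5, 30))
  expect_equal(o$x_total[2], 30)
})

test_that("x_total is exactly the sum of the processes", {
  set.seed(21)
  for (i in 1:5) {
    tr <- simulate_two_rate(random_valid_params(), default_sched)
    expect_identical(tr$x_total, tr$x_slow + tr$x_fast)
  }
})

test_that("an all-aligned schedule yields identically zero output", {
  sched <- constant_schedule(100, 0)
  set.seed(22)
  for (i in 1:5) {
    expect_equal(simulate_two_rate(random_valid_params(), sched)$x_total,
                 rep(0, 100))
  }
})

test_that("constant perturbation converges to the closed-form fixed point", {
  set.seed(23)
  sched <- constant_schedule(3000, 30)
  for (i in 1:5) {
    p <- random_valid_params()
    tr <- simulate_two_rate(p, sched)
    expect_equal(tr$x_total[3000], two_rate_steady_state(p, 30),
                 tolerance = 1e-6)
  }
  # one-rate fixed point x* = P L / (L + 1 - R)
  o <- simulate_one_rate(one_rate_params(0.9, 0.1), constant_schedule(2000, 30))
  expect_equal(o$x_total[2000], 15, tolerance = 1e-6)
})

test_that("the error clamp produces spontaneous recovery toward the slow process", {
  tr <- simulate_two_rate(reference_group_params("pause"), default_sched)
  expect_equal(tr$error[241:288], rep(0, 48))
  last_r2 <- tr$x_total[240]
  mid_clamp <- tr$x_total[264]
  expect_gt(mid_clamp, last_r2)                       # rebound
  expect_equal(sign(mid_clamp), sign(tr$x_slow[264])) # toward the slow state
})

test_that("grid search returns the best feasible nodes in order", {
  target <- c(a = 0.41, b = 0.62)
  obj <- function(p) sum((p - target)^2)
  starts <- grid_search_starts(obj, lower = c(a = 0, b = 0),
                               upper = c(a = 1, b = 1), grid_n = 6,
                               n_best = 3)
  grid_vals <- seq(0, 1, length.out = 6)
  expect_equal(starts[[1]],
               c(a = grid_vals[which.min(abs(grid_vals - 0.41))],
                 b = grid_vals[which.min(abs(grid_vals - 0.62))]))
  expect_true(all(diff(attr(starts, "objective")) >= 0))

  # 1-D quadratic centred at 0.4 on {0, 0.5, 1}: order (0.5, 0, 1)
  q <- grid_search_starts(function(p) (p - 0.4)^2, lower = 0, upper = 1,
                          grid_n = 3, n_best = 3)
  expect_equal(unlist(q), c(0.5, 0, 1), ignore_attr = TRUE)

  # n_best larger than the feasible node count clips
  few <- grid_search_starts(function(p) p[1], lower = c(0, 0), upper = c(1, 1),
                            grid_n = 2, n_best = 100,
                            feasible = function(p) p[1] < p[2])
  expect_equal(length(few), 1L)   # only (0, 1) is feasible
  expect_error(
    grid_search_starts(function(p) p[1], lower = c(0, 0), upper = c(1, 1),
                       grid_n = 2, n_best = 1,
                       feasible = function(p) FALSE),
    "finer grid")
})

test_that("noiseless self-generated data are recovered to high precision", {
  truth <- two_rate_params(0.985, 0.06, 0.78, 0.21)
  y <- simulate_two_rate(truth, default_sched)$x_total
  fit <- fit_state_space(y, default_sched)
  expect_lt(max(abs(coef(fit) - unclass(truth))), 1e-4)
  expect_lt(fit$mse, 1e-8)
  expect_equal(fit$k, 4)
  expect_equal(fit$n_points, 288)

  # boundary truth (perfect slow retention) is reachable: bounds inclusive
  tb <- reference_group_params("pause")
  fb <- fit_state_space(simulate_two_rate(tb, default_sched)$x_total,
                        default_sched)
  expect_lt(max(abs(coef(fb) - unclass(tb))), 1e-4)
})

test_that("fitted parameters always satisfy the model invariants", {
  set.seed(24)
  y <- simulate_two_rate(random_valid_params(), default_sched)$x_total +
    rnorm(288, sd = 2)
  fit <- fit_state_space(y, default_sched)
  p <- coef(fit)
  expect_true(all(p >= 0 & p <= 1))
  expect_lt(p[["Ls"]], p[["Lf"]])
  expect_gt(p[["Rs"]], p[["Rf"]])
})

test_that("degenerate zero data admit a zero-learning boundary fit", {
  sched <- constant_schedule(50, 0)
  fit <- fit_state_space(rep(0, 50), sched)
  expect_equal(fit$mse, 0)
})

test_that("the one-rate fit matches an exhaustive fine grid", {
  set.seed(25)
  sched <- constant_schedule(120, 30)
  y <- simulate_one_rate(one_rate_params(0.9, 0.12), sched)$x_total +
    rnorm(120, sd = 1.5)
  fit <- fit_state_space(y, sched, model_kind = "one_rate")
  # independent closed form: x_t = x* (1 - phi^(t-1)), phi = R - L,
  # x* = 30 L / (1 - phi); exhaustive scan of the (R, L) box
  step <- 0.005
  Rg <- seq(0, 1, by = step); Lg <- seq(0, 1, by = step)
  pw <- 0:119
  best <- c(Inf, NA, NA)
  for (R in Rg) {
    phi <- R - Lg
    xstar <- ifelse(abs(1 - phi) < 1e-12, 0, 30 * Lg / (1 - phi))
    X <- xstar * (1 - t(outer(pw, phi, function(k, p) p^k)))
    mses <- rowMeans((X - matrix(y, nrow = length(Lg), ncol = 120,
                                 byrow = TRUE))^2)
    j <- which.min(mses)
    if (mses[j] < best[1]) best <- c(mses[j], R, Lg[j])
  }
  expect_lt(abs(coef(fit)[["R"]] - best[2]), step)
  expect_lt(abs(coef(fit)[["L"]] - best[3]), step)
  expect_lte(fit$mse, best[1] + 1e-10)
})

test_that("the slow process can be the fit target", {
  truth <- two_rate_params(0.99, 0.05, 0.8, 0.2)
  slow <- simulate_two_rate(truth, default_sched)$x_slow
  fit <- fit_state_space(slow, default_sched, fit_target = "slow")
  expect_lt(fit$mse, 1e-6)
  expect_equal(fitted(fit), fit$trajectory$x_slow)
  expect_error(fit_state_space(slow, default_sched, model_kind = "one_rate",
                               fit_target = "slow"), "two-rate")
})

test_that("fit input validation rejects bad data", {
  expect_error(fit_state_space(rep(NA_real_, 288), default_sched), "missing")
  expect_error(fit_state_space(1:10, default_sched), "length")
})

test_that("fit methods expose the usual modelling surface", {
  truth <- two_rate_params(0.99, 0.05, 0.8, 0.2)
  y <- simulate_two_rate(truth, default_sched)$x_total
  fit <- fit_state_space(y, default_sched)
  expect_named(coef(fit), c("Rs", "Ls", "Rf", "Lf"))
  expect_equal(residuals(fit), y - fitted(fit))
  pred <- predict(fit, constant_schedule(10, 30))
  expect_equal(nrow(pred), 10)
  sims <- simulate(fit, nsim = 3, seed = 9, sd = 1)
  expect_equal(dim(sims), c(288L, 3L))
  expect_output(print(fit), "Two-rate")
  expect_output(print(summary(fit)), "AIC")
})
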