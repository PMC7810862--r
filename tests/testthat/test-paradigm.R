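test_that("default schedule reproduces the paradigm's phase structure", {
  s <- default_sched
  expect_equal(nrow(s), 288)
  expect_equal(s$phase[64], "aligned")
  expect_equal(s$phase[65], "rotation1")
  expect_equal(s$phase[224], "rotation1")
  expect_equal(s$phase[225], "rotation2")
  expect_equal(s$phase[241], "clamp")
  expect_equal(s$phase[288], "clamp")
  expect_true(all(s$perturbation[s$phase == "aligned"] == 0))
  expect_true(all(s$perturbation[s$phase == "rotation1"] == 30))
  expect_true(all(s$perturbation[s$phase == "rotation2"] == -30))
  expect_identical(which(s$is_clamp), 241:288)
  win <- trial_windows(s)
  expect_identical(win$R1, 65:68)
  expect_identical(win$R1_Late, 221:224)
  expect_identical(win$R2, 237:240)
  expect_identical(win$EC, 273:288)
})

test_that("target angles cycle through all four within every phase block", {
  s <- default_sched
  for (ph in unique(s$phase)) {
    tg <- s$target[s$phase == ph]
    blocks <- split(tg, (seq_along(tg) - 1) %/% 4)
    full <- blocks[lengths(blocks) == 4]
    for (b in full) expect_setequal(b, c(60, 80, 100, 120))
  }
  one_cycle <- build_schedule(data.frame(length = 4, perturbation = 30,
                                         clamp = FALSE))
  expect_setequal(one_cycle$target, c(60, 80, 100, 120))
  expect_equal(one_cycle$perturbation, rep(30, 4))
})

test_that("degenerate and invalid phase specs are handled", {
  s <- build_schedule(data.frame(length = 10, perturbation = 0, clamp = FALSE))
  expect_equal(nrow(s), 10)
  expect_true(all(s$perturbation == 0) && !any(s$is_clamp))
  expect_error(build_schedule(data.frame()), "non-empty")
  expect_error(build_schedule(data.frame(length = 0, perturbation = 0,
                                         clamp = FALSE)), "positive")
  expect_error(build_schedule(data.frame(length = -3, perturbation = 0,
                                         clamp = FALSE)), "positive")
})

test_that("schedule lengths always sum to the spec over random specs", {
  set.seed(11)
  for (i in 1:20) {
    k <- sample(1:5, 1)
    spec <- data.frame(length = sample(1:50, k, replace = TRUE),
                       perturbation = sample(c(-30, 0, 30), k, replace = TRUE),
                       clamp = sample(c(TRUE, FALSE), k, replace = TRUE))
    s <- build_schedule(spec)
    expect_equal(nrow(s), sum(spec$length))
    expect_identical(s$is_clamp, rep(spec$clamp, spec$length))
  }
})

test_that("trial-set means follow their window definitions", {
  expect_equal(unclass(extract_trial_sets(rep(10, 288), default_sched)),
               list(R1 = 10, R1_Late = 10, R2 = 10, EC = 10))
  sets <- extract_trial_sets(as.numeric(1:288), default_sched)
  expect_equal(sets$R1, mean(65:68))  # 66.5
  expect_equal(sets$EC, mean(273:288))
  y <- rep(1, 288); y[65:68] <- NA
  expect_true(is.na(extract_trial_sets(y, default_sched)$R1))
  y2 <- rep(1, 288); y2[65] <- NA
  expect_equal(extract_trial_sets(y2, default_sched)$R1, 1)
  expect_error(extract_trial_sets(1:10, default_sched), "length")
})

test_that("a noiseless two-rate series shows learning and a clamp rebound", {
  tr <- simulate_two_rate(reference_group_params("pause"), default_sched)
  sets <- extract_trial_sets(tr$x_total, default_sched)
  expect_gt(sets$R1_Late, 25)       # near the 30 deg rotation by late training
  expect_lt(sets$R2, 0)             # counter-adapted
  expect_gt(sets$EC, 0)             # spontaneous recovery above zero
})

test_that("baseline normalization subtracts each channel's own baseline", {
  y <- rep(5, 288)
  expect_equal(normalize_baseline(y), rep(0, 288))
  y2 <- c(rep(0, 32), rep(c(2, 4), 16), rep(7, 224))
  expect_equal(normalize_baseline(y2)[33], -1)  # baseline mean 3
  expect_equal(normalize_baseline(y2)[65], 4)

  mat <- rbind(rnorm(288) + 3, rnorm(288) - 2)
  co <- cohort_from_matrix(mat)
  norm <- normalize_baseline(co)
  for (id in unique(norm$participant)) {
    b <- norm$value[norm$participant == id][33:64]
    expect_equal(mean(b), 0, tolerance = 1e-12)
  }
  # idempotence
  expect_equal(normalize_baseline(norm), norm)
  # error names the offender
  co$value[co$participant == "p01" & co$trial %in% 33:64] <- NA
  expect_error(normalize_baseline(co), "p01")
})

test_that("outlier removal flags values beyond 3 cross-participant SDs", {
  mat <- matrix(0, nrow = 32, ncol = 5)
  mat[1, 3] <- 100
  co <- cohort_from_matrix(mat)
  res <- remove_outliers(co)
  expect_equal(res$n_removed, 1)
  expect_true(is.na(res$cohort$value[res$cohort$participant == "p01" &
                                     res$cohort$trial == 3]))
  expect_equal(sum(is.na(res$cohort$value)), 1)
  expect_equal(res$fraction, 1 / (32 * 5))

  # identical values: zero variance, nothing removed
  same <- remove_outliers(cohort_from_matrix(matrix(7, 10, 4)))
  expect_equal(same$n_removed, 0)
  expect_equal(same$fraction, 0)

  # effectively infinite threshold: input unchanged
  set.seed(2)
  noisy <- cohort_from_matrix(matrix(rnorm(40), 10, 4))
  expect_equal(remove_outliers(noisy, threshold_sd = 1e9)$cohort, noisy)

  expect_error(remove_outliers(noisy, threshold_sd = 0), "positive")
  expect_error(remove_outliers(noisy, threshold_sd = -1), "positive")
})

test_that("outlier removal is single-pass and its report matches the data", {
  set.seed(3)
  mat <- matrix(rnorm(32 * 10), 32, 10)
  mat[1, 1] <- 50; mat[2, 1] <- 30
  co <- cohort_from_matrix(mat)
  res <- remove_outliers(co)
  expect_equal(res$n_removed,
               sum(is.na(res$cohort$value)) - sum(is.na(co$value)))
  # re-running recomputes the SD, so cascading removal is possible but the
  # report of the second pass stands on its own
  res2 <- remove_outliers(res$cohort)
  expect_equal(res2$n_removed,
               sum(is.na(res2$cohort$value)) - sum(is.na(res$cohort$value)))
})
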