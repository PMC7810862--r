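#' Run the end-to-end adaptation analysis
#'
#' Chains the full analysis on a cohort: cross-participant outlier removal,
#' baseline normalization, trial-set means, two-rate and one-rate
#' state-space fits to the group-mean training series with AIC comparison,
#' exponential-decay fits (with participant bootstrap and saturation trials)
#' to the reach data, the model's slow process and the test channel, and —
#' for localization groups — the proportional model. Writes JSON/CSV
#' results per stage into `out_dir`; every stochastic step records its seed.
#'
#' @param input A long-format cohort data frame, a CSV path readable by
#'   [read_trial_table()], or `NULL` when `generate` is given.
#' @param generate Optional [cohort_config()]: generate a synthetic cohort
#'   instead of reading one (the truth is written alongside).
#' @param schedule A `perturbation_schedule` (default [build_schedule()]).
#' @param out_dir Output directory, created if needed.
#' @param n_boot Bootstrap resamples for the decay fits (default 1000).
#' @param seed Integer seed for all stochastic steps.
#' @param window First-rotation window alignment for decay fits
#'   (see [first_rotation_window()]).
#' @param aic_fun AIC formula, see [compare_models()].
#' @return Invisibly, a list bundle with each stage's result.
#' @export
run_pipeline <- function(input = NULL, generate = NULL,
                         schedule = build_schedule(),
                         out_dir = ".", n_boot = 1000, seed = 1,
                         window = c("post_error", "on_trial"),
                         aic_fun = aic_from_mse) {
  window <- match.arg(window)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  bundle <- list(seed = seed, n_boot = n_boot, window = window)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  json_out <- function(x, file) {
    jsonlite::write_json(x, file.path(out_dir, file), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  }

  cohort <- stage("input", {
    if (!is.null(generate)) {
      syn <- generate_cohort(generate, schedule)
      write_synthetic_cohort(syn, file.path(out_dir, "cohort.csv"))
      bundle$truth <- syn$truth
      syn$data
    } else if (is.character(input)) {
      read_trial_table(input)
    } else if (is.data.frame(input)) {
      check_cohort(input)
      input
    } else stop("either `input` or `generate` must be supplied")
  })

  n_trials <- nrow(schedule)
  outl <- stage("outlier_removal", remove_outliers(cohort))
  message(sprintf("outlier removal: %d of %d values (%.2f%%)",
                  outl$n_removed, outl$n_checked, 100 * outl$fraction))
  bundle$outliers <- outl
  json_out(list(n_checked = outl$n_checked, n_removed = outl$n_removed,
                fraction = outl$fraction), "outliers.json")

  cohort <- stage("baseline_normalization", normalize_baseline(outl$cohort))
  bundle$cohort <- cohort
  channels <- unique(cohort$channel)

  bundle$trial_sets <- stage("trial_sets", {
    ts <- lapply(channels, function(ch)
      unlist(extract_trial_sets(channel_means(cohort, ch, n_trials), schedule)))
    tsdf <- cbind(data.frame(channel = channels, stringsAsFactors = FALSE),
                  do.call(rbind, ts))
    utils::write.csv(tsdf, file.path(out_dir, "trial_sets.csv"),
                     row.names = FALSE, quote = FALSE)
    tsdf
  })

  reach_mean <- channel_means(cohort, "training", n_trials)
  fits <- stage("state_space_fits", list(
    two_rate = fit_state_space(reach_mean, schedule, "two_rate"),
    one_rate = fit_state_space(reach_mean, schedule, "one_rate")))
  comparison <- stage("model_comparison", compare_models(fits, aic_fun = aic_fun))
  bundle$fits <- fits
  bundle$comparison <- comparison
  fit_json <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    c(as.list(coef(f)),
      list(mse = f$mse, aic = comparison$aic[i],
           relative_likelihood = comparison$relative_likelihood[i],
           n = f$n_points, k = f$k))
  })
  names(fit_json) <- names(fits)
  json_out(fit_json, "model_fits.json")
  utils::write.csv(as.data.frame(comparison),
                   file.path(out_dir, "model_comparison.csv"),
                   row.names = FALSE, quote = FALSE)
  write_trajectory(fits$two_rate$trajectory,
                   file.path(out_dir, "trajectory.csv"))

  # decay fits: reach data, model slow process, and the test channel (if any)
  win <- first_rotation_window(schedule, align = window)
  test_channel <- setdiff(channels, "training")
  boot_seed <- function(offset) as.integer((seed + offset) %% .Machine$integer.max)
  decay_rows <- stage("rate_of_change", {
    rows <- list()
    reach_mat <- channel_matrix(cohort, "training", n_trials)[, win, drop = FALSE]
    rows$reach_training <- decay_summary(reach_mat, prepend_zero = FALSE,
                                         n_boot = n_boot,
                                         seed = boot_seed(1))
    slow <- fits$two_rate$trajectory$x_slow[win]
    slow_fit <- fit_decay(slow, prepend_zero = FALSE)
    rows$slow_process <- list(fit = slow_fit, ci_L = NULL, ci_A = NULL,
                              saturation = NA_integer_)
    if (length(test_channel) == 1L) {
      # test trials follow their training trial, so their first-rotation
      # values sit on the rotation trials themselves (and get the zero anchor)
      win_test <- first_rotation_window(schedule, "on_trial")
      test_mat <- channel_matrix(cohort, test_channel, n_trials)[, win_test,
                                                                 drop = FALSE]
      rows[[test_channel]] <- decay_summary(test_mat, prepend_zero = TRUE,
                                            n_boot = n_boot,
                                            seed = boot_seed(2))
    }
    rows
  })
  bundle$rate_of_change <- decay_rows
  roc_df <- do.call(rbind, lapply(names(decay_rows), function(nm) {
    r <- decay_rows[[nm]]
    data.frame(process = nm,
               rate_percent = 100 * r$fit$params[["L"]],
               rate_ci_low = if (is.null(r$ci_L)) NA else 100 * r$ci_L[1],
               rate_ci_high = if (is.null(r$ci_L)) NA else 100 * r$ci_L[2],
               asymptote = r$fit$params[["A"]],
               asymptote_ci_low = if (is.null(r$ci_A)) NA else r$ci_A[1],
               asymptote_ci_high = if (is.null(r$ci_A)) NA else r$ci_A[2],
               saturation_trial = r$saturation,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(roc_df, file.path(out_dir, "rate_of_change.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  bundle$rate_of_change_table <- roc_df

  if (length(test_channel) == 1L && grepl("^localization", test_channel)) {
    prop <- stage("proportional_model", {
      loc_mean <- channel_means(cohort, test_channel, n_trials)
      disc <- build_discrepancy(schedule, reach_mean)
      fit_proportional(loc_mean, disc, lag = 1)
    })
    bundle$proportional <- prop
    json_out(list(b = prop$b, residual_mse = prop$residual_mse,
                  lag = prop$lag), "proportional.json")
  }

  json_out(list(seed = seed, n_boot = n_boot, window = window,
                n_trials = n_trials, channels = channels),
           "run_config.json")
  invisible(bundle)
}

# point fit + bootstrap CIs + saturation trial for one participant matrix
decay_summary <- function(mat, prepend_zero, n_boot, seed) {
  fit <- bootstrap_decay(mat, n_boot = n_boot, seed = seed,
                         prepend_zero = prepend_zero)
  sat <- tryCatch(saturation_trial(fit),
                  warning = function(w) NA_integer_)
  list(fit = fit, ci_L = fit$ci_L, ci_A = fit$ci_A, saturation = sat)
}

#' Command-line interface to the analysis pipeline
#'
#' Thin dispatcher behind the `inst/scripts/tworate` Rscript. Subcommands:
#' `simulate` (write a model trajectory), `fit-tworate` (state-space fit to
#' a cohort's group-mean training series), `fit-decay` (decay fit with
#' bootstrap), `fit-proportional` (proportional localization model),
#' `compare` (two-rate vs one-rate AIC comparison) and `run` (the full
#' [run_pipeline()]).
#'
#' @param args Character vector of command-line arguments,
#'   e.g. `c("simulate", "--params", "0.99,0.05,0.8,0.2", "--out", "tr.csv")`.
#' @return Invisibly, the subcommand's result object.
#' @export
tworate_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: tworate <simulate|fit-tworate|fit-decay|fit-proportional|compare|run> [options]",
    "  common options: --input <csv> --out <path> --seed <int>",
    "  simulate:         --params Rs,Ls,Rf,Lf [--one-rate R,L]",
    "  fit-decay:        --channel <name> [--prepend] [--nboot <int>] [--window post_error|on_trial]",
    "  fit-proportional: --channel <name>",
    "  run:              [--generate <yaml config>] [--nboot <int>]",
    sep = "\n")
  if (!length(args)) stop(usage, call. = FALSE)
  cmd <- args[1]
  opts <- parse_cli_options(args[-1])
  get <- function(name, default = NULL) {
    if (!is.null(opts[[name]])) opts[[name]] else default
  }
  seed <- as.integer(get("seed", 1))
  schedule <- if (!is.null(get("schedule"))) read_schedule(get("schedule"))
              else build_schedule()
  n_trials <- nrow(schedule)
  out <- get("out")

  result <- switch(cmd,
    "simulate" = {
      tr <- if (!is.null(get("one-rate"))) {
        p <- as.numeric(strsplit(get("one-rate"), ",")[[1]])
        simulate_one_rate(one_rate_params(p[1], p[2]), schedule)
      } else {
        if (is.null(get("params")))
          stop("simulate needs --params Rs,Ls,Rf,Lf (or --one-rate R,L)")
        p <- as.numeric(strsplit(get("params"), ",")[[1]])
        simulate_two_rate(two_rate_params(p[1], p[2], p[3], p[4]), schedule)
      }
      if (!is.null(out)) write_trajectory(tr, out)
      tr
    },
    "fit-tworate" = {
      cohort <- read_trial_table(get("input"))
      y <- channel_means(cohort, get("channel", "training"), n_trials)
      fit <- fit_state_space(y, schedule,
                             model_kind = get("model", "two_rate"))
      if (!is.null(out))
        jsonlite::write_json(c(as.list(coef(fit)),
                               list(mse = fit$mse, n = fit$n_points,
                                    k = fit$k)),
                             out, auto_unbox = TRUE, digits = NA)
      fit
    },
    "fit-decay" = {
      cohort <- read_trial_table(get("input"))
      ch <- get("channel", "training")
      win <- first_rotation_window(schedule, get("window", "post_error"))
      mat <- channel_matrix(cohort, ch, n_trials)[, win, drop = FALSE]
      fit <- bootstrap_decay(mat, n_boot = as.integer(get("nboot", 1000)),
                             seed = seed,
                             prepend_zero = isTRUE(opts$prepend))
      sat <- tryCatch(saturation_trial(fit), warning = function(w) NA)
      if (!is.null(out))
        jsonlite::write_json(list(L = fit$params[["L"]],
                                  A = fit$params[["A"]],
                                  ci_L = fit$ci_L, ci_A = fit$ci_A,
                                  saturation_trial = sat,
                                  n_boot = fit$n_boot, seed = seed,
                                  prepend_zero = isTRUE(opts$prepend),
                                  window = get("window", "post_error")),
                             out, auto_unbox = TRUE, digits = NA, na = "null")
      fit
    },
    "fit-proportional" = {
      cohort <- read_trial_table(get("input"))
      ch <- get("channel")
      if (is.null(ch)) stop("fit-proportional needs --channel")
      loc <- channel_means(cohort, ch, n_trials)
      reach <- channel_means(cohort, "training", n_trials)
      fit <- fit_proportional(loc, build_discrepancy(schedule, reach))
      if (!is.null(out))
        jsonlite::write_json(list(b = fit$b,
                                  residual_mse = fit$residual_mse,
                                  lag = fit$lag),
                             out, auto_unbox = TRUE, digits = NA)
      fit
    },
    "compare" = {
      cohort <- read_trial_table(get("input"))
      y <- channel_means(cohort, get("channel", "training"), n_trials)
      fits <- list(two_rate = fit_state_space(y, schedule, "two_rate"),
                   one_rate = fit_state_space(y, schedule, "one_rate"))
      cmp <- compare_models(fits)
      if (!is.null(out))
        utils::write.csv(as.data.frame(cmp), out, row.names = FALSE,
                         quote = FALSE)
      cmp
    },
    "run" = {
      gen <- NULL
      if (!is.null(get("generate"))) {
        cfg <- yaml::read_yaml(get("generate"))
        gen <- do.call(cohort_config, cfg)
      }
      run_pipeline(input = get("input"), generate = gen,
                   schedule = schedule,
                   out_dir = get("out", "."),
                   n_boot = as.integer(get("nboot", 1000)),
                   seed = seed,
                   window = get("window", "post_error"))
    },
    stop("unknown subcommand '", cmd, "'\n", usage, call. = FALSE))
  invisible(result)
}

# parse "--name value" pairs; a flag followed by another flag (or nothing)
# becomes TRUE
parse_cli_options <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument '", a, "'", call. = FALSE)
    name <- substring(a, 3)
    if (i < length(args) && !startsWith(args[i + 1L], "--")) {
      opts[[name]] <- args[i + 1L]
      i <- i + 2L
    } else {
      opts[[name]] <- TRUE
      i <- i + 1L
    }
  }
  opts
}
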