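#' Reference group-level two-rate parameters
#'
#' Group-level two-rate parameter estimates typical of the interleaved
#' training/test paradigm, used as generator defaults: a slow process with
#' near-perfect retention and a learning rate around 0.03-0.06, and a fast
#' process with retention around 0.74-0.83 and a learning rate around
#' 0.15-0.24, depending on the interleaved test type.
#'
#' @param group One of `"pause"`, `"nocursor"`, `"active_localization"`,
#'   `"passive_localization"`.
#' @return A [two_rate_params()] object.
#' @export
reference_group_params <- function(group = c("pause", "nocursor",
                                             "active_localization",
                                             "passive_localization")) {
  group <- match.arg(group)
  switch(group,
    pause                = two_rate_params(Rs = 1,     Ls = 0.055, Rf = 0.825, Lf = 0.226),
    nocursor             = two_rate_params(Rs = 0.991, Ls = 0.036, Rf = 0.737, Lf = 0.148),
    active_localization  = two_rate_params(Rs = 0.999, Ls = 0.030, Rf = 0.760, Lf = 0.158),
    passive_localization = two_rate_params(Rs = 1,     Ls = 0.054, Rf = 0.740, Lf = 0.236))
}

#' Configuration for a synthetic cohort
#'
#' Defines the generative model for one experimental group: per-participant
#' two-rate parameters jittered around group means, per-trial Gaussian motor
#' noise on training reaches, and one interleaved test channel. Localization
#' shifts are a per-participant proportion (drawn uniformly from
#' `localization_beta_range`) of the previous trial's visual-proprioceptive
#' discrepancy plus noise; no-cursor reaches express a fraction of the slow
#' process plus a fast proportional component.
#'
#' @param n_participants Cohort size.
#' @param group Test-trial group: `"pause"`, `"nocursor"`,
#'   `"active_localization"` or `"passive_localization"`.
#' @param group_params Group-mean [two_rate_params()]; defaults to
#'   [reference_group_params()] for the group.
#' @param param_jitter_sd SD of the per-participant jitter applied on a
#'   logit scale to each parameter (default 0.2).
#' @param motor_noise_sd Per-trial reach noise in degrees (default 4).
#' @param localization_beta_range Range the per-participant proportionality
#'   constant is drawn from (default `c(0.20, 0.30)`).
#' @param localization_noise_sd Per-trial localization noise in degrees
#'   (default 3).
#' @param aftereffect_fraction Fraction of the slow process expressed in
#'   no-cursor reaches (default 0.7).
#' @param nocursor_beta Fast proportional component of no-cursor reaches
#'   (fraction of the previous trial's discrepancy, default 0.2).
#' @param seed Integer seed; all generation is deterministic given it.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants,
                          group = c("pause", "nocursor",
                                    "active_localization",
                                    "passive_localization"),
                          group_params = NULL,
                          param_jitter_sd = 0.2,
                          motor_noise_sd = 4,
                          localization_beta_range = c(0.20, 0.30),
                          localization_noise_sd = 3,
                          aftereffect_fraction = 0.7,
                          nocursor_beta = 0.2,
                          seed = 1L) {
  group <- match.arg(group)
  if (!is.numeric(n_participants) || n_participants < 1)
    stop("n_participants must be a positive count")
  if (param_jitter_sd < 0 || motor_noise_sd < 0 || localization_noise_sd < 0)
    stop("noise standard deviations must be nonnegative")
  if (length(localization_beta_range) != 2L ||
      any(localization_beta_range < 0) || any(localization_beta_range > 1) ||
      diff(localization_beta_range) < 0)
    stop("localization_beta_range must be an increasing interval within [0, 1]")
  if (is.null(group_params)) group_params <- reference_group_params(group)
  if (!inherits(group_params, "two_rate_params"))
    group_params <- do.call(two_rate_params, as.list(group_params))
  structure(list(n_participants = as.integer(n_participants),
                 group = group,
                 group_params = group_params,
                 param_jitter_sd = param_jitter_sd,
                 motor_noise_sd = motor_noise_sd,
                 localization_beta_range = localization_beta_range,
                 localization_noise_sd = localization_noise_sd,
                 aftereffect_fraction = aftereffect_fraction,
                 nocursor_beta = nocursor_beta,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Jitter parameters on a logit scale, then project back onto the feasible
# region (box plus the slow/fast orderings) so the invariants always hold.
jitter_params <- function(group_params, sd) {
  p <- as.numeric(group_params)
  names(p) <- names(group_params)
  if (sd > 0) {
    z <- stats::qlogis(pmin(pmax(p, 1e-4), 1 - 1e-4))
    p <- stats::plogis(z + stats::rnorm(length(p), sd = sd))
  }
  if (p[["Ls"]] >= p[["Lf"]]) {
    mid <- (p[["Ls"]] + p[["Lf"]]) / 2
    p[["Ls"]] <- max(0, mid - 1e-3); p[["Lf"]] <- min(1, mid + 1e-3)
  }
  if (p[["Rf"]] >= p[["Rs"]]) {
    mid <- (p[["Rs"]] + p[["Rf"]]) / 2
    p[["Rs"]] <- min(1, mid + 1e-3); p[["Rf"]] <- max(0, mid - 1e-3)
  }
  two_rate_params(p[["Rs"]], p[["Ls"]], p[["Rf"]], p[["Lf"]])
}

participant_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 99991 * index) %% .Machine$integer.max)
}

#' Generate one synthetic participant
#'
#' Draws per-participant two-rate parameters (group means jittered on a
#' logit scale, projected back to the feasible region), simulates the
#' training channel as the two-rate trajectory plus Gaussian motor noise,
#' and generates the group's test channel: localization shifts as
#' `beta * discrepancy[t-1] + noise`, or no-cursor reaches as
#' `aftereffect_fraction * x_slow + nocursor_beta * discrepancy[t-1] +
#' noise`. Deterministic given `(config$seed, participant_index)`.
#'
#' @param config A [cohort_config()].
#' @param participant_index 1-based participant number.
#' @param schedule Optional schedule; defaults to [build_schedule()].
#' @return List with `data` (long-format rows for this participant) and
#'   `truth` (generating parameters and beta).
#' @export
generate_participant <- function(config, participant_index,
                                 schedule = build_schedule()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(participant_seed(config$seed, participant_index))
  params <- jitter_params(config$group_params, config$param_jitter_sd)
  n <- nrow(schedule)
  tr <- simulate_two_rate(params, schedule)
  training <- tr$x_total + stats::rnorm(n, sd = config$motor_noise_sd)
  id <- sprintf("p%03d", participant_index)
  rows <- data.frame(participant = id, channel = "training",
                     trial = seq_len(n), phase = schedule$phase,
                     value = training, stringsAsFactors = FALSE)
  disc <- build_discrepancy(schedule, training)
  lagged <- c(0, disc)[seq_len(n)]
  beta <- NA_real_
  if (config$group %in% c("active_localization", "passive_localization")) {
    beta <- stats::runif(1, config$localization_beta_range[1],
                         config$localization_beta_range[2])
    loc <- beta * lagged + stats::rnorm(n, sd = config$localization_noise_sd)
    rows <- rbind(rows, data.frame(
      participant = id,
      channel = paste0("localization_",
                       sub("_localization", "", config$group)),
      trial = seq_len(n), phase = schedule$phase, value = loc,
      stringsAsFactors = FALSE))
  } else if (config$group == "nocursor") {
    nc <- config$aftereffect_fraction * tr$x_slow +
      config$nocursor_beta * lagged +
      stats::rnorm(n, sd = config$motor_noise_sd)
    rows <- rbind(rows, data.frame(
      participant = id, channel = "nocursor",
      trial = seq_len(n), phase = schedule$phase, value = nc,
      stringsAsFactors = FALSE))
  }
  list(data = rows,
       truth = list(participant = id,
                    params = stats::setNames(as.numeric(params), names(params)),
                    beta = beta))
}

#' Generate a synthetic cohort
#'
#' Applies [generate_participant()] over the whole cohort and keeps the
#' generating truth beside the data, so recovery experiments always compare
#' against stored truth.
#'
#' @param config A [cohort_config()].
#' @param schedule Optional schedule; defaults to [build_schedule()].
#' @return Object of class `synthetic_cohort`: list with `data` (long-format
#'   data frame), `truth` (per-participant parameters and betas, the group
#'   means, and the config), and `schedule`.
#' @examples
#' cohort <- generate_cohort(cohort_config(4, "pause", seed = 42))
#' head(cohort$data)
#' @export
generate_cohort <- function(config, schedule = build_schedule()) {
  stopifnot(inherits(config, "cohort_config"))
  parts <- lapply(seq_len(config$n_participants), function(i)
    generate_participant(config, i, schedule))
  data <- do.call(rbind, lapply(parts, `[[`, "data"))
  rownames(data) <- NULL
  truths <- lapply(parts, `[[`, "truth")
  params <- do.call(rbind, lapply(truths, function(t) t$params))
  rownames(params) <- vapply(truths, `[[`, character(1), "participant")
  structure(list(
    data = data,
    truth = list(params_per_participant = params,
                 betas = stats::setNames(
                   vapply(truths, `[[`, numeric(1), "beta"),
                   rownames(params)),
                 group_params = stats::setNames(
                   as.numeric(config$group_params),
                   names(config$group_params)),
                 seed = config$seed,
                 config = unclass(config)[setdiff(names(unclass(config)),
                                                  "group_params")]),
    schedule = schedule),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf("Synthetic %s cohort: %d participants x %d trials (seed %d)\n",
              cfg$group, cfg$n_participants, nrow(x$schedule), cfg$seed))
  cat("  channels:", paste(unique(x$data$channel), collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the long-format CSV read by [read_trial_table()] plus a JSON truth
#' file holding the generating parameters, betas, seed and config.
#'
#' @param cohort A `synthetic_cohort`.
#' @param csv_path Path for the data CSV.
#' @param truth_path Path for the truth JSON (default: `csv_path` with a
#'   `_truth.json` suffix).
#' @return `csv_path`, invisibly.
#' @export
write_synthetic_cohort <- function(cohort, csv_path,
                                   truth_path = sub("\\.csv$", "_truth.json",
                                                    csv_path)) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  write_cohort(cohort$data, csv_path)
  truth <- cohort$truth
  truth$params_per_participant <- as.data.frame(truth$params_per_participant)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(csv_path)
}
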