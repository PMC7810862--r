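#' Default phase specification for the interleaved-training paradigm
#'
#' The canonical 288-trial schedule: 64 aligned trials, 160 trials with a +30
#' degree rotation (in compensation space, so the perturbation participants
#' must counter is +30), 16 trials with the opposite rotation (-30), and 48
#' error-clamp trials in which no performance error is experienced.
#'
#' @return A data frame with columns `length`, `perturbation`, `clamp`,
#'   `label`, one row per phase, suitable for [build_schedule()].
#' @export
default_phase_spec <- function() {
  data.frame(
    length       = c(64L, 160L, 16L, 48L),
    perturbation = c(0, 30, -30, 0),
    clamp        = c(FALSE, FALSE, FALSE, TRUE),
    label        = c("aligned", "rotation1", "rotation2", "clamp"),
    stringsAsFactors = FALSE
  )
}

#' Build a per-trial perturbation schedule
#'
#' Expands an ordered phase specification into a per-trial schedule carrying
#' the signed perturbation (degrees, in compensation space: positive values
#' are deviations that counter the imposed rotation), an error-clamp flag,
#' a phase label and a training-target angle. Target angles cycle through
#' 60, 80, 100, 120 degrees in blocks of four within each phase.
#'
#' @param phase_spec Data frame with columns `length` (positive integer
#'   trials), `perturbation` (degrees) and `clamp` (logical); an optional
#'   `label` column names the phases. Defaults to [default_phase_spec()].
#' @param targets Numeric vector of training-target angles cycled within
#'   blocks.
#'
#' @return An object of class `perturbation_schedule`: a data frame with one
#'   row per trial and columns `trial`, `phase`, `perturbation`, `is_clamp`,
#'   `target`.
#' @examples
#' sched <- build_schedule()
#' nrow(sched)            # 288
#' sched$phase[65]        # first rotated trial
#' @export
build_schedule <- function(phase_spec = default_phase_spec(),
                           targets = c(60, 80, 100, 120)) {
  if (!is.data.frame(phase_spec) || nrow(phase_spec) == 0L)
    stop("`phase_spec` must be a non-empty data frame of phases")
  required <- c("length", "perturbation", "clamp")
  missing_cols <- setdiff(required, names(phase_spec))
  if (length(missing_cols))
    stop("`phase_spec` lacks column(s): ", paste(missing_cols, collapse = ", "))
  len <- phase_spec$length
  if (any(!is.finite(len)) || any(len <= 0) || any(len != round(len)))
    stop("phase lengths must be positive integers; got: ",
         paste(len, collapse = ", "))
  len <- as.integer(len)

  label <- if ("label" %in% names(phase_spec)) as.character(phase_spec$label)
           else rep(NA_character_, nrow(phase_spec))
  n_rot <- 0L
  for (i in seq_along(label)) {
    if (!is.na(label[i]) && nzchar(label[i])) {
      if (phase_spec$perturbation[i] != 0 && !phase_spec$clamp[i]) n_rot <- n_rot + 1L
      next
    }
    if (isTRUE(phase_spec$clamp[i])) {
      label[i] <- "clamp"
    } else if (phase_spec$perturbation[i] == 0) {
      label[i] <- "aligned"
    } else {
      n_rot <- n_rot + 1L
      label[i] <- paste0("rotation", n_rot)
    }
  }
  # disambiguate repeated labels so per-phase windows stay well defined
  dup <- duplicated(label)
  if (any(dup)) label[dup] <- paste0(label[dup], ".", cumsum(dup)[dup] + 1L)

  n <- sum(len)
  per_phase_targets <- function(k) targets[((seq_len(k) - 1L) %% length(targets)) + 1L]
  out <- data.frame(
    trial        = seq_len(n),
    phase        = rep(label, times = len),
    perturbation = rep(phase_spec$perturbation, times = len),
    is_clamp     = rep(as.logical(phase_spec$clamp), times = len),
    target       = unlist(lapply(len, per_phase_targets), use.names = FALSE),
    stringsAsFactors = FALSE
  )
  class(out) <- c("perturbation_schedule", "data.frame")
  out
}

#' @export
print.perturbation_schedule <- function(x, ...) {
  cat("Perturbation schedule:", nrow(x), "trials\n")
  rl <- rle(x$phase)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  for (i in seq_along(rl$values)) {
    cat(sprintf("  %-12s trials %3d-%3d  perturbation %+g deg%s\n",
                rl$values[i], starts[i], ends[i],
                x$perturbation[starts[i]],
                if (x$is_clamp[starts[i]]) "  [error clamp]" else ""))
  }
  invisible(x)
}

#' Analysis trial windows of a schedule
#'
#' Returns the 1-based trial indices of the four standard analysis windows:
#' `R1` (first four trials of the first rotation), `R1_Late` (its last four),
#' `R2` (last four trials of the counter rotation) and `EC` (last 16
#' error-clamp trials, kept short for a less noisy estimate).
#'
#' @param schedule A `perturbation_schedule`.
#' @return Named list of integer index vectors.
#' @export
trial_windows <- function(schedule) {
  stopifnot(inherits(schedule, "perturbation_schedule"))
  idx <- function(phase) which(schedule$phase == phase)
  r1 <- idx("rotation1"); r2 <- idx("rotation2"); ec <- idx("clamp")
  if (!length(r1) || !length(r2) || !length(ec))
    stop("schedule lacks rotation1/rotation2/clamp phases needed for trial windows")
  list(
    R1      = r1[seq_len(min(4L, length(r1)))],
    R1_Late = r1[seq.int(max(1L, length(r1) - 3L), length(r1))],
    R2      = r2[seq.int(max(1L, length(r2) - 3L), length(r2))],
    EC      = ec[seq.int(max(1L, length(ec) - 15L), length(ec))]
  )
}

#' Mean deviation over the analysis trial windows
#'
#' Computes the mean angular deviation over each analysis window (R1,
#' R1_Late, R2, EC). Missing values are ignored within a window; a window
#' with no observed values is reported as `NA`.
#'
#' @param series Numeric vector of per-trial deviations (degrees) aligned to
#'   the schedule; `NA` marks missing trials.
#' @param schedule A `perturbation_schedule` covering the series.
#' @return Object of class `trial_sets`: named list with elements `R1`,
#'   `R1_Late`, `R2`, `EC` (degrees).
#' @export
extract_trial_sets <- function(series, schedule) {
  stopifnot(inherits(schedule, "perturbation_schedule"))
  if (length(series) != nrow(schedule))
    stop("series length (", length(series), ") does not match schedule (",
         nrow(schedule), " trials)")
  win <- trial_windows(schedule)
  sets <- lapply(win, function(ix) {
    v <- series[ix]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  structure(sets, class = "trial_sets")
}

#' @export
print.trial_sets <- function(x, ...) {
  cat("Trial-set means (deg):\n")
  for (nm in names(x)) cat(sprintf("  %-8s %s\n", nm,
                                   formatC(x[[nm]], digits = 3, format = "fg")))
  invisible(x)
}

#' Baseline-normalize trial series
#'
#' Subtracts, per participant and channel, the mean deviation over the
#' baseline trials (by default trials 33-64, the second half of the aligned
#' phase) from every value of that participant and channel. Each channel is
#' normalized by its own baseline.
#'
#' @param cohort Either a numeric per-trial vector, or a long-format data
#'   frame with columns `participant`, `channel`, `trial`, `value`.
#' @param baseline_trials Integer trial indices defining the baseline window.
#' @return Same shape as the input, baseline-subtracted.
#' @export
normalize_baseline <- function(cohort, baseline_trials = 33:64) {
  if (is.numeric(cohort)) {
    b <- cohort[baseline_trials]
    if (all(is.na(b))) stop("all baseline trials are missing")
    return(cohort - mean(b, na.rm = TRUE))
  }
  check_cohort(cohort)
  split_id <- interaction(cohort$participant, cohort$channel, drop = TRUE)
  for (grp in levels(split_id)) {
    ix <- which(split_id == grp)
    b <- cohort$value[ix][cohort$trial[ix] %in% baseline_trials]
    if (length(b) == 0L || all(is.na(b))) {
      stop("all baseline trials missing for participant '",
           cohort$participant[ix][1], "', channel '", cohort$channel[ix][1], "'")
    }
    cohort$value[ix] <- cohort$value[ix] - mean(b, na.rm = TRUE)
  }
  cohort
}

#' Remove cross-participant outliers
#'
#' For every (channel, trial) cell, marks values lying more than
#' `threshold_sd` standard deviations from the cross-participant mean as
#' missing. The population standard deviation is used and the rule is applied
#' once, not iterated, so the SD is not recomputed after removal.
#' Zero-variance cells remove nothing.
#'
#' @param cohort Long-format data frame (`participant`, `channel`, `trial`,
#'   `value`).
#' @param threshold_sd Positive cutoff in standard deviations (default 3).
#' @return Object of class `outlier_report`: list with elements `cohort`
#'   (values replaced by `NA` where removed), `n_checked`, `n_removed` and
#'   `fraction` removed.
#' @export
remove_outliers <- function(cohort, threshold_sd = 3) {
  if (!is.numeric(threshold_sd) || length(threshold_sd) != 1L || threshold_sd <= 0)
    stop("`threshold_sd` must be a single positive number")
  check_cohort(cohort)
  cell <- interaction(cohort$channel, cohort$trial, drop = TRUE)
  removed <- logical(nrow(cohort))
  for (grp in levels(cell)) {
    ix <- which(cell == grp)
    v <- cohort$value[ix]
    ok <- !is.na(v)
    if (sum(ok) < 3L) next   # undefined spread with fewer than 3 participants
    m <- mean(v[ok])
    s <- sqrt(mean((v[ok] - m)^2))   # population SD across participants
    if (s == 0) next
    out <- ok & abs(v - m) > threshold_sd * s
    removed[ix[out]] <- TRUE
  }
  cohort$value[removed] <- NA_real_
  n_checked <- sum(!is.na(cohort$value)) + sum(removed)
  structure(list(cohort = cohort,
                 n_checked = n_checked,
                 n_removed = sum(removed),
                 fraction = if (n_checked > 0) sum(removed) / n_checked else 0),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("Outlier removal: %d of %d values removed (%.2f%%)\n",
              x$n_removed, x$n_checked, 100 * x$fraction))
  invisible(x)
}
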