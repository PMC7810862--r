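#' Validate a long-format cohort table
#'
#' @param cohort Data frame expected to carry columns `participant`,
#'   `channel`, `trial`, `value` (a `phase` column is tolerated).
#' @return The cohort, invisibly, after validation.
#' @keywords internal
check_cohort <- function(cohort) {
  if (!is.data.frame(cohort))
    stop("cohort must be a data frame in long format")
  required <- c("participant", "channel", "trial", "value")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks column(s): ", paste(missing_cols, collapse = ", "))
  key <- paste(cohort$participant, cohort$channel, cohort$trial, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (participant, channel, trial) rows, first at row ", dup[1])
  if (!is.numeric(cohort$value))
    stop("`value` must be numeric")
  bad <- which(!is.na(cohort$value) & !is.finite(cohort$value))
  if (length(bad))
    stop("non-finite value at row ", bad[1])
  invisible(cohort)
}

#' Read a long-format trial table
#'
#' Reads a CSV with header `participant,channel,trial,phase,value` (empty
#' `value` fields are missing data) and validates it: the header must match,
#' `value` must parse as numeric, and (participant, channel, trial) keys must
#' be unique. Row counts and missing-value counts are reported via
#' [message()].
#'
#' @param path Path to the CSV file.
#' @return Validated long-format data frame.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- utils::read.csv(path, nrows = 1, header = FALSE,
                            stringsAsFactors = FALSE)
  expected <- c("participant", "channel", "trial", "phase", "value")
  if (ncol(header) != length(expected) ||
      !all(trimws(unlist(header)) == expected))
    stop("malformed header in ", path, ": expected '",
         paste(expected, collapse = ","), "'")
  dat <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "integer",
                                        "character", "character"))
  if (nrow(dat) == 0L) stop("no records in ", path)
  raw <- trimws(dat$value)
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(nzchar(raw) & is.na(val))
  if (length(bad))
    stop("non-numeric value '", raw[bad[1]], "' at data row ", bad[1],
         " of ", path)
  dat$value <- val
  key <- paste(dat$participant, dat$channel, dat$trial, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (participant, channel, trial) at data row ", dup[1],
         " of ", path)
  message(sprintf("read %d rows (%d missing values) from %s",
                  nrow(dat), sum(is.na(dat$value)), path))
  dat
}

#' Write a cohort to long-format CSV
#'
#' Inverse of [read_trial_table()]: comma-separated, UTF-8, missing values
#' as empty fields, header `participant,channel,trial,phase,value`.
#'
#' @param cohort Long-format data frame; a `phase` column is added (empty)
#'   if absent.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  check_cohort(cohort)
  if (!"phase" %in% names(cohort)) cohort$phase <- ""
  cohort <- cohort[, c("participant", "channel", "trial", "phase", "value")]
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a schedule to CSV
#'
#' Serializes a [build_schedule()] result with header
#' `trial,phase,perturbation,is_clamp,target`.
#'
#' @param schedule A `perturbation_schedule`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "perturbation_schedule"))
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a schedule written by [write_schedule()]
#' @param path CSV path.
#' @return A `perturbation_schedule`.
#' @export
read_schedule <- function(path) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("trial", "phase", "perturbation", "is_clamp", "target")
  if (!all(required %in% names(dat)))
    stop("malformed schedule file: ", path)
  dat$is_clamp <- as.logical(dat$is_clamp)
  class(dat) <- c("perturbation_schedule", "data.frame")
  dat
}

#' Per-trial group-mean series for one channel
#'
#' Averages a cohort's values across participants for each trial of one
#' channel, on a 1..n_trials axis; trials with no observations are `NA`.
#'
#' @param cohort Long-format data frame.
#' @param channel Channel name to average.
#' @param n_trials Length of the trial axis.
#' @return Numeric vector of length `n_trials`.
#' @export
channel_means <- function(cohort, channel, n_trials) {
  check_cohort(cohort)
  sub <- cohort[cohort$channel == channel & !is.na(cohort$value), , drop = FALSE]
  out <- rep(NA_real_, n_trials)
  if (nrow(sub)) {
    m <- tapply(sub$value, sub$trial, mean)
    ix <- as.integer(names(m))
    keep <- ix >= 1L & ix <= n_trials
    out[ix[keep]] <- as.numeric(m)[keep]
  }
  out
}

#' Per-participant matrix for one channel
#'
#' @param cohort Long-format data frame.
#' @param channel Channel name.
#' @param n_trials Length of the trial axis.
#' @return Numeric matrix, participants in rows, trials in columns.
#' @export
channel_matrix <- function(cohort, channel, n_trials) {
  check_cohort(cohort)
  sub <- cohort[cohort$channel == channel, , drop = FALSE]
  ids <- unique(sub$participant)
  mat <- matrix(NA_real_, nrow = length(ids), ncol = n_trials,
                dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    rows <- sub[sub$participant == ids[i], , drop = FALSE]
    keep <- rows$trial >= 1L & rows$trial <= n_trials
    mat[i, rows$trial[keep]] <- rows$value[keep]
  }
  mat
}
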