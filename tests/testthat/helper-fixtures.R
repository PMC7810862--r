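# Shared fixtures, built in code at test time.

default_sched <- build_schedule()

# long-format cohort from a participants x trials value matrix
cohort_from_matrix <- function(mat, channel = "training",
                               schedule = default_sched) {
  do.call(rbind, lapply(seq_len(nrow(mat)), function(i) {
    data.frame(participant = sprintf("p%02d", i), channel = channel,
               trial = seq_len(ncol(mat)), phase = schedule$phase[seq_len(ncol(mat))],
               value = mat[i, ], stringsAsFactors = FALSE)
  }))
}

# random feasible two-rate parameter set, away from the unit bounds so the
# steady state exists and convergence is geometric
random_valid_params <- function() {
  Rs <- runif(1, 0.8, 0.98)
  Rf <- runif(1, 0.2, Rs - 0.1)
  Lf <- runif(1, 0.15, 0.6)
  Ls <- runif(1, 0.02, Lf - 0.05)
  two_rate_params(Rs, Ls, Rf, Lf)
}

# constant-perturbation schedule of n trials at P degrees
constant_schedule <- function(n, P) {
  build_schedule(data.frame(length = n, perturbation = P, clamp = FALSE))
}
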