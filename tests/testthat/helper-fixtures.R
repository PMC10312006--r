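# Build a raw_recording data frame by hand from explicit eye traces.
make_raw <- function(left, right, participant = "P01", group = "A",
                     trial = 1L, rate_hz = 60) {
  n <- length(left)
  structure(data.frame(participant_id = participant, group = group,
                       trial_id = as.integer(trial),
                       timestamp_ms = (seq_len(n) - 1) / rate_hz * 1000,
                       pupil_left_mm = left, pupil_right_mm = right,
                       validity_left = as.integer(!is.na(left)),
                       validity_right = as.integer(!is.na(right)),
                       stringsAsFactors = FALSE),
            class = c("raw_recording", "data.frame"))
}

# Internal prepared-trial representation used by exclude_by_missingness().
make_prepared <- function(participant, block, n_missing, n_total) {
  list(participant_id = participant, group = "A", block_id = as.integer(block),
       series = numeric(0), time_s = numeric(0),
       n_missing = n_missing, n_total = n_total,
       missing_fraction = n_missing / n_total)
}

# Noise-free simulation world: both eyes flat at baseline unless an effect
# or the light reflex is switched on.
quiet_world <- function(trial_length_s = 20, ...) {
  sim_config(trial_length_s = trial_length_s, phi = 0, tonic_sd = 0,
             noise_sd = 0, blink_rate_hz = 0, light_reflex_amp_mm = 0, ...)
}

# Gaussian AR(1) matrix generator used as an independent source in tests
# (deliberately not the package generator).
ar1_matrix <- function(n, T, phi, seed) {
  set.seed(seed)
  t(vapply(seq_len(n), function(i) {
    x <- numeric(T)
    x[1] <- rnorm(1)
    for (t in 2:T) x[t] <- phi * x[t - 1] + sqrt(1 - phi^2) * rnorm(1)
    x
  }, numeric(T)))
}
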