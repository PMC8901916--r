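# Fixture builders shared across the suite (all generated in code).

# random strictly positive signal with a reproducible seed
random_positive_signal <- function(seed, n = NULL, log_sd = 1) {
  set.seed(seed)
  if (is.null(n)) n <- sample(2:50, 1)
  exp(stats::rnorm(n, sd = log_sd))
}

# small deterministic carrier with geometric spacing (fast tail decay)
fixture_carrier <- function(n = 24) apd_carrier_signal(n)

# sinusoid plus one localized spike, on a positive scale
spike_series <- function(n = 1024, spike_at = 600, amp = 6, seed = 42) {
  set.seed(seed)
  base <- sin(2 * pi * seq_len(n) / 128) + stats::rnorm(n, sd = 0.1)
  base[spike_at] <- base[spike_at] + amp
  preprocess_to_positive(base, 1, 2)$values
}

# tiny complete cohort for featurizer tests (kept small for speed)
tiny_cohort <- function(n_per_class = 2, channels = 3, duration_s = 0.5,
                        seed = 7, missing = 0) {
  generate_cohort(synthetic_config(
    n_per_class = n_per_class,
    channels = paste0("ch", seq_len(channels)),
    duration_s = duration_s, missing = missing, seed = seed))
}

fast_feature_args <- function() {
  list(n_support = 48, max_obs = 160, maxit = 120)
}
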