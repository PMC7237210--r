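# Shared fixtures and independent oracles.

# O(N*M) brute-force evaluation of the tolerance-window match count:
# the number of ground-truth events with at least one sorted event within
# delta. Stays independent of the package's efficient matcher.
brute_force_matches <- function(gt_times, sorted_times, delta) {
  if (!length(gt_times) || !length(sorted_times)) return(0L)
  sum(vapply(gt_times, function(t) {
    any(abs(t - sorted_times) <= delta)
  }, logical(1)))
}

# Random strictly increasing spike train within [1, t_max].
random_train <- function(n, t_max = 1e5) {
  sort(sample.int(t_max, n))
}

# Random small firings object with `n_units` units.
random_firings <- function(n_units, events_per_unit, t_max = 1e5) {
  smp <- c(); lab <- c()
  for (u in seq_len(n_units)) {
    smp <- c(smp, random_train(events_per_unit, t_max))
    lab <- c(lab, rep(u, events_per_unit))
  }
  firings(rep(0, length(smp)), smp, lab)
}

# Tiny deterministic recording with one inserted square pulse per event.
pulse_recording <- function(n_channels = 2, n_samples = 3000,
                            sample_rate = 30000) {
  recording(matrix(0, n_channels, n_samples), sample_rate)
}
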