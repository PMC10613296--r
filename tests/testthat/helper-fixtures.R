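# Shared fixture builders; everything is generated in code at test time.

# Deterministic spike dataset: each trial of a level has exactly the given
# number of spikes, evenly spaced inside `window`.
det_spike_dataset <- function(counts_by_level, n_trials_per_level = 10,
                              window = c(0.25, 1.75), trial_duration = 2,
                              neuron_id = "det_n001", region = "amygdala") {
  lv <- names(counts_by_level)
  trials <- data.frame(
    neuron_id = neuron_id, region = region,
    trial_id = seq_len(length(lv) * n_trials_per_level),
    ambiguity_level = rep(lv, each = n_trials_per_level),
    stringsAsFactors = FALSE)
  sp <- do.call(rbind, lapply(seq_len(nrow(trials)), function(i) {
    k <- counts_by_level[[trials$ambiguity_level[i]]]
    if (k == 0) return(NULL)
    data.frame(neuron_id = neuron_id, region = region,
               trial_id = trials$trial_id[i],
               spike_time_s = window[1] +
                 (seq_len(k) - 0.5) / k * (window[2] - window[1]),
               ambiguity_level = trials$ambiguity_level[i],
               stringsAsFactors = FALSE)
  }))
  if (is.null(sp)) {
    sp <- data.frame(neuron_id = character(0), region = character(0),
                     trial_id = integer(0), spike_time_s = numeric(0),
                     ambiguity_level = character(0))
  }
  spike_dataset(sp, trials, trial_duration)
}

# Epochs assembled directly from a channels x samples x trials array.
epochs_from_array <- function(dat, fs = 250, t0 = -0.5,
                              channel_names = NULL, condition = NULL) {
  nc <- dim(dat)[1]
  if (is.null(channel_names)) {
    channel_names <- c("Pz", "Cz", "FCz", sprintf("X%d", seq_len(nc)))[
      seq_len(nc)]
  }
  if (is.null(condition)) {
    condition <- rep("anchor", dim(dat)[3])
  }
  eeg_epochs(dat, fs = fs, t0 = t0, channel_names = channel_names,
             condition = condition)
}

# The two-region latency simulation used by the differential-latency
# tests: `n_neurons` per group, rate step of +`step_hz` at `onset_s` for
# the preferred condition over a `baseline_hz` baseline.
latency_groups <- function(n_neurons = 30, n_trials = 100,
                           onset_a = 0.3, onset_b = 0.6,
                           baseline_hz = 5, step_hz = 10,
                           seed_a = 11, seed_b = 12) {
  amy <- gen_spikes(spike_truth(
    n_neurons = n_neurons, region_label = "amygdala",
    baseline_rate = baseline_hz, modulation_per_level = -step_hz / 2,
    reference_level = "high", onset_latency = onset_a,
    trial_duration = 2, n_trials_per_level = n_trials, seed = seed_a))
  dmp <- gen_spikes(spike_truth(
    n_neurons = n_neurons, region_label = "dmPFC",
    baseline_rate = baseline_hz, modulation_per_level = step_hz / 2,
    reference_level = "anchor", onset_latency = onset_b,
    trial_duration = 2, n_trials_per_level = n_trials, seed = seed_b))
  list(
    a = oriented_curves(cumulative_curves(amy), "anchor", "high"),
    b = oriented_curves(cumulative_curves(dmp), "high", "anchor"))
}
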