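#!/usr/bin/env Rscript
# Stage 1: generate every synthetic dataset the downstream analyses read.
#
# Writes under results/data/:
#   behavior.csv               24 participants (12 control, 12 patient with
#                              doubled RT-ambiguity gain), 7 morph levels
#   spikes_amygdala*.csv       30 unambiguous-preferring neurons, rate step
#                              +10 Hz at 300 ms
#   spikes_dmpfc*.csv          30 ambiguous-preferring neurons, step at 600 ms
#   epochs.{csv,json}          5-channel oscillatory epochs, Pz-Cz coherence
#                              targets and graded delta->alpha coupling
#   sources.{csv,json}         2-source MVAR(1) trials with 1 -> 2 coupling

library(ambiguitynet)

seed <- 20260919L
out <- file.path("results", "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("-- behavior: 12 controls + 12 high-gain patients")
sessions <- list()
for (i in 1:12) {
  sessions[[i]] <- gen_behavior(
    behavior_truth(x_half = 50, alpha_slope = 0.2,
                   rt_ambiguity_gain = 0.15, n_trials_per_level = 40,
                   seed = seed + i),
    participant_id = sprintf("ctrl%02d", i), group_label = "control")
  sessions[[12 + i]] <- gen_behavior(
    behavior_truth(x_half = 50, alpha_slope = 0.2,
                   rt_ambiguity_gain = 0.30, n_trials_per_level = 40,
                   seed = seed + 100 + i),
    participant_id = sprintf("pat%02d", i), group_label = "patient")
}
write_behavior_csv(do.call(rbind, sessions),
                   file.path(out, "behavior.csv"))

message("-- spikes: two regions with distinct response onsets")
amy <- gen_spikes(spike_truth(
  n_neurons = 30, region_label = "amygdala", baseline_rate = 5,
  modulation_per_level = -5, reference_level = "high",
  onset_latency = 0.3, trial_duration = 2, n_trials_per_level = 100,
  seed = seed + 201))
dmp <- gen_spikes(spike_truth(
  n_neurons = 30, region_label = "dmPFC", baseline_rate = 5,
  modulation_per_level = 5, reference_level = "anchor",
  onset_latency = 0.6, trial_duration = 2, n_trials_per_level = 100,
  seed = seed + 202))
write_spike_csv(amy, file.path(out, "spikes_amygdala"))
write_spike_csv(dmp, file.path(out, "spikes_dmpfc"))

message("-- EEG epochs: coherence targets + graded delta->alpha coupling")
targets <- data.frame(chan_a = "Pz", chan_b = "Cz",
                      band = rep(c("theta", "alpha"), each = 3),
                      condition = rep(ambiguity_levels(), 2),
                      coherence = rep(c(0.55, 0.40, 0.25), 2))
ep <- gen_eeg_epochs(eeg_truth(
  n_channels = 5, channel_names = c("Pz", "Cz", "FCz", "Fz", "Oz"),
  coherence_targets = targets,
  cfc_gain = c(anchor = 0.1, intermediate = 0.35, high = 0.6),
  n_trials_per_condition = 30, seed = seed + 301))
write_eeg_epochs(ep, file.path(out, "epochs"))

message("-- MVAR source series: unidirectional 1 -> 2 coupling")
A1 <- matrix(c(0.5, 0.4, 0, 0.5), 2, 2)
ser <- gen_mvar_series(mvar_truth(
  list(A1), n_samples = 150, n_trials = 40, fs = 250,
  source_names = c("R.dmPFC", "L.occipital"), seed = seed + 401))
write_source_csv(ser, file.path(out, "sources"))

message("done; ground truth: x_half 50%, alpha 0.2, RT gain 0.15/0.30 s,")
message("onsets 300/600 ms, Pz-Cz coherence 0.55/0.40/0.25 by condition,")
message("delta->alpha gain 0.1/0.35/0.6, MVAR coupling only 1 -> 2")
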