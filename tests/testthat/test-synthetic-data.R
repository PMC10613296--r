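# The generators must reproduce the statistical structure each analysis
# stage assumes, with exact determinism under a fixed seed.

test_that("behavioral generator follows the logistic choice model", {
  # steep-slope limit: the curve degenerates to a step at x_half = 50
  tr <- behavior_truth(p_inf = 1, x_half = 50, alpha_slope = 1e3,
                       n_trials_per_level = 50, seed = 5)
  s <- gen_behavior(tr)
  expect_true(all(s$choice[s$morph_pct %in% c(70, 100)] == "fear"))
  expect_true(all(s$choice[s$morph_pct %in% c(0, 30, 40)] == "happy"))

  # at the inflection point the fear proportion is 1/2 (3 binomial SE)
  tr <- behavior_truth(p_inf = 1, x_half = 50, alpha_slope = 0.1,
                       n_trials_per_level = 200, seed = 7)
  s <- gen_behavior(tr)
  p50 <- mean(s$choice[s$morph_pct == 50] == "fear")
  expect_lt(abs(p50 - 0.5), 3 * sqrt(0.25 / 200))
})

test_that("RT inflation under ambiguity is controlled by the gain", {
  tr0 <- behavior_truth(rt_ambiguity_gain = 0, rt_noise_sd = 0.1,
                        n_trials_per_level = 300, seed = 3)
  s <- gen_behavior(tr0)
  # no gain: high-vs-anchor RT difference is pure noise, bounded by a few
  # standard errors of the difference of means
  expect_lt(abs(ambiguity_sensitivity(s)$delta_rt), 0.02)
  expect_true(all(s$rt_s > 0))

  tr1 <- behavior_truth(rt_ambiguity_gain = 0.3, rt_noise_sd = 0.1,
                        n_trials_per_level = 300, seed = 3)
  s1 <- gen_behavior(tr1)
  lv1 <- group_ambiguity(s1$morph_pct)
  m1 <- tapply(s1$rt_s, lv1, mean)
  expect_gt(m1[["high"]], m1[["anchor"]] + 0.2)
})

test_that("generators are deterministic in the seed and vary across seeds", {
  a <- gen_behavior(behavior_truth(seed = 9))
  b <- gen_behavior(behavior_truth(seed = 9))
  c <- gen_behavior(behavior_truth(seed = 10))
  expect_identical(a, b)
  expect_false(identical(a$choice, c$choice) && identical(a$rt_s, c$rt_s))

  s1 <- gen_spikes(spike_truth(seed = 4))
  s2 <- gen_spikes(spike_truth(seed = 4))
  expect_identical(s1, s2)

  e1 <- gen_eeg_epochs(eeg_truth(seed = 4, n_trials_per_condition = 2))
  e2 <- gen_eeg_epochs(eeg_truth(seed = 4, n_trials_per_condition = 2))
  expect_identical(e1$data, e2$data)

  m1 <- gen_mvar_series(mvar_truth(list(matrix(0.5, 1, 1)), seed = 4))
  m2 <- gen_mvar_series(mvar_truth(list(matrix(0.5, 1, 1)), seed = 4))
  expect_identical(m1$data, m2$data)
})

test_that("generated choice proportions converge to the logistic curve", {
  tr <- behavior_truth(p_inf = 1, x_half = 45, alpha_slope = 0.15,
                       n_trials_per_level = 1e4, seed = 21)
  s <- gen_behavior(tr)
  x <- morph_grid()
  p_hat <- vapply(x, function(m) mean(s$choice[s$morph_pct == m] == "fear"),
                  numeric(1))
  p_true <- 1 / (1 + exp(-0.15 * (x - 45)))
  expect_lt(max(abs(p_hat - p_true)), 0.02)
})

test_that("spike generator respects rates, onset and Poisson dispersion", {
  # no modulation: empirical rate matches baseline within 3 SE at each level
  tr <- spike_truth(baseline_rate = 10, modulation_per_level = 0,
                    onset_latency = 0, trial_duration = 1,
                    n_trials_per_level = 200, seed = 6)
  ds <- gen_spikes(tr)
  for (lv in ambiguity_levels()) {
    tids <- ds$trials$trial_id[ds$trials$ambiguity_level == lv]
    counts <- vapply(tids, function(ti) {
      sum(ds$spikes$trial_id == ti)
    }, numeric(1))
    expect_lt(abs(mean(counts) - 10), 3 * sqrt(10 / length(tids)))
    # Poisson dispersion: variance/mean near 1
    expect_gt(var(counts) / mean(counts), 0.8)
    expect_lt(var(counts) / mean(counts), 1.2)
  }

  # silent baseline: no spikes before onset
  tr2 <- spike_truth(baseline_rate = 0, modulation_per_level = 10,
                     onset_latency = 0.3, trial_duration = 1,
                     n_trials_per_level = 50, seed = 8)
  ds2 <- gen_spikes(tr2)
  expect_true(all(ds2$spikes$spike_time_s >= 0.3))
  expect_true(all(ds2$spikes$spike_time_s < 1))
})

test_that("spike truth validation rejects impossible rates", {
  expect_error(spike_truth(baseline_rate = 5, modulation_per_level = -5,
                           reference_level = "anchor"),
               "negative effective firing rate")
  expect_error(spike_truth(onset_latency = 3, trial_duration = 2),
               "onset_latency")
  # the same modulation is fine with the high-ambiguity reference
  expect_s3_class(spike_truth(baseline_rate = 5, modulation_per_level = -5,
                              reference_level = "high"), "spike_truth")
})

test_that("EEG generator hits coherence targets in closed form", {
  # target 1 in every band: Cz duplicates Pz's components entirely, so
  # the estimated coherence is ~1 across the whole analysis band
  tg <- data.frame(chan_a = "Pz", chan_b = "Cz",
                   band = c("delta", "theta", "alpha", "beta"),
                   condition = NA_character_, coherence = 1)
  ep <- gen_eeg_epochs(eeg_truth(n_channels = 3,
                                 channel_names = c("Pz", "Cz", "FCz"),
                                 coherence_targets = tg,
                                 n_trials_per_condition = 15, seed = 31))
  cm <- coherence_map(ep, band = c(4, 23))
  expect_gt(cm$band_mean[["Cz"]], 0.99)

  # target 0 everywhere: estimator bias ~ 1/K for K segments
  ep0 <- gen_eeg_epochs(eeg_truth(n_channels = 3,
                                  channel_names = c("Pz", "Cz", "FCz"),
                                  n_trials_per_condition = 20, seed = 32))
  cm0 <- coherence_map(ep0, band = c(4, 23), condition = "anchor")
  expect_lt(abs(cm0$band_mean[["Cz"]] - 1 / 20), 0.03)

  # intermediate target: shared-signal mixing closed form
  tg5 <- data.frame(chan_a = "Pz", chan_b = "Cz", band = "alpha",
                    condition = NA_character_, coherence = 0.5)
  ep5 <- gen_eeg_epochs(eeg_truth(n_channels = 3,
                                  channel_names = c("Pz", "Cz", "FCz"),
                                  coherence_targets = tg5,
                                  n_trials_per_condition = 60, seed = 33))
  cm5 <- coherence_map(ep5, band = c(8, 13))
  expect_lt(abs(cm5$band_mean[["Cz"]] - 0.5), 0.1)

  expect_error(
    eeg_truth(coherence_targets = data.frame(chan_a = "Pz", chan_b = "Cz",
                                             band = "alpha",
                                             coherence = 1.5)),
    "\\[0, 1\\]")
})

test_that("null CFC gain leaves the modulation index centered on zero", {
  mi <- vapply(1:25, function(i) {
    ep <- gen_eeg_epochs(eeg_truth(n_channels = 3,
                                   channel_names = c("Pz", "Cz", "FCz"),
                                   cfc_gain = 0,
                                   n_trials_per_condition = 5,
                                   seed = 400 + i))
    amplitude_cfc(ep, method = "parametric")$modulation_index
  }, numeric(1))
  expect_lt(abs(mean(mi)), 3 * sd(mi) / sqrt(length(mi)) + 0.02)
})

test_that("MVAR generator matches closed-form moments", {
  # degenerate process: white noise with the requested covariance
  sc <- matrix(c(2, 0.5, 0.5, 1), 2, 2)
  tr <- mvar_truth(list(matrix(0, 2, 2)), noise_cov = sc,
                   n_samples = 2e4, seed = 13)
  s <- gen_mvar_series(tr)
  emp <- stats::cov(t(s$data[, , 1]))
  expect_lt(max(abs(emp - sc)), 0.1)

  # AR(1) variance: 1/(1 - a^2)
  tr1 <- mvar_truth(list(matrix(0.9, 1, 1)), n_samples = 1e5, seed = 14)
  v <- var(as.vector(gen_mvar_series(tr1)$data))
  expect_lt(abs(v - 1 / (1 - 0.81)) / (1 / (1 - 0.81)), 0.1)

  # Yule-Walker lag-1 autocovariance of AR(1): a * var
  x <- as.vector(gen_mvar_series(tr1)$data)
  acov1 <- mean((x[-1] - mean(x)) * (x[-length(x)] - mean(x)))
  expect_lt(abs(acov1 - 0.9 * v) / abs(0.9 * v), 0.05)

  # unidirectional coupling: past of 1 predicts 2 beyond 2's own past,
  # but not the reverse (lagged-regression oracle)
  A1 <- matrix(c(0.5, 0.4, 0, 0.5), 2, 2)
  s2 <- gen_mvar_series(mvar_truth(list(A1), n_samples = 5e3, seed = 15))
  x1 <- s2$data[1, , 1]; x2 <- s2$data[2, , 1]
  n <- length(x1)
  fwd <- summary(lm(x2[-1] ~ x2[-n] + x1[-n]))$coefficients
  bwd <- summary(lm(x1[-1] ~ x1[-n] + x2[-n]))$coefficients
  expect_lt(fwd["x1[-n]", "Pr(>|t|)"], 1e-10)
  expect_gt(bwd["x2[-n]", "Pr(>|t|)"], 0.01)

  expect_error(mvar_truth(list(matrix(1.1, 1, 1))), "unstable")
})
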