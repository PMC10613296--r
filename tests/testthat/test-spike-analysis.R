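# Unit filtering, PSTH arithmetic, ambiguity-coding selection, cumulative
# curves and the differential-latency machinery.

test_that("unit filter keeps neurons at or above the rate threshold", {
  slow <- det_spike_dataset(c(anchor = 0, intermediate = 0, high = 1),
                            n_trials_per_level = 10, trial_duration = 2,
                            neuron_id = "slow")   # 10 spikes / 60 s
  fast <- det_spike_dataset(c(anchor = 3, intermediate = 3, high = 3),
                            n_trials_per_level = 10, trial_duration = 2,
                            neuron_id = "fast")
  ds <- spike_dataset(rbind(slow$spikes, fast$spikes),
                      rbind(slow$trials, fast$trials), 2)
  kept <- filter_units(ds, min_rate = 0.2)
  expect_identical(sort(unique(kept$trials$neuron_id)), "fast")

  # exact boundary is retained: 12 spikes over 12 trials x 5 s = 0.2 Hz
  bnd <- det_spike_dataset(c(anchor = 1, intermediate = 1, high = 1),
                           n_trials_per_level = 4, trial_duration = 5,
                           neuron_id = "boundary")
  expect_identical(unique(filter_units(bnd)$trials$neuron_id), "boundary")

  # all fast: identity
  expect_identical(filter_units(fast)$spikes, fast$spikes)
  expect_error(filter_units(spike_dataset(
    fast$spikes[0, ], fast$trials[0, ], 2)), "empty")
})

test_that("PSTH rates follow count / (n_trials * bin_width)", {
  # one spike per trial inside a 250 ms bin -> 4 Hz in that bin
  ds <- det_spike_dataset(c(anchor = 1, intermediate = 1, high = 1),
                          n_trials_per_level = 10,
                          window = c(0.30, 0.40), trial_duration = 2)
  p <- compute_psth(ds, "det_n001")
  expect_equal(dim(p$rates), c(3, 8))
  expect_true(all(p$rates[, 2] == 4))  # bin [0.25, 0.50)
  expect_true(all(p$rates[, -2] == 0))

  # empty spike trains -> all-zero PSTH
  ds0 <- det_spike_dataset(c(anchor = 0, intermediate = 0, high = 0))
  p0 <- compute_psth(ds0, "det_n001")
  expect_true(all(p0$rates == 0))

  # Poisson 10 Hz: every bin within 3 SE of 10 Hz at 500 trials/level
  ds1 <- gen_spikes(spike_truth(baseline_rate = 10,
                                modulation_per_level = 0,
                                onset_latency = 0, trial_duration = 1,
                                n_trials_per_level = 500, seed = 41))
  p1 <- compute_psth(ds1, ds1$trials$neuron_id[1])
  se <- sqrt(10 / (500 * 0.25))  # Poisson SE of a rate estimate
  expect_true(all(abs(p1$rates - 10) < 3.5 * se))
})

test_that("selection regression identifies graded rates and their sign", {
  # noise-free rates 10/8/6 Hz at anchor/intermediate/high
  ds <- det_spike_dataset(c(anchor = 15, intermediate = 12, high = 9),
                          n_trials_per_level = 10)
  sel <- select_ambiguity_neurons(ds)
  expect_true(sel$selected)
  expect_equal(sel$preference, "unambiguous")
  expect_equal(sel$slope, -2, tolerance = 1e-9)

  # spikes only outside the selection window: constant zero rate, flagged
  ds2 <- det_spike_dataset(c(anchor = 5, intermediate = 5, high = 5),
                           window = c(1.8, 2.0))
  sel2 <- select_ambiguity_neurons(ds2)
  expect_false(sel2$selected)
  expect_true(sel2$flagged)

  # ambiguous-preferring neuron
  ds3 <- det_spike_dataset(c(anchor = 6, intermediate = 9, high = 12),
                           n_trials_per_level = 10)
  expect_equal(select_ambiguity_neurons(ds3)$preference, "ambiguous")
})

test_that("selection fraction under a Poisson null is near alpha", {
  set.seed(52)
  frac <- vapply(1:10, function(i) {
    ds <- gen_spikes(spike_truth(n_neurons = 100, baseline_rate = 5,
                                 modulation_per_level = 0,
                                 n_trials_per_level = 20,
                                 seed = 5200 + i))
    mean(select_ambiguity_neurons(ds)$selected)
  }, numeric(1))
  n_tot <- 1000
  band <- 1.96 * sqrt(0.05 * 0.95 / n_tot)
  expect_lt(abs(mean(frac) - 0.05), band + 0.01)
})

test_that("population binomial reproduces the published worked examples", {
  expect_equal(signif(population_binomial(36, 321, 0.05), 3), 2.58e-6)
  expect_equal(signif(population_binomial(29, 236, 0.05), 3), 3.09e-6)
  expect_error(population_binomial(50, 40), "exceed")
})

test_that("cumulative curves count spikes correctly and monotonically", {
  tr <- data.frame(neuron_id = "n1", region = "amygdala",
                   trial_id = 1:3,
                   ambiguity_level = c("anchor", "intermediate", "high"))
  sp <- data.frame(neuron_id = "n1", region = "amygdala", trial_id = 1,
                   spike_time_s = 0.5, ambiguity_level = "anchor")
  ds <- spike_dataset(sp, tr, 1)
  cc <- cumulative_curves(ds)
  m <- cc$curves[["n1"]]
  expect_true(all(m["anchor", cc$times < 0.5] == 0))
  expect_true(all(m["anchor", cc$times >= 0.5] == 1))

  ds2 <- gen_spikes(spike_truth(baseline_rate = 8, seed = 3,
                                n_trials_per_level = 20))
  cc2 <- cumulative_curves(ds2)
  for (m2 in cc2$curves) {
    expect_true(all(apply(m2, 1, function(r) all(diff(r) >= 0))))
    # end point equals the mean spike count per trial at each level
    for (lv in rownames(m2)) {
      tids <- ds2$trials$trial_id[ds2$trials$ambiguity_level == lv]
      expect_equal(unname(m2[lv, ncol(m2)]),
                   sum(ds2$spikes$trial_id %in% tids) / length(tids),
                   tolerance = 1e-9)
    }
  }
})

test_that("differential latency recovers a known rate-step onset", {
  g <- latency_groups(n_neurons = 12, n_trials = 60, seed_a = 61,
                      seed_b = 62)
  la <- differential_latency(g$a)
  lb <- differential_latency(g$b)
  expect_lt(abs(la$latency_ms - 300), 60)
  expect_lt(abs(lb$latency_ms - 600), 60)

  # identical condition curves: no cluster, latency undefined
  null_oc <- structure(list(pref = g$a$pref, nonpref = g$a$pref,
                            times = g$a$times),
                       class = "oriented_curves")
  expect_true(is.na(differential_latency(null_oc)$latency_ms))
  expect_error(differential_latency(structure(
    list(pref = g$a$pref[1:2, ], nonpref = g$a$nonpref[1:2, ],
         times = g$a$times), class = "oriented_curves")), ">= 3 neurons")
})

test_that("latency estimate shifts with the injected onset (equivariance)", {
  mk <- function(onset) {
    ds <- gen_spikes(spike_truth(n_neurons = 12, baseline_rate = 5,
                                 modulation_per_level = -5,
                                 reference_level = "high",
                                 onset_latency = onset,
                                 trial_duration = 2,
                                 n_trials_per_level = 60, seed = 71))
    differential_latency(
      oriented_curves(cumulative_curves(ds), "anchor", "high"))$latency_ms
  }
  l300 <- mk(0.3)
  l600 <- mk(0.6)
  expect_lt(abs((l600 - l300) - 300), 60)
})

test_that("latency is insensitive to added baseline spikes", {
  g <- latency_groups(n_neurons = 12, n_trials = 60, seed_a = 81,
                      seed_b = 82)
  l0 <- differential_latency(g$a)$latency_ms
  # add the same neuron-specific constant cumulative drift to both
  # conditions (a baseline-rate offset common to all trials of a neuron)
  set.seed(83)
  drift <- matrix(rexp(nrow(g$a$pref), rate = 1 / 5),
                  nrow(g$a$pref), length(g$a$times)) *
    matrix(g$a$times, nrow(g$a$pref), length(g$a$times), byrow = TRUE)
  g2 <- structure(list(pref = g$a$pref + drift,
                       nonpref = g$a$nonpref + drift,
                       times = g$a$times), class = "oriented_curves")
  expect_equal(differential_latency(g2)$latency_ms, l0)
})

test_that("latency permutation separates distinct onsets and is seeded", {
  g <- latency_groups(n_neurons = 15, n_trials = 60, seed_a = 91,
                      seed_b = 92)
  lp <- latency_permutation(g$a, g$b, n_perm = 300, seed = 7)
  expect_lt(lp$p_value, 0.05)
  lp2 <- latency_permutation(g$a, g$b, n_perm = 300, seed = 7)
  expect_identical(lp$p_value, lp2$p_value)

  # group B a copy of group A: zero observed difference, p near 1
  lp_null <- latency_permutation(g$a, g$a, n_perm = 200, seed = 8)
  expect_gt(lp_null$p_value, 0.9)
})
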