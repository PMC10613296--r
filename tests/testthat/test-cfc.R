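# Band envelopes and delta-band amplitude-amplitude coupling.

test_that("band envelope recovers constant and modulated amplitudes", {
  fs <- 250; ns <- 500
  t <- (0:(ns - 1)) / fs
  # constant-amplitude alpha oscillation: envelope flat away from edges
  x <- array(0, dim = c(3, ns, 1))
  x[1, , 1] <- 2 * sin(2 * pi * 10 * t)
  ep <- epochs_from_array(x, fs = fs)
  env <- band_envelope(ep, "alpha", channel = "Pz")
  keep <- attr(env, "edge_keep")
  ev <- env[keep, 1]
  expect_lt(sd(ev) / mean(ev), 0.05)
  expect_lt(abs(mean(ev) - 2), 0.1)

  # amplitude-modulated carrier: envelope tracks A(t) within 5% RMS
  A <- 1 + 0.5 * sin(2 * pi * 0.8 * t)
  x[1, , 1] <- A * sin(2 * pi * 10 * t)
  ep2 <- epochs_from_array(x, fs = fs)
  env2 <- band_envelope(ep2, c(6, 15), channel = "Pz")[keep, 1]
  rel_rms <- sqrt(mean((env2 - A[keep])^2)) / sqrt(mean(A[keep]^2))
  expect_lt(rel_rms, 0.05)

  expect_error(band_envelope(ep, c(100, 130), channel = "Pz"), "Nyquist")
})

test_that("narrowband Gaussian envelopes follow Rayleigh statistics", {
  fs <- 250; ns <- 2000
  withr::with_seed(31, {
    x <- array(rnorm(3 * ns), dim = c(3, ns, 1))
  })
  ep <- epochs_from_array(x, fs = fs)
  env <- band_envelope(ep, "delta", channel = "Pz")
  keep <- attr(env, "edge_keep")
  bp <- ambiguitynet:::fft_bandpass(x[1, , 1], fs, 1, 4)
  # Rayleigh envelope mean = sigma * sqrt(pi / 2)
  ratio <- mean(env[keep, 1]) / (sd(bp[keep]) * sqrt(pi / 2))
  expect_lt(abs(ratio - 1), 0.1)
})

test_that("a constructed envelope dependence yields a positive index", {
  fs <- 250; ns <- 500
  withr::with_seed(37, {
    n_tr <- 12
    dat <- array(rnorm(3 * ns * n_tr, sd = 0.1), dim = c(3, ns, n_tr))
    for (tr in seq_len(n_tr)) {
      d <- ambiguitynet:::bandlimited_noise(ns, fs, 1, 4)
      ed <- Mod(ambiguitynet:::analytic_signal(d))
      carrier <- sin(2 * pi * 10 * (0:(ns - 1)) / fs)
      dat[1, , tr] <- d + ed * carrier   # alpha amplitude = delta envelope
    }
    ep <- epochs_from_array(dat, fs = fs,
                            condition = rep("high", n_tr))
  })
  r <- amplitude_cfc(ep, low = "delta", high = "alpha", channel = "Pz",
                     n_perm = 199, seed = 2)
  expect_gt(r$modulation_index, 0.5)
  expect_lt(r$p_value, 0.05)
  expect_lte(abs(r$modulation_index), 1)
})

test_that("modulation index is invariant to linear rescaling", {
  ep <- gen_eeg_epochs(eeg_truth(n_channels = 3,
                                 channel_names = c("Pz", "Cz", "FCz"),
                                 cfc_gain = 0.5,
                                 n_trials_per_condition = 6, seed = 41))
  r1 <- amplitude_cfc(ep, method = "parametric")
  ep$data <- ep$data * 40 + 0
  r2 <- amplitude_cfc(ep, method = "parametric")
  expect_equal(r1$modulation_index, r2$modulation_index,
               tolerance = 1e-10)
})

test_that("recovered index grows with the injected coupling gain", {
  gains <- c(0, 0.2, 0.4, 0.6, 0.8)
  mi <- vapply(gains, function(g) {
    mean(vapply(1:3, function(s) {
      ep <- gen_eeg_epochs(eeg_truth(
        n_channels = 3, channel_names = c("Pz", "Cz", "FCz"),
        cfc_gain = g, n_trials_per_condition = 15, seed = 100 + s))
      amplitude_cfc(ep, method = "parametric")$modulation_index
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mi) > 0))
})

test_that("coupling is specific to the band that was driven", {
  # delta drives alpha only; theta and beta indices stay null
  ep <- gen_eeg_epochs(eeg_truth(n_channels = 3,
                                 channel_names = c("Pz", "Cz", "FCz"),
                                 cfc_gain = 0.7,
                                 n_trials_per_condition = 20, seed = 43))
  r_alpha <- amplitude_cfc(ep, high = "alpha", n_perm = 199, seed = 3)
  r_theta <- amplitude_cfc(ep, high = "theta", n_perm = 199, seed = 3)
  r_beta <- amplitude_cfc(ep, high = "beta", n_perm = 199, seed = 3)
  expect_lt(r_alpha$p_value, 0.05)
  expect_gt(r_theta$p_value, 0.05)
  expect_gt(r_beta$p_value, 0.05)
  expect_gt(r_alpha$modulation_index,
            max(abs(r_theta$modulation_index),
                abs(r_beta$modulation_index)))
})

test_that("degenerate envelopes are rejected", {
  dat <- array(0, dim = c(3, 500, 4))
  ep <- epochs_from_array(dat)
  expect_error(amplitude_cfc(ep), "constant delta envelope")
})

test_that("condition contrast has power for a graded coupling effect", {
  set.seed(47)
  hits <- vapply(1:100, function(i) {
    tab <- cbind(rnorm(22, 0.1, 0.05), rnorm(22, 0.2, 0.05),
                 rnorm(22, 0.3, 0.05))
    cfc_condition_contrast(tab)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  same <- matrix(rep(rnorm(5), 3), 5, 3)
  expect_equal(cfc_condition_contrast(same)$F, 0)
})
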