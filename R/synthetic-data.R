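# Synthetic-data generators with known ground truth for every analysis
# stage: logistic choice behavior with RT inflation under ambiguity,
# condition-dependent Poisson spiking with a rate-step onset, oscillatory
# EEG epochs with controlled pairwise coherence and delta->alpha amplitude
# coupling, and multichannel series from a known stable MVAR process.

# --------------------------------------------------------------------------
# Behavior
# --------------------------------------------------------------------------

#' Ground truth for a synthetic behavioral session
#'
#' Parameters of the generative model inverted by [fit_psychometric()]:
#' choices at morph level x are Bernoulli with
#' `P(fear) = p_inf / (1 + exp(-alpha_slope * (x - x_half)))`, and reaction
#' times are `rt_base` plus an ambiguity-dependent gain (0 at anchor, half
#' at intermediate, full at high ambiguity) plus zero-mean Gaussian noise
#' floored at 1 ms.
#'
#' @param p_inf Upper asymptote of the psychometric curve, in (0, 1].
#' @param x_half Inflection point (threshold), percent-fear units.
#' @param alpha_slope Logistic steepness (sensitivity), per percent; > 0.
#' @param rt_base Baseline mean reaction time, seconds; > 0.
#' @param rt_ambiguity_gain Extra mean RT at high ambiguity, seconds; >= 0.
#'   Interpolated linearly at intermediate ambiguity.
#' @param rt_noise_sd SD of Gaussian RT noise, seconds; >= 0.
#' @param confidence_model Named numeric vector mapping ambiguity level
#'   (`anchor`, `intermediate`, `high`) to mean confidence on the 1-3 scale.
#' @param n_trials_per_level Trials per morph level.
#' @param seed Integer seed; identical seeds give byte-identical sessions.
#' @return An object of class `behavior_truth`.
#' @export
behavior_truth <- function(p_inf = 1, x_half = 50, alpha_slope = 0.2,
                           rt_base = 1.0, rt_ambiguity_gain = 0.15,
                           rt_noise_sd = 0.15,
                           confidence_model = c(anchor = 2.8,
                                                intermediate = 2.2,
                                                high = 1.7),
                           n_trials_per_level = 40, seed = 1) {
  check_scalar(p_inf, "p_inf", lower = 0, upper = 1, strict_lower = TRUE)
  check_scalar(x_half, "x_half")
  check_scalar(alpha_slope, "alpha_slope", lower = 0, strict_lower = TRUE)
  check_scalar(rt_base, "rt_base", lower = 0, strict_lower = TRUE)
  check_scalar(rt_ambiguity_gain, "rt_ambiguity_gain", lower = 0)
  check_scalar(rt_noise_sd, "rt_noise_sd", lower = 0)
  if (!all(ambiguity_levels() %in% names(confidence_model))) {
    stop_invalid("confidence_model must name all of ",
                 paste(ambiguity_levels(), collapse = ", "))
  }
  structure(list(p_inf = p_inf, x_half = x_half, alpha_slope = alpha_slope,
                 rt_base = rt_base, rt_ambiguity_gain = rt_ambiguity_gain,
                 rt_noise_sd = rt_noise_sd,
                 confidence_model = confidence_model,
                 n_trials_per_level = check_count(n_trials_per_level,
                                                  "n_trials_per_level"),
                 seed = check_count(seed, "seed", min = 0)),
            class = "behavior_truth")
}

# Ambiguity weight used for the RT gain: anchor 0, intermediate 1/2, high 1.
ambiguity_weight <- function(level) {
  c(anchor = 0, intermediate = 0.5, high = 1)[level]
}

#' Generate a synthetic behavioral session
#'
#' Simulates fear/happy choices and reaction times at the seven morph
#' levels under the logistic-choice model in `truth`. Deterministic given
#' the seed stored in `truth`.
#'
#' @param truth A [behavior_truth()] object.
#' @param participant_id Participant label for the output table.
#' @param group_label Optional cohort label (e.g. "control").
#' @return A data.frame (behavioral session) with columns `participant_id`,
#'   `trial_index`, `morph_pct`, `choice` ("fear"/"happy"), `rt_s`,
#'   `confidence` (1-3), `confidence_rt_s`, `group_label`.
#' @export
gen_behavior <- function(truth, participant_id = "sim01",
                         group_label = NA_character_) {
  if (!inherits(truth, "behavior_truth")) {
    stop_invalid("truth must be a behavior_truth object")
  }
  grid <- morph_grid()
  n <- truth$n_trials_per_level
  morph <- rep(grid, each = n)
  p_fear <- truth$p_inf /
    (1 + exp(-truth$alpha_slope * (morph - truth$x_half)))
  level <- group_ambiguity(morph)
  w <- ambiguity_weight(level)
  conf_mean <- truth$confidence_model[level]
  with_seed(truth$seed, {
    choice <- ifelse(stats::runif(length(morph)) < p_fear, "fear", "happy")
    rt <- truth$rt_base + truth$rt_ambiguity_gain * w +
      stats::rnorm(length(morph), 0, truth$rt_noise_sd)
    rt <- pmax(rt, 1e-3)
    confidence <- pmin(3L, pmax(1L, as.integer(round(
      stats::rnorm(length(morph), conf_mean, 0.5)))))
    conf_rt <- pmax(0.4 + 0.1 * w +
                      stats::rnorm(length(morph), 0, 0.1), 1e-3)
    data.frame(participant_id = participant_id,
               trial_index = seq_along(morph),
               morph_pct = morph,
               choice = choice,
               rt_s = rt,
               confidence = confidence,
               confidence_rt_s = conf_rt,
               group_label = group_label,
               stringsAsFactors = FALSE)
  })
}

# --------------------------------------------------------------------------
# Spikes
# --------------------------------------------------------------------------

#' Ground truth for a synthetic spiking population
#'
#' Each neuron fires as an inhomogeneous Poisson process: homogeneous at
#' `baseline_rate` before `onset_latency`, then stepping to
#' `baseline_rate + modulation_per_level * (level_code - reference_code)`
#' where level codes are anchor = 1, intermediate = 2, high = 3. The
#' reference level fires at baseline even after onset. A negative
#' `modulation_per_level` with `reference_level = "high"` models a neuron
#' preferring unambiguous faces (rate steps up for anchors); a positive
#' modulation with the default `reference_level = "anchor"` prefers
#' ambiguous faces. The rate step (rather than a ramp) makes the latency
#' ground truth unambiguous for recovery tests.
#'
#' @param n_neurons Number of neurons to simulate.
#' @param region_label Region tag, e.g. "amygdala" or "dmPFC".
#' @param baseline_rate Pre-onset firing rate, Hz; >= 0.
#' @param modulation_per_level Signed rate change per ambiguity step, Hz.
#' @param reference_level Ambiguity level whose post-onset rate stays at
#'   baseline ("anchor" by default).
#' @param onset_latency Response onset after stimulus onset, seconds.
#' @param trial_duration Trial length, seconds.
#' @param n_trials_per_level Trials per ambiguity level.
#' @param seed Integer seed.
#' @return An object of class `spike_truth`.
#' @export
spike_truth <- function(n_neurons = 1, region_label = "amygdala",
                        baseline_rate = 5, modulation_per_level = 2,
                        reference_level = "anchor",
                        onset_latency = 0.3, trial_duration = 2,
                        n_trials_per_level = 30, seed = 1) {
  check_scalar(baseline_rate, "baseline_rate", lower = 0)
  check_scalar(onset_latency, "onset_latency", lower = 0)
  check_scalar(trial_duration, "trial_duration", lower = 0,
               strict_lower = TRUE)
  if (onset_latency >= trial_duration) {
    stop_invalid("onset_latency must be < trial_duration")
  }
  check_scalar(modulation_per_level, "modulation_per_level")
  if (!reference_level %in% ambiguity_levels()) {
    stop_invalid("reference_level must be one of ",
                 paste(ambiguity_levels(), collapse = ", "))
  }
  ref_code <- match(reference_level, ambiguity_levels())
  min_rate <- baseline_rate +
    min(modulation_per_level * ((1:3) - ref_code))
  if (min_rate < 0) {
    stop_invalid("negative effective firing rate at some ambiguity level ",
                 "(baseline ", baseline_rate, " Hz, modulation ",
                 modulation_per_level, " Hz/step)")
  }
  structure(list(n_neurons = check_count(n_neurons, "n_neurons"),
                 region_label = as.character(region_label),
                 baseline_rate = baseline_rate,
                 modulation_per_level = modulation_per_level,
                 reference_level = reference_level,
                 onset_latency = onset_latency,
                 trial_duration = trial_duration,
                 n_trials_per_level = check_count(n_trials_per_level,
                                                  "n_trials_per_level"),
                 seed = check_count(seed, "seed", min = 0)),
            class = "spike_truth")
}

#' Generate a trial-aligned synthetic spike dataset
#'
#' @param truth A [spike_truth()] object.
#' @param levels Optional character vector giving the ambiguity level of
#'   each trial (the condition schedule). Defaults to
#'   `n_trials_per_level` trials of each of anchor/intermediate/high.
#' @return An object of class `spike_dataset`: a list with `spikes`
#'   (data.frame: `neuron_id`, `region`, `trial_id`, `spike_time_s`,
#'   `ambiguity_level`), `trials` (one row per neuron x trial, so empty
#'   trials are represented), and `trial_duration` (seconds).
#' @export
gen_spikes <- function(truth, levels = NULL) {
  if (!inherits(truth, "spike_truth")) {
    stop_invalid("truth must be a spike_truth object")
  }
  if (is.null(levels)) {
    levels <- rep(ambiguity_levels(), each = truth$n_trials_per_level)
  }
  if (!all(levels %in% ambiguity_levels())) {
    stop_invalid("levels must be among: ",
                 paste(ambiguity_levels(), collapse = ", "))
  }
  if (!all(ambiguity_levels() %in% levels)) {
    stop_invalid("condition schedule must cover all 3 ambiguity levels")
  }
  codes <- match(levels, ambiguity_levels())  # anchor 1 .. high 3
  ref_code <- match(truth$reference_level, ambiguity_levels())
  post_rates <- truth$baseline_rate +
    truth$modulation_per_level * (codes - ref_code)
  n_tr <- length(levels)
  with_seed(truth$seed, {
    nids <- sprintf("%s_n%03d", truth$region_label,
                    seq_len(truth$n_neurons))
    acc <- vector("list", truth$n_neurons)
    for (ni in seq_len(truth$n_neurons)) {
      # Poisson segment counts for all trials at once, then uniform times
      # within each segment (sorted later by the container constructor)
      k_pre <- stats::rpois(n_tr, truth$baseline_rate *
                              truth$onset_latency)
      k_post <- stats::rpois(n_tr, post_rates *
                               (truth$trial_duration -
                                  truth$onset_latency))
      t_pre <- stats::runif(sum(k_pre), 0, truth$onset_latency)
      t_post <- stats::runif(sum(k_post), truth$onset_latency,
                             truth$trial_duration)
      tr_pre <- rep.int(seq_len(n_tr), k_pre)
      tr_post <- rep.int(seq_len(n_tr), k_post)
      acc[[ni]] <- data.frame(
        neuron_id = nids[ni], region = truth$region_label,
        trial_id = c(tr_pre, tr_post),
        spike_time_s = c(t_pre, t_post),
        ambiguity_level = levels[c(tr_pre, tr_post)],
        stringsAsFactors = FALSE)
    }
    spikes <- do.call(rbind, acc)
    trials <- expand.grid(trial_id = seq_len(n_tr),
                          neuron_id = sprintf("%s_n%03d", truth$region_label,
                                              seq_len(truth$n_neurons)),
                          stringsAsFactors = FALSE)
    trials$region <- truth$region_label
    trials$ambiguity_level <- levels[trials$trial_id]
    trials <- trials[, c("neuron_id", "region", "trial_id",
                         "ambiguity_level")]
    spike_dataset(spikes, trials, truth$trial_duration)
  })
}

#' Construct a spike dataset container
#'
#' @param spikes data.frame with columns `neuron_id`, `region`, `trial_id`,
#'   `spike_time_s`, `ambiguity_level`. Spike times are seconds relative to
#'   stimulus onset and are sorted within each trial.
#' @param trials data.frame with one row per neuron x trial (`neuron_id`,
#'   `region`, `trial_id`, `ambiguity_level`); needed so that trials with
#'   zero spikes still count toward firing rates.
#' @param trial_duration Trial length in seconds.
#' @return Object of class `spike_dataset`.
#' @export
spike_dataset <- function(spikes, trials, trial_duration) {
  need <- c("neuron_id", "region", "trial_id", "spike_time_s",
            "ambiguity_level")
  if (!all(need %in% names(spikes))) {
    stop_invalid("spikes must have columns: ", paste(need, collapse = ", "))
  }
  check_scalar(trial_duration, "trial_duration", lower = 0,
               strict_lower = TRUE)
  o <- order(spikes$neuron_id, spikes$trial_id, spikes$spike_time_s)
  spikes <- spikes[o, , drop = FALSE]
  rownames(spikes) <- NULL
  structure(list(spikes = spikes, trials = trials,
                 trial_duration = trial_duration),
            class = "spike_dataset")
}

# --------------------------------------------------------------------------
# EEG epochs
# --------------------------------------------------------------------------

#' Ground truth for synthetic EEG epochs
#'
#' Each channel is a sum of unit-variance band-limited stochastic
#' components (delta/theta/alpha/beta). Pairwise coherence is controlled by
#' shared-signal mixing: for a target coherence T in a band, the two
#' channels' band components are `a*s + b*u_ch` with `a = T^(1/4)`,
#' `b = sqrt(1 - sqrt(T))`, a shared `s`, and channel-private `u_ch`, which
#' gives in-band magnitude-squared coherence exactly T. Delta-to-alpha
#' amplitude coupling at Pz is injected by modulating the alpha component's
#' instantaneous amplitude with the (normalized) delta envelope, scaled by
#' `cfc_gain`.
#'
#' @param n_channels Number of channels.
#' @param channel_names Channel labels; must include "Pz", "Cz", "FCz".
#' @param fs Sampling rate, Hz (must exceed twice the top band edge).
#' @param epoch_window Epoch limits in seconds relative to stimulus onset.
#' @param coherence_targets data.frame with columns `chan_a`, `chan_b`,
#'   `band` (name or "lo-hi"), `condition` (an ambiguity level or NA for
#'   all), `coherence` in \[0, 1\].
#' @param cfc_gain Delta-envelope -> alpha-amplitude coupling coefficient;
#'   scalar or named per-condition vector.
#' @param n_trials_per_condition Trials per ambiguity level.
#' @param seed Integer seed.
#' @return An object of class `eeg_truth`.
#' @export
eeg_truth <- function(n_channels = 5,
                      channel_names = c("Pz", "Cz", "FCz", "Fz", "Oz"),
                      fs = 250, epoch_window = c(-0.5, 1.5),
                      coherence_targets = NULL,
                      cfc_gain = 0,
                      n_trials_per_condition = 20, seed = 1) {
  check_count(n_channels, "n_channels")
  if (length(channel_names) != n_channels) {
    stop_invalid("channel_names must have length n_channels")
  }
  if (!all(c("Pz", "Cz", "FCz") %in% channel_names)) {
    stop_invalid("channel_names must include Pz, Cz and FCz")
  }
  check_scalar(fs, "fs", lower = 0, strict_lower = TRUE)
  top <- max(eeg_bands()$hi)
  if (fs < 2 * top) {
    stop_invalid("fs must be >= twice the highest band edge (", 2 * top,
                 " Hz)")
  }
  if (!is.null(coherence_targets)) {
    need <- c("chan_a", "chan_b", "band", "coherence")
    if (!all(need %in% names(coherence_targets))) {
      stop_invalid("coherence_targets needs columns: ",
                   paste(need, collapse = ", "))
    }
    if (any(coherence_targets$coherence < 0 |
            coherence_targets$coherence > 1)) {
      stop_invalid("coherence targets must lie in [0, 1]")
    }
    if (is.null(coherence_targets$condition)) {
      coherence_targets$condition <- NA_character_
    }
    bad <- setdiff(c(coherence_targets$chan_a, coherence_targets$chan_b),
                   channel_names)
    if (length(bad)) stop_invalid("unknown channels in targets: ",
                                  paste(bad, collapse = ", "))
  }
  if (is.null(names(cfc_gain))) {
    cfc_gain <- stats::setNames(rep(cfc_gain[1], 3), ambiguity_levels())
  }
  structure(list(n_channels = as.integer(n_channels),
                 channel_names = channel_names, fs = fs,
                 epoch_window = epoch_window,
                 coherence_targets = coherence_targets,
                 cfc_gain = cfc_gain,
                 n_trials_per_condition =
                   check_count(n_trials_per_condition,
                               "n_trials_per_condition"),
                 seed = check_count(seed, "seed", min = 0)),
            class = "eeg_truth")
}

#' Construct an EEG epochs container
#'
#' @param data Numeric array, channels x samples x trials.
#' @param fs Sampling rate, Hz.
#' @param t0 Epoch start relative to stimulus onset, seconds.
#' @param channel_names Channel labels, length = dim(data)\[1\].
#' @param condition Per-trial ambiguity level, length = dim(data)\[3\].
#' @param participant_id Participant label.
#' @return Object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, fs, t0 = -0.5, channel_names,
                       condition, participant_id = "sim01") {
  if (length(dim(data)) != 3) {
    stop_invalid("data must be a channels x samples x trials array")
  }
  if (dim(data)[1] != length(channel_names)) {
    stop_invalid("channel_names length must match dim(data)[1]")
  }
  if (dim(data)[3] != length(condition)) {
    stop_invalid("condition length must match dim(data)[3]")
  }
  dimnames(data) <- list(channel_names, NULL, NULL)
  structure(list(data = data, fs = fs, t0 = t0,
                 channel_names = channel_names,
                 condition = as.character(condition),
                 participant_id = participant_id),
            class = "eeg_epochs")
}

#' Generate synthetic oscillatory EEG epochs
#'
#' See [eeg_truth()] for the generative model. Deterministic given the seed.
#'
#' @param truth An [eeg_truth()] object.
#' @param participant_id Participant label.
#' @return An [eeg_epochs()] object (channels x samples x trials).
#' @export
gen_eeg_epochs <- function(truth, participant_id = "sim01") {
  if (!inherits(truth, "eeg_truth")) {
    stop_invalid("truth must be an eeg_truth object")
  }
  fs <- truth$fs
  n_samp <- round((truth$epoch_window[2] - truth$epoch_window[1]) * fs)
  bands <- eeg_bands()
  conds <- rep(ambiguity_levels(), each = truth$n_trials_per_condition)
  n_tr <- length(conds)
  nc <- truth$n_channels
  tg <- truth$coherence_targets
  with_seed(truth$seed, {
    dat <- array(0, dim = c(nc, n_samp, n_tr))
    for (tr in seq_len(n_tr)) {
      cond <- conds[tr]
      # band components per channel
      comp <- array(0, dim = c(nc, n_samp, nrow(bands)))
      for (bi in seq_len(nrow(bands))) {
        lo <- bands$lo[bi]; hi <- bands$hi[bi]
        # default: private unit-variance band noise per channel
        for (ch in seq_len(nc)) {
          comp[ch, , bi] <- bandlimited_noise(n_samp, fs, lo, hi)
        }
        if (!is.null(tg)) {
          rows <- which((is.na(tg$condition) | tg$condition == cond) &
                          vapply(tg$band, function(b)
                            isTRUE(all.equal(band_edges(b), c(lo, hi))),
                            logical(1)))
          for (r in rows) {
            ia <- match(tg$chan_a[r], truth$channel_names)
            ib <- match(tg$chan_b[r], truth$channel_names)
            Tc <- tg$coherence[r]
            a <- Tc^(1 / 4)
            b <- sqrt(1 - sqrt(Tc))
            s <- bandlimited_noise(n_samp, fs, lo, hi)
            comp[ia, , bi] <- a * s + b * comp[ia, , bi]
            comp[ib, , bi] <- a * s + b * comp[ib, , bi]
          }
        }
      }
      # delta -> alpha amplitude coupling at Pz
      g <- truth$cfc_gain[[cond]]
      if (is.finite(g) && g != 0) {
        pz <- match("Pz", truth$channel_names)
        delta_i <- match("delta", bands$name)
        alpha_i <- match("alpha", bands$name)
        env_d <- Mod(analytic_signal(comp[pz, , delta_i]))
        modu <- 1 + g * (env_d / mean(env_d) - 1)
        modu <- pmax(modu, 0.05)
        comp[pz, , alpha_i] <- comp[pz, , alpha_i] * modu
      }
      dat[, , tr] <- apply(comp, c(1, 2), sum)
    }
    eeg_epochs(dat, fs = fs, t0 = truth$epoch_window[1],
               channel_names = truth$channel_names,
               condition = conds, participant_id = participant_id)
  })
}

# --------------------------------------------------------------------------
# MVAR source series
# --------------------------------------------------------------------------

#' Ground truth for a synthetic MVAR source process
#'
#' `x_t = sum_k A_k x_(t-k) + e_t`, with `e_t ~ N(0, noise_cov)`. The
#' process must be stable: the companion-matrix spectral radius must be
#' below 1.
#'
#' @param coeff_matrices List of p square coefficient matrices A_1..A_p.
#' @param noise_cov Positive-definite innovation covariance.
#' @param n_samples Samples per trial (after burn-in).
#' @param n_trials Number of independent trials (realizations).
#' @param fs Nominal sampling rate, Hz (metadata for the DTF stage).
#' @param source_names Optional source labels.
#' @param seed Integer seed.
#' @return An object of class `mvar_truth`.
#' @export
mvar_truth <- function(coeff_matrices, noise_cov = NULL, n_samples = 500,
                       n_trials = 1, fs = 250, source_names = NULL,
                       seed = 1) {
  if (!is.list(coeff_matrices) || !length(coeff_matrices)) {
    stop_invalid("coeff_matrices must be a non-empty list of matrices")
  }
  n <- nrow(coeff_matrices[[1]])
  for (A in coeff_matrices) {
    if (!is.matrix(A) || any(dim(A) != n)) {
      stop_invalid("all coefficient matrices must be square of equal size")
    }
  }
  if (is.null(noise_cov)) noise_cov <- diag(n)
  if (!isTRUE(all.equal(noise_cov, t(noise_cov))) ||
      any(eigen(noise_cov, symmetric = TRUE,
                only.values = TRUE)$values <= 0)) {
    stop_invalid("noise_cov must be symmetric positive-definite")
  }
  rho <- mvar_spectral_radius(coeff_matrices)
  if (rho >= 1) {
    stop_invalid("unstable MVAR process (companion spectral radius = ",
                 format(rho, digits = 4), " >= 1)")
  }
  if (is.null(source_names)) source_names <- sprintf("S%d", seq_len(n))
  structure(list(n_sources = n, order = length(coeff_matrices),
                 coeff_matrices = coeff_matrices, noise_cov = noise_cov,
                 n_samples = check_count(n_samples, "n_samples"),
                 n_trials = check_count(n_trials, "n_trials"),
                 fs = fs, source_names = source_names,
                 seed = check_count(seed, "seed", min = 0)),
            class = "mvar_truth")
}

# Spectral radius of the MVAR companion matrix.
mvar_spectral_radius <- function(A_list) {
  n <- nrow(A_list[[1]]); p <- length(A_list)
  comp <- matrix(0, n * p, n * p)
  comp[1:n, ] <- do.call(cbind, A_list)
  if (p > 1) {
    comp[(n + 1):(n * p), 1:(n * (p - 1))] <- diag(n * (p - 1))
  }
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Construct a source time-series container
#'
#' @param data Sources x samples matrix, or sources x samples x trials
#'   array.
#' @param fs Sampling rate, Hz.
#' @param source_names Source labels.
#' @param window Optional analysis window (seconds relative to onset).
#' @return Object of class `source_series`.
#' @export
source_series <- function(data, fs, source_names = NULL, window = NULL) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1))
  if (length(dim(data)) != 3) {
    stop_invalid("data must be sources x samples (x trials)")
  }
  if (dim(data)[1] < 1) stop_invalid("need at least one source")
  if (any(!is.finite(data))) stop_invalid("source series contains missing samples")
  if (is.null(source_names)) {
    source_names <- sprintf("S%d", seq_len(dim(data)[1]))
  }
  structure(list(data = data, fs = fs, source_names = source_names,
                 window = window),
            class = "source_series")
}

#' Simulate a stable MVAR process
#'
#' Burn-in of `max(10 * order, 100)` samples is generated and discarded for
#' every trial so the output is (approximately) stationary.
#'
#' @param truth An [mvar_truth()] object.
#' @return A [source_series()] object, sources x samples x trials.
#' @export
gen_mvar_series <- function(truth) {
  if (!inherits(truth, "mvar_truth")) {
    stop_invalid("truth must be an mvar_truth object")
  }
  n <- truth$n_sources; p <- truth$order
  burn <- max(10 * p, 100)
  total <- truth$n_samples + burn
  L <- chol(truth$noise_cov)
  with_seed(truth$seed, {
    dat <- array(0, dim = c(n, truth$n_samples, truth$n_trials))
    for (tr in seq_len(truth$n_trials)) {
      e <- matrix(stats::rnorm(total * n), total, n) %*% L
      x <- matrix(0, total, n)
      for (t in seq_len(total)) {
        acc <- e[t, ]
        for (k in seq_len(min(p, t - 1))) {
          acc <- acc + truth$coeff_matrices[[k]] %*% x[t - k, ]
        }
        x[t, ] <- acc
      }
      dat[, , tr] <- t(x[(burn + 1):total, , drop = FALSE])
    }
    source_series(dat, fs = truth$fs, source_names = truth$source_names)
  })
}
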