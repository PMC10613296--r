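# Cross-frequency amplitude-amplitude coupling: the delta-band amplitude
# envelope as a predictor of the theta/alpha/beta envelopes over the 2-s
# epoch, per participant and condition, with a trial-shuffling permutation
# for inference and repeated-measures condition contrasts.

#' Band-limited amplitude envelope of epoched data
#'
#' Zero-phase band-pass (frequency-domain masking, so there is no filter
#' delay) followed by the analytic-signal amplitude. The first and last
#' 10 percent of samples of each epoch are flagged as edge samples
#' (filter/Hilbert transients) and should be excluded from downstream
#' statistics; the flag is returned as the `edge_keep` attribute.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param band Band name ("delta", "theta", "alpha", "beta") or `c(lo,
#'   hi)` Hz.
#' @param channel Optional channel name; if given, a samples x trials
#'   matrix for that channel is returned, else a channels x samples x
#'   trials array.
#' @param edge_frac Fraction of samples flagged at each edge (default
#'   0.1).
#' @return Envelope array/matrix with attribute `edge_keep`, a logical
#'   vector over samples (TRUE = usable).
#' @export
band_envelope <- function(epochs, band, channel = NULL, edge_frac = 0.1) {
  if (!inherits(epochs, "eeg_epochs")) {
    stop_invalid("epochs must be an eeg_epochs object")
  }
  be <- band_edges(band)
  if (be[2] >= epochs$fs / 2) {
    stop_invalid("band upper edge at/above Nyquist frequency")
  }
  chans <- if (is.null(channel)) epochs$channel_names else channel
  miss <- setdiff(chans, epochs$channel_names)
  if (length(miss)) stop_invalid("unknown channel(s): ",
                                 paste(miss, collapse = ", "))
  ns <- dim(epochs$data)[2]
  n_tr <- dim(epochs$data)[3]
  edge <- floor(edge_frac * ns)
  keep <- rep(TRUE, ns)
  if (edge > 0) keep[c(seq_len(edge), (ns - edge + 1):ns)] <- FALSE
  env1 <- function(x) Mod(analytic_signal(fft_bandpass(x, epochs$fs,
                                                       be[1], be[2])))
  if (!is.null(channel)) {
    ci <- match(channel, epochs$channel_names)
    out <- vapply(seq_len(n_tr),
                  function(tr) env1(epochs$data[ci, , tr]), numeric(ns))
    attr(out, "edge_keep") <- keep
    return(out)
  }
  out <- array(0, dim = dim(epochs$data),
               dimnames = list(epochs$channel_names, NULL, NULL))
  for (ci in seq_along(epochs$channel_names)) {
    for (tr in seq_len(n_tr)) {
      out[ci, , tr] <- env1(epochs$data[ci, , tr])
    }
  }
  attr(out, "edge_keep") <- keep
  out
}

#' Amplitude-amplitude cross-frequency coupling index
#'
#' Regresses the standardized high-band amplitude envelope on the
#' standardized delta (low-band) envelope, with samples pooled across
#' trials within the participant and edge samples excluded. The
#' modulation index is the standardized slope (a correlation, so bounded
#' by 1 in absolute value). Because narrowband envelopes are strongly
#' autocorrelated in time, the default p-value comes from a
#' trial-shuffling permutation (the high-band envelope's trials are
#' re-paired with the low-band envelope's trials), which preserves the
#' within-trial autocorrelation under the null; `method = "parametric"`
#' gives the naive pooled-OLS p instead.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param low Low band (default "delta").
#' @param high High band: "theta", "alpha" or "beta".
#' @param channel Channel to analyze (default "Pz").
#' @param condition Optional ambiguity level restriction.
#' @param method "permutation" (default) or "parametric".
#' @param n_perm Shuffles for the permutation p (default 200).
#' @param seed Seed for the permutation.
#' @return Object of class `cfc_result`: list with `pair`, `channel`,
#'   `condition`, `modulation_index`, `p_value`, `n_trials`, `method`.
#' @export
amplitude_cfc <- function(epochs, low = "delta", high = "alpha",
                          channel = "Pz", condition = NULL,
                          method = c("permutation", "parametric"),
                          n_perm = 200, seed = 1) {
  method <- match.arg(method)
  trials <- seq_along(epochs$condition)
  if (!is.null(condition)) trials <- which(epochs$condition == condition)
  if (length(trials) < 2) stop_invalid("need >= 2 trials")
  env_lo <- band_envelope(epochs, low, channel = channel)
  env_hi <- band_envelope(epochs, high, channel = channel)
  keep <- attr(env_lo, "edge_keep")
  lo_m <- env_lo[keep, trials, drop = FALSE]
  hi_m <- env_hi[keep, trials, drop = FALSE]
  if (stats::sd(lo_m) == 0) {
    stop_invalid("constant delta envelope; regressor degenerate")
  }
  if (stats::sd(hi_m) == 0) {
    stop_invalid("constant high-band envelope; response degenerate")
  }
  r_obs <- stats::cor(as.vector(lo_m), as.vector(hi_m))
  n_tr <- length(trials)
  if (method == "parametric") {
    n <- length(lo_m)
    tval <- r_obs * sqrt((n - 2) / (1 - r_obs^2))
    p <- 2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE)
  } else {
    null_r <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        perm <- sample.int(n_tr)
        stats::cor(as.vector(lo_m), as.vector(hi_m[, perm]))
      }, numeric(1))
    })
    p <- (1 + sum(abs(null_r) >= abs(r_obs))) / (n_perm + 1)
  }
  structure(list(pair = c(low = if (is.character(low)) low else "custom",
                          high = if (is.character(high)) high else "custom"),
                 channel = channel, condition = condition,
                 modulation_index = r_obs, p_value = p,
                 n_trials = n_tr, method = method),
            class = "cfc_result")
}

#' Condition contrast of CFC indices across participants
#'
#' One-way repeated-measures ANOVA of per-participant modulation indices
#' across the three ambiguity levels.
#'
#' @param indices Numeric matrix, participants x 3 conditions.
#' @return List with `F`, `df1`, `df2`, `p_value`, `partial_eta2`.
#' @export
cfc_condition_contrast <- function(indices) {
  indices <- as.matrix(indices)
  if (ncol(indices) != 3) {
    stop_invalid("expected a participants x 3-condition table")
  }
  rm_anova(indices)
}

#' Phase-amplitude coupling variant (exploratory)
#'
#' Phase-binned mean amplitude: the low-band instantaneous phase is cut
#' into `n_bins` bins and the normalized entropy deficit of the mean
#' high-band amplitude across bins is returned (0 = amplitude flat over
#' phase, larger = more phase-locked amplitude). Provided for comparison
#' with the amplitude-amplitude index; not part of the primary analysis
#' path.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param low,high Bands as in [amplitude_cfc()].
#' @param channel Channel name.
#' @param condition Optional condition restriction.
#' @param n_bins Number of phase bins (default 18).
#' @return List with `pac_index` and `bin_means`.
#' @export
phase_amplitude_cfc <- function(epochs, low = "delta", high = "alpha",
                                channel = "Pz", condition = NULL,
                                n_bins = 18) {
  trials <- seq_along(epochs$condition)
  if (!is.null(condition)) trials <- which(epochs$condition == condition)
  be <- band_edges(low)
  ci <- match(channel, epochs$channel_names)
  if (is.na(ci)) stop_invalid("unknown channel: ", channel)
  env_hi <- band_envelope(epochs, high, channel = channel)
  keep <- attr(env_hi, "edge_keep")
  ph_all <- amp_all <- NULL
  for (tr in trials) {
    x <- epochs$data[ci, , tr]
    ph <- Arg(analytic_signal(fft_bandpass(x, epochs$fs, be[1], be[2])))
    ph_all <- c(ph_all, ph[keep])
    amp_all <- c(amp_all, env_hi[keep, tr])
  }
  bins <- cut(ph_all, breaks = seq(-pi, pi, length.out = n_bins + 1),
              include.lowest = TRUE)
  bm <- tapply(amp_all, bins, mean)
  bm[is.na(bm)] <- mean(amp_all)
  pmf <- bm / sum(bm)
  h <- -sum(pmf * log(pmf))
  list(pac_index = (log(n_bins) - h) / log(n_bins), bin_means = as.numeric(bm))
}
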