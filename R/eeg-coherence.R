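# Event-related cross-channel coherence: magnitude-squared coherence of
# every channel with a source channel (Pz by default), estimated by
# averaging Hann-tapered per-trial cross/auto spectra (each trial is one
# segment), summarized over the 4-23 Hz band, with repeated-measures
# condition contrasts.

# Select the sample indices of an analysis window (seconds relative to
# stimulus onset) inside an epochs object.
epoch_sample_idx <- function(epochs, window) {
  n <- dim(epochs$data)[2]
  t <- epochs$t0 + (seq_len(n) - 1) / epochs$fs
  idx <- which(t >= window[1] & t < window[2])
  if (length(idx) < 8) stop_invalid("analysis window too short")
  idx
}

#' Coherence of all channels with a source channel
#'
#' Magnitude-squared coherence `|G_xy(f)|^2 / (G_xx(f) G_yy(f))`, with
#' cross- and auto-power spectral densities averaged across trials
#' (each trial = one Hann-tapered segment, mean removed). Values lie in
#' \[0, 1\] at every frequency; the coherence of the source with itself is
#' 1. The band summary is the unweighted mean over FFT bins inside
#' `band`. Note the estimator's well-known positive bias on independent
#' signals, approximately `1/K` for `K` averaged segments.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param source Source channel name (default "Pz").
#' @param band Frequency band `c(lo, hi)` Hz for the band mean (default
#'   4-23 Hz, covering theta through low beta).
#' @param condition Optional ambiguity level; if given, only those trials
#'   enter.
#' @param window Analysis window in seconds relative to stimulus onset
#'   (default 0 to 1.5, the post-stimulus epoch).
#' @return Object of class `coherence_map`: list with `freqs` (Hz),
#'   `coherence` (channels x freqs matrix), `band_mean` (named vector),
#'   `n_segments`, `source`, `band`.
#' @export
coherence_map <- function(epochs, source = "Pz", band = c(4, 23),
                          condition = NULL, window = c(0, 1.5)) {
  if (!inherits(epochs, "eeg_epochs")) {
    stop_invalid("epochs must be an eeg_epochs object")
  }
  if (!source %in% epochs$channel_names) {
    stop_invalid("source channel '", source, "' not present")
  }
  if (band[1] <= 0 || band[2] >= epochs$fs / 2) {
    stop_invalid("band must lie inside (0, fs/2)")
  }
  trials <- seq_along(epochs$condition)
  if (!is.null(condition)) trials <- which(epochs$condition == condition)
  if (length(trials) < 2) {
    stop_invalid("need >= 2 trials (segments); coherence is degenerate at 1 otherwise")
  }
  if (length(trials) < 8) {
    warning("fewer than 8 segments; coherence estimates will be noisy",
            call. = FALSE)
  }
  idx <- epoch_sample_idx(epochs, window)
  ns <- length(idx)
  w <- hann_window(ns)
  si <- match(source, epochs$channel_names)
  nc <- length(epochs$channel_names)
  nf <- floor(ns / 2) + 1
  freqs <- (seq_len(nf) - 1) * epochs$fs / ns
  gxx <- matrix(0, nc, nf)           # auto-spectra per channel
  gxy <- matrix(0i, nc, nf)          # cross-spectra source x channel
  for (tr in trials) {
    seg <- epochs$data[, idx, tr, drop = FALSE][, , 1]
    seg <- seg - rowMeans(seg)
    segw <- sweep(seg, 2, w, `*`)
    X <- t(apply(segw, 1, stats::fft))[, seq_len(nf), drop = FALSE]
    gxx <- gxx + Mod(X)^2
    gxy <- gxy + X[rep(si, nc), , drop = FALSE] * Conj(X)
  }
  coh <- Mod(gxy)^2 / (gxx[rep(si, nc), , drop = FALSE] * gxx)
  coh[!is.finite(coh)] <- 0
  coh[si, ] <- 1
  rownames(coh) <- epochs$channel_names
  in_band <- freqs >= band[1] & freqs <= band[2]
  band_mean <- rowMeans(coh[, in_band, drop = FALSE])
  structure(list(freqs = freqs, coherence = coh, band_mean = band_mean,
                 n_segments = length(trials), source = source,
                 band = band),
            class = "coherence_map")
}

#' Condition contrast of band coherence across participants
#'
#' One-way repeated-measures ANOVA of per-participant band-mean coherence
#' across the three ambiguity levels.
#'
#' @param band_means Numeric matrix, participants x conditions (3
#'   columns: anchor, intermediate, high). No missing cells.
#' @return List with `F`, `df1`, `df2`, `p_value`, `partial_eta2`.
#' @export
coherence_condition_contrast <- function(band_means) {
  band_means <- as.matrix(band_means)
  if (ncol(band_means) != 3) {
    stop_invalid("expected a participants x 3-condition table")
  }
  rm_anova(band_means)
}
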