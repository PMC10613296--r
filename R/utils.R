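# Shared helpers: conventions, seeded RNG, spectral primitives, RM-ANOVA.
#
# Time convention throughout the package: seconds, relative to stimulus
# onset; bins are half-open [t, t + dt); sample indexing is 0-based in time
# (sample k sits at t0 + k/fs).

# Morph grid and ambiguity grouping used by the face-morph task ------------

#' Morph levels used by the fear-happy judgment task
#'
#' The task presents faces morphed between happy (0% fear) and fearful
#' (100% fear) at seven fixed levels. 0 and 100 are unambiguous anchors,
#' 30/70 are intermediate, and 40-60 are highly ambiguous.
#'
#' @return Integer vector of the seven morph levels (percent fear).
#' @export
morph_grid <- function() c(0L, 30L, 40L, 50L, 60L, 70L, 100L)

#' Ambiguity level labels, in increasing order of ambiguity
#' @return `c("anchor", "intermediate", "high")`
#' @export
ambiguity_levels <- function() c("anchor", "intermediate", "high")

#' Canonical EEG frequency bands
#'
#' Band edges used by both the synthetic generator and the coupling
#' analyses: delta 1-4, theta 4-8, alpha 8-13, beta 13-30 Hz. Bands share
#' edges but do not overlap.
#'
#' @return A data.frame with columns `name`, `lo`, `hi` (Hz).
#' @export
eeg_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta"),
    lo = c(1, 4, 8, 13),
    hi = c(4, 8, 13, 30),
    stringsAsFactors = FALSE
  )
}

band_edges <- function(band) {
  if (is.character(band)) {
    b <- eeg_bands()
    i <- match(band, b$name)
    if (is.na(i)) stop("unknown band name: ", band, call. = FALSE)
    c(b$lo[i], b$hi[i])
  } else {
    band <- as.numeric(band)
    if (length(band) != 2 || !all(is.finite(band)) || band[1] <= 0 ||
        band[2] <= band[1]) {
      stop("band must be a name or c(lo, hi) with 0 < lo < hi", call. = FALSE)
    }
    band
  }
}

# Validation helpers --------------------------------------------------------

stop_invalid <- function(...) {
  stop(paste0(...), call. = FALSE)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop_invalid(name, " must be a finite numeric scalar")
  }
  if (strict_lower && x <= lower) {
    stop_invalid(name, " must be > ", lower)
  }
  if (!strict_lower && x < lower) stop_invalid(name, " must be >= ", lower)
  if (x > upper) stop_invalid(name, " must be <= ", upper)
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
      x != round(x) || x < min) {
    stop_invalid(name, " must be an integer >= ", min)
  }
  invisible(as.integer(x))
}

# Seeded evaluation: every stochastic operation takes an explicit seed and
# leaves the caller's RNG state untouched.
with_seed <- function(seed, code) {
  check_count(seed, "seed", min = 0)
  withr::with_seed(as.integer(seed), code)
}

# One global pipeline seed expands into per-stage seeds by a fixed counter
# scheme (seed + 1000 * stage index), so each stage is reproducible on its
# own. Stage indices are documented in run_pipeline().
stage_seed <- function(seed, stage_index) {
  s <- as.integer(seed) + 1000L * as.integer(stage_index)
  if (s >= .Machine$integer.max) s <- s %% .Machine$integer.max
  s
}

# Spectral primitives -------------------------------------------------------

# Frequency (Hz) of each FFT bin for an n-sample signal at rate fs.
fft_freqs <- function(n, fs) {
  (seq_len(n) - 1) / n * fs
}

# Logical mask over FFT bins whose |frequency| falls inside [lo, hi].
# Includes the mirrored negative-frequency bins so that masking keeps the
# signal real after inverse FFT.
fft_band_mask <- function(n, fs, lo, hi) {
  f <- fft_freqs(n, fs)
  f_signed <- ifelse(f > fs / 2, f - fs, f)
  abs(f_signed) >= lo & abs(f_signed) <= hi
}

# Zero-phase band-pass by FFT masking: exact passband, no filter delay.
fft_bandpass <- function(x, fs, lo, hi) {
  n <- length(x)
  if (hi >= fs / 2) stop_invalid("band upper edge ", hi,
                                 " Hz is at/above Nyquist (fs = ", fs, ")")
  X <- stats::fft(x)
  X[!fft_band_mask(n, fs, lo, hi)] <- 0i
  Re(stats::fft(X, inverse = TRUE)) / n
}

# Analytic signal via the frequency-domain Hilbert construction.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Unit-variance Gaussian noise band-limited to [lo, hi] Hz. Consumes RNG.
bandlimited_noise <- function(n, fs, lo, hi) {
  x <- fft_bandpass(stats::rnorm(n), fs, lo, hi)
  s <- stats::sd(x)
  if (s == 0) stop_invalid("degenerate band-limited noise (band too narrow?)")
  x / s
}

hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

# One-way repeated-measures ANOVA ------------------------------------------

#' One-way repeated-measures ANOVA on a participants x conditions table
#'
#' Classic within-subject decomposition: the subject stratum is removed and
#' the condition effect is tested against the subject-by-condition residual.
#' Also reports partial eta squared, the effect size conventionally quoted
#' with this design.
#'
#' @param mat Numeric matrix, rows = participants, columns = conditions.
#'   No missing cells allowed.
#' @return List with `F`, `df1`, `df2`, `p_value`, `partial_eta2`, `method`.
#' @export
rm_anova <- function(mat) {
  mat <- as.matrix(mat)
  if (any(!is.finite(mat))) stop_invalid("rm_anova: missing cells in table")
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2 || k < 2) stop_invalid("rm_anova: need >= 2 participants and >= 2 conditions")
  grand <- mean(mat)
  ss_cond <- n * sum((colMeans(mat) - grand)^2)
  ss_subj <- k * sum((rowMeans(mat) - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  ms_err <- ss_err / df2
  f <- if (ms_err > 0) (ss_cond / df1) / ms_err else if (ss_cond == 0) 0 else Inf
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  pe2 <- if (ss_cond + ss_err > 0) ss_cond / (ss_cond + ss_err) else 0
  list(F = f, df1 = df1, df2 = df2, p_value = p, partial_eta2 = pe2,
       method = "one-way repeated-measures ANOVA")
}

# Cohen's d with pooled SD for two independent samples.
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  if (sp == 0) return(0)
  (mean(x) - mean(y)) / sp
}

# Tiny polynomial rolling hash over a string; used to fingerprint run
# configurations so outputs from different configs are distinguishable.
# (Not cryptographic; a stable 8-hex-digit checksum is all that is needed.)
config_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967291
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
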