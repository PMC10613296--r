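# Single-neuron analysis: unit filtering, PSTHs, trial-by-trial
# ambiguity-coding selection, cumulative-sum differential latency with
# FDR/cluster thresholding, and between-group permutation inference.

neuron_ids <- function(dataset) unique(dataset$trials$neuron_id)

neuron_trials <- function(dataset, id) {
  dataset$trials[dataset$trials$neuron_id == id, , drop = FALSE]
}

neuron_spikes <- function(dataset, id) {
  dataset$spikes[dataset$spikes$neuron_id == id, , drop = FALSE]
}

# Whole-task mean firing rate of a neuron (all spikes / total recorded time).
whole_task_rate <- function(dataset, id) {
  nsp <- nrow(neuron_spikes(dataset, id))
  ntr <- nrow(neuron_trials(dataset, id))
  if (ntr == 0) return(NA_real_)
  nsp / (ntr * dataset$trial_duration)
}

#' Filter units by overall firing rate
#'
#' Retains neurons whose average firing rate over the entire task is at
#' least `min_rate` (inclusive at the boundary). Sparsely firing units
#' below this rate do not yield stable condition-resolved estimates.
#'
#' @param dataset A [spike_dataset()].
#' @param min_rate Minimum whole-task rate in Hz (default 0.2).
#' @return The filtered [spike_dataset()].
#' @export
filter_units <- function(dataset, min_rate = 0.2) {
  if (!inherits(dataset, "spike_dataset")) {
    stop_invalid("dataset must be a spike_dataset")
  }
  ids <- neuron_ids(dataset)
  if (!length(ids)) stop_invalid("empty dataset")
  rates <- vapply(ids, function(id) whole_task_rate(dataset, id),
                  numeric(1))
  keep <- ids[rates >= min_rate]
  spike_dataset(
    dataset$spikes[dataset$spikes$neuron_id %in% keep, , drop = FALSE],
    dataset$trials[dataset$trials$neuron_id %in% keep, , drop = FALSE],
    dataset$trial_duration)
}

#' Peri-stimulus time histogram for one neuron
#'
#' Trial-averaged firing rate per condition in consecutive bins aligned to
#' stimulus onset: `rate[b] = total spikes in bin b / (n_trials *
#' bin_width)`. Bins are half-open `[t, t + bin_width)`.
#'
#' @param dataset A [spike_dataset()].
#' @param neuron_id Which neuron.
#' @param bin_width Bin width in seconds (default 0.250).
#' @param window Time range `c(t0, t1)` in seconds relative to onset;
#'   defaults to the full trial.
#' @return Object of class `psth`: list with `bin_edges` (left edges),
#'   `bin_width`, `rates` and `sem` (conditions x bins matrices, Hz),
#'   `n_trials` per condition.
#' @export
compute_psth <- function(dataset, neuron_id, bin_width = 0.250,
                         window = NULL) {
  if (is.null(window)) window <- c(0, dataset$trial_duration)
  if (window[2] <= window[1]) stop_invalid("window must have t1 > t0")
  edges <- seq(window[1], window[2], by = bin_width)
  if (length(edges) < 2) stop_invalid("window shorter than one bin")
  nb <- length(edges) - 1
  tr <- neuron_trials(dataset, neuron_id)
  if (!nrow(tr)) stop_invalid("unknown neuron: ", neuron_id)
  sp <- neuron_spikes(dataset, neuron_id)
  conds <- ambiguity_levels()[ambiguity_levels() %in% tr$ambiguity_level]
  rates <- matrix(0, length(conds), nb,
                  dimnames = list(conds, NULL))
  sems <- rates
  n_trials <- stats::setNames(integer(length(conds)), conds)
  for (cd in conds) {
    tids <- tr$trial_id[tr$ambiguity_level == cd]
    if (!length(tids)) stop_invalid("no trials for condition ", cd)
    n_trials[cd] <- length(tids)
    counts <- matrix(0, length(tids), nb)
    for (i in seq_along(tids)) {
      st <- sp$spike_time_s[sp$trial_id == tids[i]]
      st <- st[st >= window[1] & st < window[2]]
      if (length(st)) {
        counts[i, ] <- tabulate(findInterval(st, edges,
                                             rightmost.closed = FALSE),
                                nbins = nb)
      }
    }
    rates[cd, ] <- colSums(counts) / (length(tids) * bin_width)
    sems[cd, ] <- apply(counts, 2, stats::sd) / sqrt(length(tids)) /
      bin_width
  }
  structure(list(bin_edges = edges[-length(edges)], bin_width = bin_width,
                 rates = rates, sem = sems, n_trials = n_trials),
            class = "psth")
}

# Per-trial spike count of one neuron inside [t0, t1).
window_counts <- function(dataset, id, window) {
  tr <- neuron_trials(dataset, id)
  sp <- neuron_spikes(dataset, id)
  in_win <- sp$spike_time_s >= window[1] & sp$spike_time_s < window[2]
  cnt <- table(factor(sp$trial_id[in_win], levels = tr$trial_id))
  data.frame(trial_id = tr$trial_id, ambiguity_level = tr$ambiguity_level,
             count = as.integer(cnt))
}

#' Select neurons whose firing rate tracks emotion ambiguity
#'
#' For each neuron, ordinary least-squares regression of the per-trial
#' firing rate in the selection window on the ambiguity level code
#' (anchor = 1, intermediate = 2, high = 3; only the ordering matters).
#' Neurons with a two-sided slope p below `alpha` are selected as
#' ambiguity-coding. Preference is classified from the mean window rate at
#' the extremes: "ambiguous" if high-ambiguity exceeds anchor, otherwise
#' "unambiguous" (ties fall to "unambiguous").
#'
#' @param dataset A [spike_dataset()].
#' @param window Selection window in seconds (default 0.250 to 1.750 after
#'   stimulus onset).
#' @param alpha Selection threshold on the slope p-value (default 0.05).
#' @return data.frame with one row per neuron: `neuron_id`, `region`,
#'   `slope` (Hz per ambiguity step), `p_value`, `selected`, `preference`,
#'   `flagged` (TRUE when the rate is constant and the test undefined).
#' @export
select_ambiguity_neurons <- function(dataset, window = c(0.250, 1.750),
                                     alpha = 0.05) {
  if (!inherits(dataset, "spike_dataset")) {
    stop_invalid("dataset must be a spike_dataset")
  }
  ids <- neuron_ids(dataset)
  win_len <- window[2] - window[1]
  res <- lapply(ids, function(id) {
    wc <- window_counts(dataset, id, window)
    if (length(unique(wc$ambiguity_level)) < 2) {
      stop_invalid("neuron ", id, ": need >= 2 ambiguity levels with trials")
    }
    rate <- wc$count / win_len
    code <- match(wc$ambiguity_level, ambiguity_levels())
    region <- neuron_trials(dataset, id)$region[1]
    if (stats::var(rate) == 0 || stats::var(code) == 0) {
      return(data.frame(neuron_id = id, region = region, slope = NA_real_,
                        p_value = NA_real_, selected = FALSE,
                        preference = NA_character_, flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    fit <- stats::lm.fit(cbind(1, code), rate)
    n <- length(rate)
    rss <- sum(fit$residuals^2)
    sxx <- sum((code - mean(code))^2)
    se <- sqrt(rss / (n - 2) / sxx)
    slope <- unname(fit$coefficients[2])
    tval <- slope / se
    p <- 2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE)
    mean_high <- mean(rate[wc$ambiguity_level == "high"])
    mean_anchor <- mean(rate[wc$ambiguity_level == "anchor"])
    pref <- if (is.finite(mean_high) && is.finite(mean_anchor) &&
                mean_high > mean_anchor) "ambiguous" else "unambiguous"
    data.frame(neuron_id = id, region = region, slope = slope,
               p_value = p, selected = is.finite(p) && p < alpha,
               preference = pref, flagged = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Population-level binomial test for selection counts
#'
#' Tail probability of observing more than `k_selected` ambiguity-coding
#' neurons among `n_total` when each is selected independently with
#' probability `p0`. The strict upper tail `P(X > k)` is used: for
#' example, 36 selected of 321 at `p0 = 0.05` gives 2.58e-6, and 29 of
#' 236 gives 3.09e-6.
#'
#' @param k_selected Number of selected neurons.
#' @param n_total Total number of neurons tested.
#' @param p0 Chance selection probability (default 0.05, the selection
#'   alpha).
#' @return The tail probability (numeric scalar).
#' @export
population_binomial <- function(k_selected, n_total, p0 = 0.05) {
  k <- check_count(k_selected, "k_selected", min = 0)
  n <- check_count(n_total, "n_total", min = 1)
  if (k > n) stop_invalid("k_selected cannot exceed n_total")
  check_scalar(p0, "p0", lower = 0, upper = 1)
  stats::pbinom(k, n, p0, lower.tail = FALSE)
}

#' Cumulative spike-count curves on a 1-ms grid
#'
#' Spike trains are binned at `bin` resolution, averaged across trials of
#' each ambiguity level, and cumulatively summed. The result for each
#' neuron is a levels x timepoints matrix of mean cumulative spike counts,
#' monotone non-decreasing along time.
#'
#' @param dataset A [spike_dataset()].
#' @param bin Bin width in seconds (default 0.001).
#' @param t_range Time range `c(t0, t1)` in seconds (default the full
#'   trial).
#' @return Object of class `cumulative_curves`: list with `times` (bin
#'   left edges, seconds), `bin`, and `curves`, a named list (per neuron)
#'   of levels x timepoints matrices.
#' @export
cumulative_curves <- function(dataset, bin = 0.001, t_range = NULL) {
  if (!inherits(dataset, "spike_dataset")) {
    stop_invalid("dataset must be a spike_dataset")
  }
  if (is.null(t_range)) t_range <- c(0, dataset$trial_duration)
  edges <- seq(t_range[1], t_range[2], by = bin)
  nb <- length(edges) - 1
  times <- edges[-length(edges)]
  ids <- neuron_ids(dataset)
  curves <- lapply(ids, function(id) {
    tr <- neuron_trials(dataset, id)
    sp <- neuron_spikes(dataset, id)
    lvls <- ambiguity_levels()[ambiguity_levels() %in% tr$ambiguity_level]
    m <- matrix(0, length(lvls), nb, dimnames = list(lvls, NULL))
    for (lv in lvls) {
      tids <- tr$trial_id[tr$ambiguity_level == lv]
      st <- sp$spike_time_s[sp$trial_id %in% tids]
      st <- st[st >= t_range[1] & st < t_range[2]]
      cnt <- if (length(st)) {
        tabulate(findInterval(st, edges, rightmost.closed = FALSE),
                 nbins = nb)
      } else numeric(nb)
      m[lv, ] <- cumsum(cnt / length(tids))
    }
    m
  })
  names(curves) <- ids
  structure(list(times = times, bin = bin, curves = curves),
            class = "cumulative_curves")
}

#' Orient cumulative curves as preferred vs non-preferred
#'
#' Builds the neurons x timepoints matrices of mean cumulative counts for
#' a uniform group of neurons: one matrix for the preferred ambiguity
#' level and one for the non-preferred level. For an amygdala-like group
#' preferring unambiguous faces use `preferred = "anchor",
#' nonpreferred = "high"`; the reverse for a dmPFC-like group.
#'
#' @param cc A [cumulative_curves()] object.
#' @param preferred,nonpreferred Ambiguity levels to contrast.
#' @return Object of class `oriented_curves`: list with `pref`, `nonpref`
#'   (neurons x timepoints matrices) and `times` (seconds).
#' @export
oriented_curves <- function(cc, preferred, nonpreferred) {
  if (!inherits(cc, "cumulative_curves")) {
    stop_invalid("cc must be a cumulative_curves object")
  }
  pull <- function(level) {
    t(vapply(cc$curves, function(m) {
      if (!level %in% rownames(m)) {
        stop_invalid("a neuron lacks level '", level, "'")
      }
      m[level, ]
    }, numeric(length(cc$times))))
  }
  structure(list(pref = pull(preferred), nonpref = pull(nonpreferred),
                 times = cc$times),
            class = "oriented_curves")
}

# Vectorized one-tailed paired t over time points: tests pref > nonpref.
paired_onetail_p <- function(pref, nonpref) {
  d <- pref - nonpref
  n <- nrow(d)
  m <- colMeans(d)
  v <- pmax(colSums(d^2) - n * m^2, 0) / (n - 1)
  p <- rep(1, length(m))
  nz <- v > 0
  p[nz] <- stats::pt(m[nz] / sqrt(v[nz] / n), n - 1, lower.tail = FALSE)
  p[!nz & m > 0] <- 0
  p
}

#' Differential response latency of a uniform neuron group
#'
#' At every time point the mean cumulative spike count for the preferred
#' level is compared against the non-preferred level with a one-tailed
#' paired t-test across neurons (preferred > non-preferred). P-values are
#' Benjamini-Hochberg corrected over time points and thresholded at
#' `alpha`; surviving points are grouped into maximal runs, and the
#' latency is the first time point of the dominant (longest) run longer
#' than `cluster_min` points, the earliest on ties. Taking the dominant
#' cluster rather than the first qualifying one keeps the estimate robust
#' to short chance runs that can survive the adaptive FDR threshold when
#' a strong genuine cluster is present (cumulative sums are strongly
#' autocorrelated, so chance excursions come in runs). Because the
#' contrast is paired within neuron, the estimate is insensitive to
#' baseline-rate differences across neurons.
#'
#' @param oc An [oriented_curves()] object (>= 3 neurons).
#' @param alpha Threshold on BH-adjusted p (default 0.01).
#' @param cluster_min Minimum cluster size, exclusive (default 10: runs
#'   must exceed 10 points, i.e. length >= 11).
#' @return Object of class `latency_result`: list with `latency_ms`
#'   (NA when no qualifying cluster), `cluster_start_ms`,
#'   `cluster_length`, `alpha`, `cluster_min`, `n_neurons`.
#' @export
differential_latency <- function(oc, alpha = 0.01, cluster_min = 10) {
  if (!inherits(oc, "oriented_curves")) {
    stop_invalid("oc must be an oriented_curves object")
  }
  n <- nrow(oc$pref)
  if (n < 3) stop_invalid("need >= 3 neurons for the paired t-test")
  p <- paired_onetail_p(oc$pref, oc$nonpref)
  padj <- stats::p.adjust(p, method = "BH")
  sig <- padj < alpha
  lat <- NA_real_; cstart <- NA_real_; clen <- 0L
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values & r$lengths > cluster_min)
  if (length(hit)) {
    i <- hit[which.max(r$lengths[hit])]
    lat <- oc$times[starts[i]] * 1000
    cstart <- lat
    clen <- r$lengths[i]
  }
  structure(list(latency_ms = lat, cluster_start_ms = cstart,
                 cluster_length = as.integer(clen), alpha = alpha,
                 cluster_min = as.integer(cluster_min), n_neurons = n),
            class = "latency_result")
}

#' Permutation test for a between-group latency difference
#'
#' The observed statistic is the difference of differential latencies
#' between two neuron groups (e.g. amygdala vs dmPFC). The null is built
#' by shuffling the group assignment of the (preference-oriented) neurons
#' while keeping group sizes, recomputing both latencies per shuffle.
#' `p = (1 + #(|null| >= |observed|)) / (n_perm + 1)`.
#'
#' @param oc_a,oc_b [oriented_curves()] for the two groups (time grids
#'   must match).
#' @param n_perm Number of shuffles (default 1000).
#' @param seed Integer seed; identical seeds give identical p-values.
#' @param alpha,cluster_min Passed to [differential_latency()].
#' @return Object of class `latency_permutation`: list with
#'   `latency_a_ms`, `latency_b_ms`, `observed_diff_ms`, `null_diffs`,
#'   `p_value`, `n_undefined` (shuffles where a latency was undefined,
#'   dropped from the null), `n_perm`, `seed`.
#' @export
latency_permutation <- function(oc_a, oc_b, n_perm = 1000, seed = 1,
                                alpha = 0.01, cluster_min = 10) {
  if (!identical(oc_a$times, oc_b$times)) {
    stop_invalid("the two groups must share the same time grid")
  }
  la <- differential_latency(oc_a, alpha, cluster_min)$latency_ms
  lb <- differential_latency(oc_b, alpha, cluster_min)$latency_ms
  if (is.na(la) || is.na(lb)) {
    stop_invalid("both groups must yield defined latencies")
  }
  obs <- la - lb
  pool_pref <- rbind(oc_a$pref, oc_b$pref)
  pool_non <- rbind(oc_a$nonpref, oc_b$nonpref)
  na <- nrow(oc_a$pref); ntot <- nrow(pool_pref)
  null_diffs <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(ntot, na)
      oa <- structure(list(pref = pool_pref[idx, , drop = FALSE],
                           nonpref = pool_non[idx, , drop = FALSE],
                           times = oc_a$times), class = "oriented_curves")
      ob <- structure(list(pref = pool_pref[-idx, , drop = FALSE],
                           nonpref = pool_non[-idx, , drop = FALSE],
                           times = oc_a$times), class = "oriented_curves")
      differential_latency(oa, alpha, cluster_min)$latency_ms -
        differential_latency(ob, alpha, cluster_min)$latency_ms
    }, numeric(1))
  })
  n_undef <- sum(is.na(null_diffs))
  if (n_undef > n_perm / 2) {
    warning("latency undefined in ", n_undef, " of ", n_perm,
            " shuffles; permutation p unreliable", call. = FALSE)
  }
  valid <- null_diffs[!is.na(null_diffs)]
  p <- (1 + sum(abs(valid) >= abs(obs))) / (length(valid) + 1)
  structure(list(latency_a_ms = la, latency_b_ms = lb,
                 observed_diff_ms = obs, null_diffs = null_diffs,
                 p_value = p, n_undefined = n_undef,
                 n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "latency_permutation")
}
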