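---
title: "Methods: quantifying emotion-ambiguity processing across modalities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying emotion-ambiguity processing across modalities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ambiguitynet)
```

## The scientific problem

Judging the emotion of a morphed fear-happy face becomes harder as the
morph approaches the category boundary. `ambiguitynet` implements, as one
tested pipeline, the quantitative machinery used to study how the brain
represents and resolves this ambiguity across four kinds of recordings:

1. **Behavior** — logistic psychometric curves over the morph continuum,
   reaction-time (RT) and confidence modulation by ambiguity;
2. **Single neurons** — selection of ambiguity-coding units and a
   cumulative-sum differential-latency estimate comparing brain regions;
3. **Scalp EEG** — Pz-seeded cross-channel coherence and delta-band
   amplitude-amplitude cross-frequency coupling (CFC);
4. **Source-level series** — directed connectivity via the directed
   transfer function (DTF) on multivariate autoregressive (MVAR) models;

plus a linear model predicting amygdala-dmPFC functional connectivity
from a participant's behavioral ambiguity sensitivity.

Since the original human recordings are not redistributable, a
first-class synthetic-data module generates all four input kinds with
known ground truth; every claim the test suite makes is a claim about
recovery of that ground truth or about closed-form/oracle agreement.

## Task structure and grouping

The morph grid is fixed at {0, 30, 40, 50, 60, 70, 100}% fear. Levels 0
and 100 are unambiguous *anchors*, 30/70 are *intermediate*, and 40-60
are *high* ambiguity (`group_ambiguity()`). All analyses use this
three-level ordinal grouping, coded 1/2/3 where a code is needed; only
the ordering matters for the statistics computed here.

## Behavioral model

Choices follow the three-parameter logistic

$$P(x) = \frac{P_\infty}{1 + e^{-\alpha (x - x_{half})}}$$

where $x_{half}$ is the discrimination threshold (percent fear at the
inflection) and $\alpha$ the sensitivity (steepness, per percent).
`fit_psychometric()` minimizes the sum of squared deviations between the
curve and the *per-level observed fear proportions* (not a trial-level
likelihood — the fit target is the proportion table). The optimizer is a
bounded multi-start quasi-Newton search with $P_\infty \in (0, 1.05]$,
$x_{half} \in [0, 100]$, $\alpha \in (0, 5]$, started from a
moment-based guess plus a coarse grid; flat-slope regimes have shallow,
multimodal RSS surfaces and a single start is not reliable. A session in
which every choice is identical leaves $\alpha$ unidentifiable and is
returned with `converged = FALSE` rather than a spurious fit. The test
suite pins the optimizer against a brute-force profiled grid search and
against noise-free self-consistency.

Ambiguity sensitivity is the raw RT difference
$\Delta RT = \overline{RT}_{high} - \overline{RT}_{anchor}$ in
**seconds**. Modulation indices are
$(\overline{m}_{high} - \overline{m}_{anchor}) / \overline{m}_{anchor}$
for RT, confidence, or confidence RT; trials missing a measure are
dropped per measure, not per session.

The generator (`gen_behavior()`) draws Bernoulli choices from the
logistic and RTs as `rt_base` plus a gain linear in ambiguity (0 at
anchor, half at intermediate, full at high) plus Gaussian noise floored
at 1 ms. The RT distribution family is not constrained by the design
being emulated; truncated-Gaussian is the simplest choice producing
strictly positive RTs, and nothing downstream depends on the shape
beyond its mean structure. Default study-scale conditions: 40 trials per
morph level per participant, `rt_base` 1 s, gain 0.15 s (0.30 s for the
simulated high-sensitivity "patient" cohort), noise SD 0.15 s.

## Single-neuron analysis

Units with a whole-task mean rate below 0.2 Hz are excluded
(inclusive boundary: exactly 0.2 Hz is kept). PSTHs count spikes across
trials in consecutive 250 ms half-open bins, `rate = count /
(n_trials * bin_width)`.

**Selection.** For each neuron, the per-trial firing rate in the 250 to
1750 ms window is regressed on the ambiguity code 1/2/3; two-sided slope
p below 0.05 selects the neuron as ambiguity-coding. Preference is
classified by comparing mean window rates at the two extremes (high vs
anchor), ties falling to "unambiguous". The population-level excess of
selected neurons over the 5% chance rate is quantified with the strict
binomial upper tail $P(X > k)$ — the convention that reproduces the
published worked examples (36/321 gives 2.58e-6 and 29/236 gives
3.09e-6).

**Differential latency.** Spike trains are binned at 1 ms, averaged
across trials of each level, and cumulatively summed. For a uniform
group of neurons (same preference direction), a one-tailed paired t-test
(preferred > non-preferred) is run at every time point, and p-values are
Benjamini-Hochberg corrected across time points and thresholded at 0.01.
(The procedure being emulated states "P < 0.01, one-tailed pairwise
t-test; FDR corrected"; we read that as BH-adjusted p thresholded at
0.01.) Significant points are grouped into maximal runs; the latency is
the first time point of the **dominant (longest) run** exceeding 10
points, earliest on ties.

Why the dominant run and not the first qualifying run: BH's threshold is
adaptive, so in the presence of a long genuine post-onset cluster a
pre-onset point survives at raw $p \approx 0.01 \times$ (fraction
significant). Cumulative-sum noise is so strongly autocorrelated that
such chance excursions arrive in runs comfortably exceeding 10 points,
and the "first run" rule then occasionally returns a spurious early
latency even at 30 neurons and 100 trials. Anchoring on the dominant
cluster removes this failure mode without changing the null behavior
(no qualifying cluster at all yields an undefined latency). The paired
within-neuron contrast makes the estimate insensitive to baseline-rate
differences across neurons, which the tests assert directly.

**Permutation inference.** The group statistic is the latency difference
between two regions. The null shuffles the region assignment of the
preference-oriented neurons while keeping group sizes, recomputing both
latencies per shuffle (1000 runs), with
$p = (1 + \#\{|null| \ge |obs|\}) / (n_{perm} + 1)$. Shuffles where a
latency is undefined are dropped from the null and counted; a warning is
raised when more than half are undefined. The emulated procedure says
only "shuffling the labels for groups"; region-assignment shuffling is
the reading consistent with a between-region statistic.

Synthetic spiking is inhomogeneous Poisson with a rate *step* (not a
ramp) at the onset: a step makes the latency ground truth unambiguous,
at the cost of not emulating the gradual onset of real neurons — latency
recovery tests therefore check a 60 ms window above the true step time
(accumulation lag), not exact equality. Study-scale conditions: 30
neurons per region, 100 trials per level, 5 Hz baseline, ±10 Hz step
between extreme conditions, onsets 300 vs 600 ms.

## EEG coherence

Magnitude-squared coherence
$\Gamma^2_{xy}(f) = |G_{xy}(f)|^2 / (G_{xx}(f) G_{yy}(f))$ is estimated
event-related: each trial is one Hann-tapered, mean-removed segment;
cross- and auto-spectra are averaged across trials; the band summary is
the unweighted mean over FFT bins in 4-23 Hz. Pz is the source channel
(a flag allows others). The analysis window defaults to the 0-1.5 s
post-stimulus epoch; window and taper are estimator choices not fixed by
the emulated design. Two well-known estimator properties are treated as
features to test against, not bugs: coherence of independent signals is
biased upward by about $1/K$ for $K$ segments, and coherence is
invariant to per-channel gain. Condition contrasts across the three
ambiguity levels use a one-way repeated-measures ANOVA (closed-form
within-subject decomposition, cross-checked against `aov()` with an
`Error()` stratum; partial eta squared reported).

The generator builds each channel as a sum of unit-variance band-limited
components (delta 1-4, theta 4-8, alpha 8-13, beta 13-30 Hz — edges are
package-wide constants shared with the CFC module). A coherence target
$T$ for a channel pair in a band is realized by shared-signal mixing
with weight $a = T^{1/4}$ on a common component and
$b = \sqrt{1 - \sqrt{T}}$ on the channel-private component, giving
in-band coherence exactly $T$; no additional broadband noise is layered
on top, so this closed form is exact and testable. What the generator
does **not** emulate: volume conduction, 1/f spectra, artifacts, and
non-stationarity — passing tests demonstrate estimator correctness, not
robustness to real-world EEG contamination. Note that a band summary
over 4-23 Hz dilutes targets set only on theta and alpha with the
incoherent beta range; the per-condition orderings are preserved.

## Cross-frequency coupling

Within the 2 s epoch (-0.5 to +1.5 s), signals are band-passed by
zero-phase frequency-domain masking and the analytic-signal amplitude is
taken; the outer 10% of samples on each side are flagged as edge
transients and excluded from statistics. The coupling index regresses
the standardized high-band envelope (theta, alpha, or beta) on the
standardized delta envelope, samples pooled across trials within a
participant — the index is thus a correlation, bounded by 1.

Inference is the one place the naive GLM read-out is statistically
wrong: narrowband envelopes decorrelate on the scale of the inverse
bandwidth (hundreds of ms), so pooled samples are far from independent
and the OLS p-value is anti-conservative by an order of magnitude. The
default p-value therefore comes from a trial-shuffling permutation
(re-pairing high-band trials against delta trials), which preserves
within-trial autocorrelation under the null and is calibrated (type-I
near 0.045 with 199-399 shuffles); `method = "parametric"` exposes the
naive p for comparison. The emulated procedure describes
amplitude-amplitude coupling in its methods while mentioning delta phase
elsewhere; amplitude-amplitude is implemented as the primary index, and
an exploratory phase-binned variant (`phase_amplitude_cfc()`) is
provided separately.

The generator injects coupling by modulating the Pz alpha component's
instantaneous amplitude with the normalized delta envelope scaled by a
per-condition gain (floored so the modulation factor stays positive).
Study-scale conditions: gains 0.1 / 0.35 / 0.6 for
anchor/intermediate/high, 20-30 trials per condition at 250 Hz.

## MVAR and the directed transfer function

Source reconstruction (inverse imaging) is out of scope; the module
consumes region-of-interest time series directly. `fit_mvar()` is a
multichannel least-squares fit stacked across trials; `order = "auto"`
minimizes BIC (AIC optional) over 1..20 — the emulated toolbox's
criterion is unstated, and BIC's stronger penalty suits the short
analysis windows used here. Unstable fits (companion spectral radius at
or above 1) are flagged and refused by the DTF rather than silently
used.

The DTF is $\gamma^2_{ij}(f) = |H_{ij}(f)|^2 / \sum_m |H_{im}(f)|^2$
with $H(f) = (I - \sum_k A_k e^{-i 2 \pi f k / f_s})^{-1}$, evaluated on
a 1-30 Hz grid in 1 Hz steps; sink rows sum to 1 by construction
(asserted at machine precision). Two properties are documented and
tested so users are not misled: the DTF reflects *total* (direct plus
mediated) flow — on a chain 1→2→3 the 1→3 entry is nonzero — and it is
invariant to uniform but not per-channel rescaling.

Significance uses a permutation that destroys cross-source temporal
alignment while preserving each source's spectrum: with trials
available (at least 20), each source's trial assignment is shuffled
independently; for a long single series (the group-averaged evoked
signal path), each source is circularly time-shifted by an independent
random offset. The observed band-mean DTF per directed pair is compared
against its null, 1000 runs by default. The surrogate construction is
not specified by the emulated procedure; trial-misalignment is the
standard choice for trial-based data.

## Connectivity prediction

`predict_connectivity()` applies $y = a \cdot \Delta RT + b$ with the
published coefficients $a = 2.4739$, $b = -0.1329$ as defaults ($y$ in
dimensionless model units; the underlying fMRI fit is not reproduced
here). $\Delta RT$ is in seconds; if milliseconds were intended the
predictions would scale by 1000, which is why `validate_inputs()` warns
on RT columns that look like milliseconds. Group comparisons are
two-tailed pooled-variance t-tests of each cohort against controls with
Cohen's d; because the map is affine, these statistics equal the same
tests on $\Delta RT$ itself (asserted to 1e-10), so the model changes
units and interpretation, never inference. Normalized predictions
subtract the control-group mean.

## Numerical conventions and degenerate inputs

* Time is in seconds relative to stimulus onset; bins are half-open
  $[t, t + \Delta)$; sample $k$ of an epoch sits at $t_0 + k/f_s$.
* Every stochastic operation takes an explicit integer seed and restores
  the caller's RNG state; a pipeline-level seed expands into per-stage
  seeds as `seed + 1000 * stage_index`.
* Permutation p-values use the add-one convention
  $(1 + k)/(n + 1)$, so they are never exactly zero.
* Degenerate inputs fail loudly: constant regressors, missing source
  channels, off-grid morph levels, unstable MVAR coefficients, fewer
  than 3 neurons for a paired t, fewer than 2 coherence segments
  (coherence is identically 1 from one segment).

## Problem sizes

The packaged tests and the acceptance script run: latency recovery at 30
neurons per region with 100 trials per level and 1000 shuffles;
selection null calibration at 200 neurons times 100 replicates;
CFC and DTF type-I calibration at 100 replicates each (399 and 199
shuffles); psychometric recovery at 200 trials per level times 100
replicates; spectral oracles at 50-100 segments. These sizes give
stable Monte-Carlo estimates at interactive runtimes on a single CPU.

## Known limitations

* The synthetic EEG has flat band spectra and no volume conduction;
  coherence topographies are not physiologically patterned.
* The spike generator's rate step yields a small positive bias
  (accumulation lag) in recovered latencies, bounded by the test
  tolerance of 60 ms at the study's trial counts.
* The DTF does not separate direct from mediated flow; use it as a
  directed-influence summary, not a structural estimate.
* The chi-square statistic sometimes quoted alongside the preference
  counts of ambiguity-coding neurons is not reproducible from the
  stated counts under standard one-degree-of-freedom constructions and
  is deliberately not implemented.
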