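# ambiguitynet

Multimodal analysis of how the brain processes **ambiguous facial
emotion**, packaged as a tested R pipeline. The scientific setting:
participants judge faces morphed between happy (0% fear) and fearful
(100% fear) at seven morph levels; levels group into three ambiguity
conditions (anchor 0/100, intermediate 30/70, high 40–60). The package
implements the quantitative core used to study this task across four
recording modalities, plus a synthetic-data module that generates every
input kind with known ground truth, so the whole pipeline is testable
without access to human recordings.

For researchers in cognitive/systems neuroscience who need these
estimators as reusable, validated components:

* **Behavior** — logistic psychometric fit
  `P(x) = P_inf / (1 + exp(-α (x − x_half)))` giving threshold `x_half`
  and sensitivity `α`; ambiguity modulation indices
  `(high − anchor)/anchor`; ambiguity sensitivity `ΔRT` (seconds).
* **Single neurons** — 0.2 Hz unit filter; 250 ms PSTHs; trial-by-trial
  regression selection of ambiguity-coding neurons with a strict-tail
  binomial population test `P(X > k | n, 0.05)`; cumulative-sum (1 ms)
  **differential latency** via one-tailed paired t-tests across neurons,
  Benjamini–Hochberg FDR at 0.01 and a >10-point cluster rule, with
  1000-run group-label permutation inference.
* **EEG** — event-related magnitude-squared coherence
  `Γ²(f) = |G_xy|² / (G_xx G_yy)` of all channels with source Pz,
  summarized over 4–23 Hz; delta-band amplitude–amplitude
  cross-frequency coupling (standardized envelope regression with
  trial-shuffling permutation inference); repeated-measures condition
  contrasts.
* **Directed connectivity** — least-squares MVAR fitting with BIC order
  selection and the directed transfer function
  `γ²_ij(f) = |H_ij(f)|² / Σ_m |H_im(f)|²` on a 1–30 Hz grid with
  trial-misalignment permutation significance.
* **Prediction** — the linear map `y = a·ΔRT + b` (defaults
  `a = 2.4739`, `b = −0.1329`) from behavioral ambiguity sensitivity to
  amygdala–dmPFC functional connectivity, with affine-invariant group
  comparisons against controls.

See `vignettes/ambiguitynet-methods.Rmd` for the full model account,
estimator choices, and limitations.

## Worked example

The `analysis/` directory holds the narrative drivers
(`01_simulate.R` … `05_prediction.R`); each writes its tables under
`results/`. Running them in order on the packaged study conditions
prints:

```
$ Rscript analysis/02_behavior.R
fitted 24 participants (24 converged)
median threshold x_half = 50.5%, median sensitivity = 0.218
mean delta RT: control 0.142 s, patient 0.293 s
delta-RT group contrast: t = -19.24, p = 3e-15, d = -7.85
```

The simulated truth was `x_half = 50`, `α = 0.2`, RT gains 0.15 s
(controls) vs 0.30 s (patients): thresholds and sensitivities are
recovered, and the cohorts separate cleanly on `ΔRT`.

```
$ Rscript analysis/03_spike_latency.R
amygdala: 30/30 neurons ambiguity-coding (100.0%), binomial tail p = 0
dmPFC: 30/30 neurons ambiguity-coding (100.0%), binomial tail p = 0
differential latency: amygdala-like 308 ms, dmPFC-like 614 ms (truth 300/600)
latency difference -306 ms, permutation p = 0.0010 (1000 runs)
```

The amygdala-like population (preferring unambiguous faces, rate step at
300 ms) is recovered ~300 ms before the dmPFC-like population (step at
600 ms), and the 1000-run permutation calls the difference significant.

```
$ Rscript analysis/04_eeg_connectivity.R
Pz-Cz coherence anchor/intermediate/high: 0.27 / 0.19 / 0.14
delta-alpha index anchor/intermediate/high: 0.05 / 0.15 / 0.19
selected MVAR order 1 (BIC), stable: TRUE
band-mean flow R.dmPFC -> L.occipital: 0.328 (p = 0.000999); reverse 0.000 (p = 0.278)
```

Coherence tracks the per-condition targets (the 4–23 Hz summary dilutes
targets set on theta/alpha with the incoherent beta range, preserving
the ordering), the delta→alpha coupling index follows the injected
gains, and the DTF recovers the one-way source coupling.

```
$ Rscript analysis/05_prediction.R
predicted connectivity, control mean: 0.219
patient vs control: mean diff 0.372, t(22) = 19.24, p = 2.99e-15, d = 7.85
```

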