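---
title: "Methods: discriminating birdsong performance contexts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discriminating birdsong performance contexts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters, and numerical choices
behind `songsift`. The package studies a single scientific question at two
levels: can a classifier detect, from acoustic features alone, whether a
song motif was performed in a courtship or a non-courtship context — and
does a trained listener's behavior track the same signal?

Because no recordings or trial logs ship with the package, everything runs
against a synthetic generator whose ground truth is known by construction.
All problem sizes, effect sizes, and seeds below are the package's own
choices, fixed once before the acceptance runs.

## 1. Synthetic motif model

A motif is a sequence of harmonic-stack syllables (default 4) at 44.1 kHz.
The harmonic stack uses cosine phases, which makes the bare carrier an
even (palindromic) waveform — time-reversible by construction. Any
measured time irreversibility therefore comes from the amplitude
envelope, not the carrier, which keeps the spectral cues and the
irreversibility cue separable by design.
Each bird has a stable "song profile" (per-syllable fundamental ratios,
duration pattern, baseline harmonic decay) drawn from its own seeded
stream, so adding birds or renditions never perturbs existing ones. Bird
`i`'s base fundamental is `600 + (i - 1) * 60` Hz.

Three knobs inject the context contrast:

- `f0_context_shift` (default 0.05): courtship raises the fundamental by
  5% — a pitch/spectral-location cue.
- `bandwidth_effect` (default 0.3): non-courtship weakens the per-harmonic
  amplitude decay by 30%, widening the spectral spread — the cue the PSD
  interquartile-range features target.
- `asym_effect` (default 0.4): non-courtship increases the attack/decay
  asymmetry of the amplitude envelope. The asymmetry is applied at the
  syllable scale *and* at the fundamental-period scale (a pulsatile
  per-cycle envelope). The period-scale component is deliberate: a purely
  syllable-scale asymmetry modulates the waveform so slowly that its
  contribution to lag-1..4 difference statistics cancels, whereas real
  vocal asymmetries live at the glottal-pulse scale. This is what makes the
  waveform measurably time-irreversible.

Rendition-to-rendition variability is lognormal jitter with per-parameter
coefficients of variation `(f0 = 0.02, decay = 0.15, asym = 0.20,
dur = 0.08, amp = 0.12)` — pitch is highly stereotyped in zebra finches
while timbre and envelope dynamics vary more — plus additive white noise at
1% of signal RMS.

```{r}
library(songsift)
cfg <- synth_config(n_birds = 17, renditions_per_context = 30, seed = 1)
dataset <- make_dataset(cfg)
```

## 2. Feature bank

`default_registry()` holds ~19 operations producing ~180 scalar features
per motif, mirroring the families of a large time-series feature library:
autocorrelation shape and first zero; automutual information (histogram
estimator) and its first minimum; time irreversibility (`co_trev`,
`dk_trev`) at fixed lags and at data-driven lags (first ACF zero, first AMI
minimum); noise-robustness of the AMI; permutation entropy at several
orders and coarse-graining scales; symbolic-dynamics statistics
(above/below-mean runs, quantile-alphabet transition matrices, word
entropies); AR model order selection, coefficients, and forecast errors;
sliding-window stationarity; difference statistics; a random-walker
surrogate; iterated-preprocessing comparisons; spectral summaries (centroid,
spread, IQR, entropy, peaks) from Welch, windowed-FFT, and periodogram PSD
estimators; and a 12-feature spectrogram baseline (mean pitch, amplitude,
and mean/variance of centroid, Wiener entropy, pitch goodness, FM, AM),
explicitly labeled an approximation of the Sound Analysis Pro defaults.

Preprocessing before extraction: DC removal, 250–8000 Hz bandpass, RMS
normalization.

Numerical choices worth knowing:

- FFT lengths are zero-padded to the next power of two. Motif lengths are
  often twice a prime, for which R's mixed-radix FFT degrades badly; padding
  changes only the frequency grid, and spectral summaries integrate over
  it.
- ACF lag scans are capped at 128 lags and AMI first-minimum scans at 30;
  motif ACF first zeros sit near lag 15–20 at 44.1 kHz, far inside the cap.
- Per-motif computations (ACF vectors, quantile symbolizations) are
  memoized across operations, which dominates throughput at study scale
  (~1000 motifs extract in ~3 minutes on one CPU).
- Failed or undefined features return NA markers rather than erroring; the
  normalization stage filters them.

## 3. Normalization

`normalize_features()` applies, in order: (1) drop features with any
non-finite value or zero variance; (2) outlier-robust sigmoid per feature,
`1 / (1 + exp(-(v - median) / (1.35 * IQR)))`; (3) min–max scaling to
[0, 1]. The sigmoid's constant makes `1.35 * IQR` a robust estimate of one
standard deviation for Gaussian data. Note that extreme outliers (beyond
~36 robust SDs) saturate to exactly 0 or 1 in double precision; the
subsequent unit scaling is unaffected.

## 4. Classification protocol

The classifier is a bagged decision-tree ensemble (implemented with
`ranger`: bootstrap-resampled trees, `sqrt(p)` features per split, 300
trees, impurity importance, single-threaded for exact reproducibility).
The class score is the fraction of trees voting "courtship"; ties at 0.5
resolve to "noncourtship".

- **Accuracy**: stratified 10-fold cross-validation repeated 10 times; the
  headline number is the median over iterations.
- **Importance**: impurity importance from a model trained on all data,
  normalized to max 1.
- **Panels**: `top_k_evaluation()` re-runs the CV on the 50 most important
  features; `random_subset_benchmark()` does the same for random 50-feature
  panels (default 200 draws) to show the ranked panel is not a size
  artifact.
- **Confidence**: `|score - 0.5|`, signed positive when the predicted label
  is correct; `classifier_vs_subject()` regresses subject accuracy on
  confidence.

At study scale (17 birds × 30 renditions × 2 contexts, default effects) the
combined classifier exceeds 80% median CV accuracy, and with all three
context effects at zero it stays inside the 95% binomial interval of
chance — both enforced as acceptance tests.

## 5. Behavioral analysis

Synthetic 2AFC sessions draw per-trial correctness from a sigmoid
`p(day) = p_start + (p_asymptote - p_start) / (1 + exp(-slope (day - d0)))`
with probe trials interleaved at 15% and rewarded at a fixed rate
regardless of response.

The learning criterion proceeds in four steps:

1. Summarize days (≥ 20 responses, reward-balanced perches only) and fit a
   4-parameter logistic to daily percent correct (`L, U` bounded to
   [0, 100], `s ≥ 0`), via Levenberg–Marquardt least squares.
2. Compute the learning threshold as the lower 95% bound of a single day's
   observed asymptotic performance:
   `U - t * sqrt(se(U)^2 + sigma^2)`, where `se(U)` comes from the fit's
   parameter covariance and `sigma` is the residual day-to-day SD. The
   parameter-only bound `U - t * se(U)` is also available
   (`threshold_method = "parameter"`), but it is *not* usable with a
   run-length rule: its margin shrinks like `sigma / sqrt(days)`, so at
   hundreds of trials per day it sits well inside the daily binomial noise
   and consecutive-day runs above it break by chance even in a fully
   learned subject (per-day exceedance ≈ 0.8, detection a coin flip at any
   slope or session count). The prediction-style bound keeps per-day
   exceedance at asymptote near 0.96 without costing specificity: a flat
   performer sits above its (low) bound essentially every day, which makes
   any run uninformative, and the subject is declared not learned.
3. `required_run_length(n, p, alpha)` returns the smallest `r` with
   `n * p^r < alpha`: the run length whose expected number of chance
   occurrences across the task falls below `alpha`. `p` is the empirical
   fraction of days above the threshold. The rule is validated against an
   exact dynamic-programming run-probability oracle and is conservative.
4. The learning day is the first day beginning `r` consecutive qualifying
   days above the threshold.

Probe generalization requires each context's daily probe accuracies to be
significantly above chance (one-sided t test); `per_stimulus_accuracy()`
and `pairwise_subject_correlations()` support the stimulus-level
inter-subject analyses.

```{r}
trials <- make_behavior_sessions(behavior_config(seed = 1))
assess_learning(trials)
probe_performance(trials)
```

## 6. Pipeline and reproducibility

`run_simulate()`, `run_extract()`, `run_classify()`, and `run_behave()`
chain the stages with TSV/CSV/JSON artifacts and a manifest;
`inst/scripts/songsift.R` wraps them for the shell. Every random draw
derives from a root seed through stable string-keyed hashing
(`derive_seed()`), so results are bit-reproducible across runs and
machines, and `scripts/acceptance.R --seed N` regenerates the headline
numbers from scratch.
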