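# songsift

Can subtle differences in how a song is *performed* — rather than what song
it is — be detected, and do they matter to the listener? Male zebra finches
sing the same motif both when courting a female and when alone, and the two
renditions differ only in fine acoustic detail. `songsift` implements a
complete, self-contained workflow for studying that problem:

1. **synthesize** motif waveforms (harmonic-stack syllables) with
   controllable courtship/non-courtship contrasts, plus two-alternative
   forced-choice (2AFC) operant sessions, so that every downstream stage is
   testable with ground truth known by construction;
2. **extract** a bank of ~180 time-series features per motif — temporal
   statistics (autocorrelation shape, automutual information, time
   irreversibility), model-based statistics (AR fits, stationarity,
   forecasting), symbolic dynamics, permutation entropy, spectral summaries
   from several PSD estimators, and a 12-feature spectrogram-based baseline;
3. **normalize** features (finite/variance filter, outlier-robust sigmoid,
   unit scaling);
4. **classify** performance context with bagged decision trees
   (cross-validated accuracy, feature importance, top-k panels, random-panel
   benchmarks, signed confidence scores);
5. **analyze behavior**: sigmoid learning curves, a run-length learning
   criterion, probe-stimulus generalization, and classifier-vs-subject
   coupling.

A centerpiece statistic is waveform *time irreversibility*: the normalized
third moment of lagged differences,

```
co_trev(x, tau) = mean(d^3) / mean(d^2)^1.5,   d = x[t - tau] - x[t]
```

which is zero for any time-reversible signal and is exercised here against
brute-force oracles, exact worked examples, and reversal/palindrome
symmetries:

```r
library(songsift)
co_trev(c(1, 2, 3))        # -1
co_trev(c(1, 2, 1, 2, 1))  #  0
dk_trev(c(1, 2, 3, 4))     # -26
```

## Worked example

Synthesize a small corpus (3 birds, 8 renditions per context), extract and
normalize features, and cross-validate the context classifier:

```r
library(songsift)
cfg <- synth_config(n_birds = 3, renditions_per_context = 8, seed = 7)
dataset <- make_dataset(cfg)
M <- normalize_features(collect_features(dataset, seed = 7))
M
#> <feature_matrix> 48 motifs x 176 features [unit]
#>   birds: 3  contexts: courtship/noncourtship  dropped so far: 6

cv <- kfold_cv(M$values, M$index$context, k = 5, n_iterations = 2, seed = 7)
cv
#> <cv_result> 5-fold x 2 iterations: median accuracy 83.3%
#>   per-iteration: 83.3 83.3
#> confusion (median-accuracy iteration; actual x predicted):
#>               predicted
#> actual         courtship noncourtship
#>   courtship           18            6
#>   noncourtship         2           22

rk <- importance_ranking(train_bgdt(M$values, M$index$context, seed = 7))
head(rk[, c("rank", "feature", "importance")], 5)
#>  rank               feature importance
#>     1   walker_a10_signasym  1.0000000
#>     2             acf_lag33  0.3444249
#>     3             ar_fpe_p7  0.2971858
#>     4             ar_fpe_p5  0.2557041
#>     5 sp_four_hamm_centroid  0.2522596
```

Simulate an operant subject learning the same discrimination and apply the
learning criterion (sigmoid fit, lower 95% bound of the asymptote,
geometric run-length rule) and the probe-generalization test:

```r
trials <- make_behavior_sessions(behavior_config(seed = 7))
assess_learning(trials)
#> <learning_assessment> learned on day 14 (threshold 78.8%, run >= 12 of 30 days)
#>   sigmoid: L=49.1 U=82.2 d0=10.0 s=0.58 (U se 0.43)

pp <- probe_performance(trials)
sprintf("probe %.1f%% vs training %.1f%%, generalized: %s",
        pp$probe_pct_correct, pp$training_pct_correct, pp$generalized)
#> "probe 71.7% vs training 71.7%, generalized: TRUE"
```

At study scale (17 birds, 30 renditions per context, the default moderate
context effects) the combined classifier reaches >80% cross-validated
accuracy, a top-50-feature panel comes within a few points of the full
feature set, and time-irreversibility features rank in the top importance
decile; with all context effects set to zero the same pipeline stays at
chance. These properties are enforced by the acceptance tests (below).
One acceptance assertion is a *known red*: the spectral-spread (PSD IQR)
family, although individually discriminative (per-feature AUC ≈ 0.77),
sits just outside the top importance decile because its impurity credit is
split across twelve strongly correlated estimator variants; the assertion
is kept as written rather than weakened (see the test file comment).

## Command-line pipeline

A thin wrapper around the same functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "songsift.R", package = "songsift"))')" \
  all --seed 7 --out runs/demo
```

Subcommands `simulate`, `extract`, `classify`, `behave`, and `all` read an
optional YAML config (`--config`), write TSV/CSV/JSON artifacts under
`--out`, and exit 2 on configuration errors, 3 on data errors.

## Notes

- All computation is deterministic given the seeds; per-object seeds are
  derived from a root seed, so adding birds or renditions never perturbs
  existing ones.
- The 12-feature spectrogram baseline (`baseline_spectral_features`) is an
  explicitly labeled approximation of the Sound Analysis Pro feature set.
- A methods vignette (`vignettes/birdsong-performance.Rmd`) documents the
  generator model, the feature bank, the normalization chain, the
  classifier protocol, and the learning criterion, including the numerical
  and statistical design choices.
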