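# drowsyTE

Transfer-entropy effective connectivity for drowsy-driving EEG.

`drowsyTE` is an R package for analysts studying how directed
interactions between EEG channels change as a driver's vigilance
declines during a sustained-attention (lane-keeping) task. It links a
behavioral vigilance index derived from reaction times to directed,
model-free information transfer between channel pairs, and ships a
synthetic session generator with known ground truth so every stage can
be validated without access to recorded subject data.

## What it computes

**Driving performance (DP).** Per-trial reaction times are normalized
by the mean of the subject's fastest decile, clipped below at 1, and
mapped through a bounded logistic transform

DP = −(1+e^−0.5)/(1−e^−0.5) + [(2+2e^−0.5)/(1−e^−0.5)] · 1/(1+e^−0.5·nRT),

which equals 1 for an alert response, 2.26 at normalized RT 2.5, 3.11
at 4, and saturates at 4.08 — so minute-long lapses register as
"deeply drowsy" without dominating the statistics. Trials are grouped
as optimal (DP < 2), sub-optimal (2 ≤ DP ≤ 3) and poor (DP > 3).

**Transfer entropy (TE).** For each ordered channel pair, the package
estimates TE(Y → X) = I(x_{t+u}; y-state | x-state) on 1-s
pre-stimulus baseline epochs with a Kraskov-style k-nearest-neighbor
estimator (k = 4, Chebyshev norm, Theiler window 1), with delay
embedding selected by autocorrelation decay and Cao's criterion, the
prediction time scanned over 5–100 ms, and significance from
trial-shuffle surrogates. Granger causality (BIC-selected VAR order)
and FFT band powers (delta/theta/alpha/beta) are computed alongside as
linear and spectral reference measures.

**DP-sorted statistics.** Per-subject TE is baseline-normalized (mean
over the best tenth percentile of DP subtracted), pooled across
subjects, sorted by DP, and averaged in moving windows (width 0.5 DP,
step 0.1, 26 windows over DP 1–4). Each window is tested against the
alert DP 1–1.5 window by Wilcoxon rank-sum with Benjamini–Hochberg FDR
adjustment; performance groups are compared by one-way
repeated-measures ANOVA and pairwise signed-rank tests.

## Worked example

Simulate a small study in which the Cz→Pz coupling follows an
inverted-U over DP (peaking at DP 2.5) and Pz→Oz declines
monotonically, then run the full pipeline:

```r
library(drowsyTE)

truths <- list(
  coupling_truth("Cz", "Pz", lag = 2, shape = "inverted_u", peak_dp = 2.5),
  coupling_truth("Pz", "Oz", lag = 2, shape = "monotone_decreasing")
)
study <- simulate_study(n_subjects = 4, n_trials = 250, truths, seed = 20)
fit <- dp_connectivity(lapply(study, `[[`, "session"),
                       pairs = list(c("Cz", "Pz"), c("Pz", "Oz")),
                       config = pipeline_config())
print(fit)
```

```
DP-sorted connectivity analysis: 4 subject(s), 1000 trial(s), 2 pair(s)
  DP windows: width 0.50 step 0.10 over [1, 4]; FDR family: per_pair
  Cz->Pz     peak relative TE at DP 2.55; 16/26 windows significant
  Pz->Oz     peak relative TE at DP 1.25; 21/26 windows significant
```

```r
summary(fit)
```

```
    pair peak_center n_sig_windows  anova_F      anova_p p_opt_vs_sub p_sub_vs_poor p_opt_vs_poor
1 Cz->Pz        2.55            16 519.4530 1.893311e-07       0.1875        0.1875         1.000
2 Pz->Oz        1.25            21 209.9137 2.797388e-06       0.1250        0.1250         0.125
```

Reading the output: the planted inverted-U pair peaks at window center
DP 2.55 (truth: 2.5) with the elevation over the alert window
FDR-significant; the occipital-like pair is maximal in the most alert
window and declines across DP. The ANOVA detects the group effect for
both pairs; with only 4 subjects the exact signed-rank contrasts
cannot go below p = 0.125 (= 2/2^4), which is why group contrasts are
reported on 12-subject studies. `plot(fit, "Cz->Pz")` draws the
profile with the significant windows emphasized and the
Granger-causality trace overlaid when computed.

Lower-level entry points mirror the analysis stages:
`gen_coupled_pair()` / `gen_nonlinear_pair()` (estimator fixtures),
`bandpass_zero_phase()`, `downsample()`, `extract_baseline_epochs()`,
`time_shift_test()`, `normalize_rts()`, `dp_transform()`, `ksg_te()`,
`surrogate_test()`, `granger()`, `band_power()`,
`dp_window_profile()`, `rm_anova()`, `pairwise_signed_rank()`, and
`run_pipeline()` which writes tidy CSV artifacts plus a JSON manifest.

## Vignette

`vignettes/drowsyTE-methods.Rmd` documents the models and their
assumptions, every tunable parameter with its default and rationale,
what the synthetic generator does and does not emulate, and the
package's numerical conventions.
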