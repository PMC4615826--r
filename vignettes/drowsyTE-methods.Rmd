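---
title: "Methods: DP-sorted transfer-entropy connectivity for drowsy-driving EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DP-sorted transfer-entropy connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

During a long, monotonous drive, vigilance drifts from alertness into
drowsiness, and reaction times to lane-departure events stretch from
under a second to tens or hundreds of seconds. This package implements
an analysis that links that behavioral drift to *directed* interactions
between EEG channels: how much information each channel's recent past
transfers to another channel's immediate future, over and above what
the receiving channel already "knows" about itself. The analysis has
four stages: a behavioral vigilance index, signal conditioning,
directed connectivity estimation, and a nonparametric statistical
surface that relates the two.

# The driving-performance index

Reaction times (RTs) are heavy-tailed: an alert response takes well
under a second, a drowsy lapse can take minutes. Raw RTs are therefore
first normalized per subject by the mean of the fastest decile
(the `ceiling(0.1 N)` smallest RTs), and clipped from below at 1 — a
response faster than the subject's own alert baseline carries no extra
information about vigilance. The normalized RT is then mapped through a
bounded logistic transform:

$$
\mathrm{DP} = -\frac{1+e^{-0.5}}{1-e^{-0.5}}
  + \frac{2+2e^{-0.5}}{1-e^{-0.5}}\cdot
    \frac{1}{1+e^{-0.5\,\mathrm{nRT}}}
$$

The transform is exactly 1 at normalized RT 1, nearly linear up to 2.5
(DP 2.26), reaches 3.11 at 4, and saturates at 4.083 as RT grows
without bound, so a 300-second lapse and a 30-second lapse both read as
"deeply drowsy" rather than dominating every summary statistic. We keep
the full-precision value rather than capping at 4.00; display rounding
is left to the caller. Trials are grouped as *optimal* (DP < 2),
*sub-optimal* (2 ≤ DP ≤ 3) and *poor* (DP > 3), with both boundaries
assigned to the middle group.

The transform count rule for the fastest decile uses the ceiling so the
denominator set is never empty; ties break by ascending trial index.

# Signal conditioning

Continuous records are band-passed 1–50 Hz with a windowed-sinc
(Hamming) FIR filter applied forward and backward, so the net group
delay is zero and in-band phase is untouched. The default order follows
the common EEG-toolbox heuristic of `3 * fs / low_cut` taps (rounded to
even); any design meeting the attenuation contract — at least 40 dB of
two-pass attenuation at half the low cut and 1.5 times the high cut —
is acceptable, and `bandpass_response()` lets users check a custom
order. Edges are stabilized by odd reflection padding; a localized
transient of roughly the filter length remains possible at the record
boundaries, which is why the synthetic generator leaves a 2-s tail
after the last trial and why epochs are never taken from the first
seconds of a record.

Records are then decimated by an integer factor (500 → 250 Hz by
default; the signal is already low-passed far below the new Nyquist),
and a 1-s baseline epoch is cut per trial as the half-open window
`[onset − 1 s, onset)`: the epoch ends one sample before the deviation
onset and never reads stimulus-driven samples. Trials too close to the
start of the record are dropped with a warning, never silently.

Before connectivity is interpreted, an ordered channel pair can be
screened for instantaneous mixing (volume conduction) with the
time-shift test: if shifting the source one sample toward the future
*increases* the estimated transfer entropy, the dependence is
simultaneous rather than lagged, and the pair is flagged. Significance
comes from a one-sided sign-flip permutation over trials at
$\alpha = 0.05$; the shift is one sample. On the artifact-free
synthetic sessions the screen is expected to pass all pairs.

# Transfer entropy

For sink $X$ and source $Y$, past states are delay-embedded,
$\mathbf{x}^d_t = (x_t, x_{t-\tau},\dots,x_{t-(d-1)\tau})$, and the
transfer entropy is the conditional mutual information

$$
\mathrm{TE}(Y \to X) = I\!\left(x_{t+u};\, \mathbf{y}^m_t \,\middle|\,
\mathbf{x}^d_t\right),
$$

estimated by Kraskov-style k-nearest-neighbor counting (algorithm-1
counts, Chebyshev norm, one combined neighbor search) rather than as a
difference of four separately estimated entropies — the shared
neighborhood radius cancels most of the individual biases. Defaults:
$k = 4$ neighbors; Theiler window $T = 1$ sample, excluding temporally
adjacent state vectors from every neighbor search; natural logs
internally with results reported in bits. Inputs are z-scored per
trial, which makes the estimate exactly invariant to separate affine
rescaling of source and sink and puts pooled trials on one amplitude
scale. A deterministic, sub-numerical-precision dither breaks distance
ties so repeated values cannot produce degenerate neighborhoods.

Parameter selection policies, where the analysis is run data-driven:

* the embedding delay $\tau$ is the first lag at which the sample
  autocorrelation drops below $1/e$. The literature's dimension
  criterion (Cao's) is sometimes loosely credited with delay selection
  too; we deliberately split the roles — autocorrelation decay for
  $\tau$, Cao's $E_1$ saturation for the dimension — and document that
  as an interpretation;
* dimensions $d$ and $m$ are selected per series as the smallest
  dimension at which Cao's $E_1(d)$ saturates within tolerance 0.05
  (plus one, per Cao's rule), capped at `d_max`; Cao's $E_2$ is exposed
  for distinguishing deterministic from stochastic series;
* the prediction time $u$ is scanned over {5, 10, 20, 40, 60, 80,
  100} ms and the value maximizing TE is kept, ties to the smallest.
  Milliseconds convert to samples by round-half-up with a floor of one
  sample, so 5 ms at 250 Hz is 1 sample. A stated prediction time of
  "5" is read as 5 ms (the scanning set is in ms); users who mean 5
  samples can set `u` directly.

Pipeline defaults use a fixed spec ($d = m = 2$, $\tau = 1$, $u = 1$
sample, $k = 4$, $T = 1$): on 250-sample epochs, per-trial data-driven
selection is unstable and slow, and a low-order embedding maximizes
sensitivity to the epoch-level coupling changes the profile analysis
targets. `embedding = "auto"` enables the data-driven path (resolved
per subject and pair on pooled baselines).

Per-trial estimation on 250 samples is deliberately supported but
small-sample biased; the bias largely cancels in the within-subject
baseline normalization and in the rank-based window tests, and a pooled
mode (state vectors concatenated across trials, with neighbor searches
masked at trial boundaries) is available where a single more stable
estimate per condition is wanted.

Significance of a TE value uses surrogates that destroy the
source–sink temporal relationship while preserving each series'
autocorrelation: trial shuffling of the source when trials are
available, circular shifting otherwise, with
$p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(1 + n_\mathrm{perm})$.
When only the accept/reject decision at a known level matters, the
optional Besag–Clifford sequential stopping rule (`alpha_stop`) halts
surrogate generation as soon as rejection has become impossible; the
decision is provably identical to the full run and the cost on null
pairs drops by an order of magnitude.

# Reference measures

Granger causality is the linear benchmark:
$\mathrm{GC} = \ln(\sigma^2_\mathrm{restricted}/\sigma^2_\mathrm{full})$
from least-squares fits of the sink on its own lags without/with the
source's lags, with the order chosen by BIC over a bivariate VAR. On
linear-Gaussian data TE (nats) converges to GC/2, which the test suite
uses as an exact oracle; on quadratically coupled data GC is blind
while TE is not, which is the point of using a model-free measure.

Significance of GC is available in two flavors. The classical nested-F
test is exact under a correctly specified linear model, but when the
true coupling is nonlinear the omitted term leaves residuals that are
heteroskedastic and serially dependent, and the classical test then
rejects far too often even though the population linear-projection
coefficients — and hence the population GC — are zero. `granger(...,
robust = TRUE)` therefore offers a HAC (Newey–West, Bartlett kernel)
Wald test of the source-lag coefficients, which stays at its nominal
size in that regime; the truncation lag defaults to the usual
$4(n/100)^{2/9}$ rule. The validation suite uses the robust test
wherever the data are nonlinearly coupled by construction.

Spectral context comes from one-sided rectangular-taper periodograms of
the 1-s epochs (1 Hz bins), summed over delta 1–4, theta 5–7, alpha
8–12 and beta 13–20 Hz inclusive — the band definitions are disjoint,
so the 4 Hz bin is delta's and the 5 Hz bin theta's. Band power is
correlated with DP by Pearson's r, on log10 power by default (a
config switch restores linear power; log power is the conventional
scale for EEG amplitude statistics).

# The statistical surface

Per subject and pair, trial TE values are re-expressed relative to the
subject's own alert state: the mean TE over the best tenth percentile
of DP is subtracted. Relative values from all subjects are pooled,
sorted by DP, and averaged in overlapping windows 0.5 DP wide stepped
by 0.1 from DP 1 to 4 — 26 windows, the first spanning DP 1–1.5.
Each window is compared with the first by a two-sided Wilcoxon
rank-sum test; Benjamini–Hochberg adjustment is applied across the 26
windows *within* each ordered pair (the family definition is a config
option, `per_pair` or `global`; the per-cell display of the profile
grid motivates the default), and windows with adjusted p < 0.001 are
drawn bold. Overlapping windows reuse trials across tests by
construction; this is documented, not "corrected", since the profile
is descriptive and each window's test is against the same fixed
reference.

Group analysis averages relative TE per subject within the three
performance groups, then runs a one-way repeated-measures ANOVA
(sphericity assumed; subjects missing any group are dropped listwise
with a warning) and the three pairwise Wilcoxon signed-rank tests with
BH adjustment across the three contrasts (pairwise deletion).
Degenerate inputs follow explicit conventions: a zero error mean
square reports p = 1 with a warning, as do all-zero signed-rank
differences; windows with fewer than two members carry a missing
p-value.

# The synthetic-data generator

No recorded data ship with the package, so validation rests on a
generator whose ground truth is known exactly.

* **Behavior.** Latent vigilance $v \in [0,1]$ follows a configurable
  trajectory (default: smooth decline from 1 to 0.05 over the session,
  exponent 1.2). RT = $\exp(\log 0.75 + 2.1(1-v) + \sigma z)$ with
  $\sigma = 0.2$, giving alert medians near 0.75 s and drowsy medians
  near 6 s; with probability $0.15(1-v)^2$ a trial is a lapse with RT
  uniform in 10–300 s, reproducing the extreme right tail that
  motivates the bounded DP transform. The generator's "true" DP is
  computed from these RTs through the behavior module itself, so there
  is exactly one DP definition in the package.
* **Timeline.** Trials are separated by inter-trial intervals uniform
  in 5–10 s at a 500 Hz generation rate; the continuous record stores
  at most 6 s of post-onset signal per trial (lapses advance the
  clock; only the 1-s pre-onset baseline is analyzed, and the full RT
  is kept in the behavior table), plus a 2-s tail.
* **Spectra.** Each channel mixes four unit-variance band-limited
  noise sources (4th-order Butterworth bands) with vigilance-dependent
  weights — delta $0.5 + 1.5(1-v)$, theta $0.6 + 0.8(1-v)$, alpha
  $1.5 - 1.1(1-v)$, beta $1.0 - 0.6(1-v)$ — plus broadband noise at
  0.3. The signs reproduce the canonical drowsiness pattern (slow
  power up, fast power down); the spectral contract is asserted on the
  weights themselves, with FFT-level correlations checked at the
  pipeline level.
* **Couplings.** Each declared coupling adds a dedicated *broadband*
  (4–40 Hz) source, amplitude 2, to its source channel, and mixes it
  into the sink `lag` samples later scaled by `strength_profile(DP)`
  evaluated at each trial's DP. Broadband matters: a narrowband
  oscillation is almost perfectly predictable from the sink's own
  past, so however strongly it is mixed it transfers nearly no
  *conditional* information — an instructive failure mode we hit and
  document here. Profiles are `constant`, `inverted_u` (Gaussian bump,
  default peak DP 2.5, width 0.5) and `monotone_decreasing` (linear
  decline to 10% at DP 4). The quantitative coupling magnitudes are
  free parameters of the generator — connectivity profiles in this
  setting are meaningful only relative to each subject's alert
  baseline — so recovery tests are qualitative (shape and direction),
  not magnitude-matched.
* **Determinism.** All randomness flows from one seed per session;
  stage seeds in the pipeline derive deterministically from the run
  seed, so identical configurations reproduce results bit for bit.

What the generator does *not* emulate: eye-blink/EMG artifacts, volume
conduction and reference-electrode geometry, non-stationary noise, and
1/f background structure. Passing tests therefore demonstrate that the
estimators and statistics behave correctly on signals with the stated
spectral and coupling structure — not that real scalp EEG meets those
assumptions.

# Problem sizes and numerical choices

The validation suite runs at sizes chosen to exercise asymptotic
behavior while staying desk-scale: estimator oracles at $10^3$–$10^5$
samples, surrogate calibration on 200 pairs of 4096 samples with 100
permutations each, and a full pipeline recovery study of 12 simulated
subjects with 250 trials each on the two planted pairs. Tie-breaks are
everywhere deterministic (dither for neighbor searches, smallest-u for
prediction-time ties, ascending trial index for decile ties).
Estimates may be slightly negative on finite data although the
population quantities are non-negative; no truncation at zero is
applied anywhere, so averages remain unbiased.

# Known limitations

Bivariate TE only (no conditioning on third channels); no ensemble
estimator for non-stationarity; sensor-space interpretation is limited
by volume conduction in real recordings (the time-shift screen flags
only the instantaneous part); per-epoch estimates at 250 samples are
noisy by design and should be interpreted through the pooled profiles,
not individually. A weak reverse-direction TE on strongly mixed pairs
is genuine (the sink's past helps denoise the shared source) and is
why direction claims rest on the *difference* between the two ordered
directions, not on a zero reverse value.
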