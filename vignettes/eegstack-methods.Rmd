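---
title: "Methods: region-wise EEG features and stacking-ensemble depression detection"
author: "eegstack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: region-wise EEG features and stacking-ensemble depression detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis problem

Resting-state EEG carries group-level signatures of major depressive
disorder (MDD): relative to healthy controls (HC), depressed patients tend
to show shifted relative power in the theta, alpha, beta and gamma bands,
with the temporal scalp regions among the most discriminative. `eegstack`
implements a complete, testable detection pipeline around this phenomenon:

1. **Cohort** — multichannel resting EEG (19 channels in the 10–20 montage,
   256 Hz), either simulated by the package's generator or read from disk
   (EDF or array bundles).
2. **Preprocessing** — common average reference; zero-phase FIR band-pass
   0.5–50 Hz plus a 49–51 Hz FIR notch; ICA-based suppression of
   components correlated with a frontal (Fp1/Fp2) blink proxy.
3. **Segmentation** — crop to 30–155 s, cut 32 s epochs with 1 s overlap
   (exactly 4 per subject at the default geometry), and reject epochs with
   any channel above 100 µV absolute amplitude or below 1 µV peak-to-peak.
4. **Features** — 19 features per scalp region × 5 regions = 95 columns.
5. **Selection** — per-feature two-group tests routed by normality and
   variance-homogeneity gates, Bonferroni-adjusted.
6. **Classification** — a stacking ensemble (kNN + decision tree + gradient
   boosting bases, decision-tree meta-learner, original-feature
   passthrough) under subject-grouped stratified 5-fold cross-validation,
   next to seven single-model baselines.
7. **Reports** — per-region ablation ranking and relative band-power group
   statistics.

## The feature schema

Per region the schema comprises 9 spectral, 3 temporal, 5 nonlinear and 2
time-frequency features (45/15/25/10 over the five regions):

* **Spectral** — spectral centroid and peak frequency; absolute Simpson-
  integrated band powers for delta (0.5–4 Hz), theta (4–8), alpha (8–13),
  beta1 (13–21), beta2 (21–30), gamma (30–48); total power. The PSD is a
  single full-range Welch estimate (4 s Hann segments, 50% overlap,
  window-power normalization), shared by all bands so that relative powers
  are mutually consistent. Band integration uses composite Simpson's rule
  on the PSD grid. An alternative band preset (`bandScheme("table2")`,
  delta 1–3 Hz etc.) ships for comparison but is not the default.
* **Temporal** — skewness, excess kurtosis (Fisher convention), peak
  absolute amplitude.
* **Nonlinear** — sample entropy (`m = 2`, `r = 0.2 × SD`, Chebyshev
  distance with matches at `d ≤ r`, self-matches excluded); Higuchi
  fractal dimension (`kmax = 10`, least-squares slope of
  `log L(k)` vs `log k`, clipped to [1, 2]); Hurst exponent by rescaled
  range over dyadic window sizes, windows anchored from both ends of the
  series so the estimate is invariant under time reversal; Shannon entropy
  of the amplitude histogram (128 equal-width bins on [min, max]); C0
  complexity, by default the maximum single-sided normalized FFT amplitude
  (a "standard" spectral-irregularity mode is also provided — the two
  definitions differ in the literature, so both are exposed and the choice
  is a parameter).
* **Time-frequency** — mean and maximum of the magnitude-squared STFT
  (1 s Hann windows, 50% overlap).

Features are computed **per channel and then averaged over each region's
channels**. The alternative — features of the region-averaged signal — is
not equivalent for nonlinear features and is sensitive to channel polarity;
per-channel averaging is the more robust convention and is fixed here.

Region aggregation uses the five-region partition of the 19-channel
montage: Frontal (Fp1, Fp2, F3, F4), Left Temporal (F7, T3, T5),
Parietal–Occipital (P3, P4, O1, O2), Right Temporal (F8, T4, T6), Central
(C3, C4, Fz, Cz, Pz).

### Numerical choices and degenerate inputs

* Sample entropy: `B = 0` (no length-`m` matches) returns `Inf`; `A = 0`
  with `B > 0` returns the finite cap `ln B + ln(N − m)` with a saturation
  flag, so downstream feature matrices stay finite.
* Constant series: sample entropy 0, Shannon entropy 0, Higuchi dimension
  1, Hurst 0.5, skewness/kurtosis 0 — all flagged degenerate.
* Spectral peak ties break toward the lowest frequency.
* Quartiles in the band-power report use linear interpolation (R type 7).

## The synthetic cohort generator

Each channel is the sum of: six band-limited Gaussian noise carriers (FFT
masking with 0.5 Hz raised-cosine edges; filtered noise rather than pure
tones, so spectra are band-shaped and the nonlinear features are
non-degenerate), a `1/f` background (default exponent 1, RMS 6 µV), frontal
blink transients (Hann-shaped pulses of 0.3–2 s and 80–150 µV on Fp1/Fp2,
scaled 0.3 on F3/F4 and 0.05 elsewhere; default 12/min), and a common-phase
50 Hz mains sinusoid (default 5 µV). Default per-band carrier RMS
amplitudes are delta 8, theta 5, alpha 10, beta1 4, beta2 3, gamma 2 µV —
chosen so that a typical epoch peaks well under the 100 µV rejection
threshold while keeping all bands spectrally visible.

Group effects are **multiplicative on band amplitude** (hence approximately
squared on power) and can be restricted to a set of regions. The default
effect map encodes relatively higher theta/alpha/beta and lower gamma power
in the MDD group (factors 1.2/1.2/1.15/1.15/0.85), the direction used
throughout the resting-state depression literature this package models; the
literature is not unanimous on the alpha direction, so the factor is a
plain parameter. Default cohort counts are 34 MDD / 30 HC and recordings
are 160 s, long enough for the standard 30–155 s crop.

What the generator does **not** emulate: volume-conduction correlation
between channels, non-stationarity across the recording, EMG/ECG
artifacts, subject-level heterogeneity of spectral shape. Passing tests on
synthetic cohorts therefore demonstrates the pipeline's statistical
correctness (error control, effect recovery, absence of leakage), not
clinical performance on real EEG.

## Preprocessing decisions

The FIR band-pass is a Hamming-window design with a 0.5 Hz transition at
the low edge (order ≈ 3.3·fs/Δf, forced even), applied with exact
group-delay compensation — linear phase makes "zero phase" a sample shift.
The notch is a 49–51 Hz FIR band-stop of the same design. Both are applied
by FFT convolution.

Artifact removal uses symmetric FastICA (tanh contrast) with component
count equal to the numerical rank of the channel covariance (average
referencing removes one dimension). The only removal criterion is the
absolute correlation of a component's time course with the frontal proxy —
the mean of Fp1 and Fp2 *before* decomposition — at the default threshold
0.7. On synthetic data most sources are Gaussian band noise, whose ICA
rotation is indeterminate; the symmetric iteration therefore may not meet
its convergence tolerance even though the non-Gaussian blink component is
stable. The decomposition records its convergence state in the report
rather than failing, and is deterministic given the seed.

## Feature selection

For each feature the two groups are compared with either a one-way
two-group ANOVA (equivalent to the pooled t-test) or a two-sided
Mann–Whitney U test. The parametric branch requires Shapiro–Wilk normality
in **both** groups *and* Levene homogeneity of variance (median-centered,
i.e. Brown–Forsythe), all at gate level 0.05. Raw p-values are
Bonferroni-adjusted over the full feature family (`min(1, m·p)`); a
Benjamini–Hochberg mode exists but is off by default because family-wise
control is the stated protocol. Selection operates on epoch-level rows by
default, treating each epoch as a sample; a subject-mean mode mitigates the
pseudo-replication this entails. With `alpha = 1` selection is vacuous and
keeps everything (adjusted p-values are capped at exactly 1).

## Classification

Baselines: decision tree (depth 20, min split 10), kNN (k = 5,
distance-weighted), random forest (200 trees), RBF SVM (C = 1, gamma =
1/p), XGBoost (lr 0.05, 1000 rounds), gradient boosting (lr 0.1, 200
rounds), and a single-hidden-layer perceptron (50 units, 1000 iterations;
deeper multilayer topologies are outside the scope of the backing
implementation). The kNN scorer is internal because no installed
implementation exposes distance-weighted class probabilities; SVM scores
are decision values mapped through a logistic link, which keeps ranking
and labels intact while avoiding the non-deterministic internal
cross-validation of Platt scaling. An LGBM learner kind is part of the
registry surface and errors informatively when its backing package is
absent.

The stacking ensemble fits kNN (k = 5), a depth-5 decision tree and
gradient boosting (lr 0.01, depth 3, 100 rounds) as bases. Meta-features
are the bases' **out-of-fold positive-class probabilities** (5 internal
stratified folds — refitting on the full training set and predicting it
would leak), concatenated with the original feature columns
("passthrough", default on). The meta-learner is a depth-5 decision tree.
Probabilities rather than hard labels are used as meta-features because
they are strictly more informative.

Cross-validation is stratified 5-fold and **subject-grouped by default**:
all epochs of a subject share a fold, so the reported performance cannot
profit from within-subject leakage. Epoch-level grouping is available for
comparison; on synthetic strong-effect cohorts the gap between the two is
small, but on real data epoch-level CV can be badly optimistic. Accuracy,
recall and F1 are computed from pooled fold confusion counts; AUC is
reported both from pooled scores and as the mean of per-fold AUCs.

## Region ablation and band report

Ablation restricts the table to one region's 19 columns, reruns selection
inside the subset (Bonferroni family = 19), cross-validates the stacking
ensemble on the survivors (falling back, flagged, to the raw columns if
nothing survives), and ranks regions by accuracy. The band report
summarizes relative band power (band power / regional total power) per
region × band × group as median/quartiles/outliers with a Mann–Whitney
annotation, and renders grouped box plots.

## Problem sizes used in the shipped checks

The package's own test suite runs its Monte-Carlo checks (family-wise
error under a null effect map, recovery of a Left-Temporal alpha effect,
ensemble no-harm, permutation nulls) on scaled-down cohorts — 5 + 5
subjects, 16 s recordings, 4 s epochs — which preserve the full montage,
the 95-column schema and the effect structure while keeping replicate
counts affordable; these sizes are a deliberate design choice for the
simulation studies. Count-sensitive checks (the 4-epochs-per-subject
geometry, the 95-column decomposition) and the acceptance script use the
full 160 s / 32 s geometry.

## Known limitations

* The generator's channels are statistically independent apart from the
  blink and mains components; ICA on such data separates the blink well
  but real EEG mixing is denser.
* R/S Hurst estimation carries its known small-sample upward bias for
  white noise (≈ 0.55 at N = 8192); no bias correction is applied.
* The `rf` baseline approximates a depth limit via `maxnodes` because its
  backing implementation has no depth parameter.
* Subject-grouped CV with few subjects per class produces coarse-grained
  fold metrics; the reported pooled metrics remain exact but fold-level
  variance is high.
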