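---
title: "Complexity-feature EEG classification of dementia subtypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complexity-feature EEG classification of dementia subtypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegdem)
```

## The problem

Alzheimer's disease (AD) and frontotemporal dementia (FTD) alter the
statistical structure of resting-state EEG: AD is associated with a global
slowing of the spectrum (more delta/theta power, less alpha), FTD with a
slowing concentrated over frontal electrodes. `eegdem` implements a
window-based pipeline that turns 19-channel, 500 Hz recordings into
per-window complexity features and evaluates how well simple supervised
learners discriminate the three groups (AD, FTD, healthy controls — HC) in
three binary tasks, while guarding strictly against subject-level
information leaking from training into test data.

The pipeline is: segment → extract → split (by subject) → balance (SMOTE,
training rows only) → train → evaluate → channel importance → scalp topomap.

## Windowing

Recordings are cut into 1 s windows (500 samples at 500 Hz) with a
configurable overlap fraction; the two study settings are 50% (step 250
samples) and 90% (step 50 samples). Windows are sample-aligned, 0-based and
half-open, the step is `round(w * (1 - overlap))`, and the trailing
remainder is discarded so every window has exactly `w` samples. The window
count is `floor((N - w)/step) + 1`. For the study settings the step is
exact, so rounding only matters for non-standard configurations.

## The five complexity measures

All five are implemented from their defining formulas and applied per
channel per window, giving a feature table with one row per window and one
column per channel.

**SVD entropy.** The window is delay-embedded (order $M = 3$, lag 1) into a
matrix whose rows are lagged vectors; with normalised singular values
$\bar\sigma_i$ the feature is
$H_{SVD} = -\sum_{i=1}^{M} \bar\sigma_i \log_2 \bar\sigma_i \in [0, \log_2 M]$.
It is 0 for a constant window and approaches $\log_2 3 \approx 1.585$ for
broadband noise. The entropy is deliberately *not* normalised by
$\log_2 M$. Singular values below $10^{-7}$ of the largest are treated as
rank noise and zeroed, which is what makes the constant-window case exactly
0 in floating point.

**Higuchi fractal dimension.** For interval length $k \le k_{max} = 10$ and
start $m \le k$, the subsampled curve length is
$L_m(k) = \frac{N-1}{\lfloor (N-m)/k \rfloor\, k}\cdot\frac{1}{k}
\sum_i |x(m+ik) - x(m+(i-1)k)|$; lengths are averaged over $m$ and the
dimension is the slope of $\ln L(k)$ on $\ln(1/k)$ (unweighted least
squares over all $k$). A straight line gives 1, white noise 2, a Brownian
path 1.5; these limits are asserted in the tests. A constant window returns
1 by definition.

**Zero-crossing rate.** The fraction of adjacent pairs with
$s_t s_{t-1} < 0$. The inequality is strict, so sample pairs containing an
exact zero do not count; the measure is therefore sensitive to sampling
phase for signals that touch zero exactly, which is documented behaviour
rather than a defect.

**DFA.** The mean-centred window is integrated; for each of ~12 log-spaced
box sizes $n \in [4, w/4]$ the profile is split into non-overlapping boxes
(partial trailing box discarded), a first-order polynomial is removed per
box, and $F(n)$ is the RMS residual. The exponent $\alpha$ is the slope of
$\log F(n)$ on $\log n$ (0.5 for white noise, 1.5 for Brownian motion). If
any $F(n) = 0$ — a polynomial signal — the function refuses and names the
degenerate scale.

**Hjorth parameters.** Activity = var(x) (µV²); mobility =
$\sqrt{\mathrm{var}(\Delta x)/\mathrm{var}(x)}$ with $\Delta$ the first
difference (per-sample, no sampling-rate scaling, hence dimensionless);
complexity = mobility of $\Delta x$ over mobility of $x$. Because the
feature table needs one column per channel, the Hjorth feature is the
arithmetic mean of mobility and complexity; activity is excluded from the
scalar because it is the only quantity carrying physical units (and is not
gain-invariant). Both raw parameters remain available via `hjorth()`.

All measures except Hjorth activity are invariant under positive rescaling
of the signal, which the property tests assert; activity scales as the gain
squared.

## Subject-disjoint evaluation

The split operates on subjects, never on windows: ~20% of subjects per
group are held out for test (rounding ties resolved toward the larger
training set) and the training subjects are dealt round-robin per group
into 15 cross-validation folds, so each fold's validation set is a held-out
subject subset. SMOTE (k = 5 neighbours, convex interpolation between a
minority row and one of its k nearest minority neighbours) is applied only
to training rows — inside each CV fold, only to that fold's training part —
and synthetic rows carry the sentinel subject id `"SMOTE"` so they can
never reach a validation or test set. Test windows are never resampled.
With 16 training subjects and 15 folds most validation sets contain one
subject and hence often a single class; fold metrics that are undefined for
such folds are reported as `NA` and excluded from fold means.

## Learners and hyperparameters

Four learners with fixed hyperparameters are evaluated. KNN (k = 6,
Euclidean, uniform weights) is implemented natively; since k is even, 3–3
vote ties are broken toward the class of the single nearest neighbour,
which is deterministic and local. The positive-class score is the fraction
of positive neighbours. Random Forest (120 trees, gini, min 28 samples to
split, min 10 per leaf) and Extra Trees (150 trees, gini, no bootstrap,
random split points, min 30 to split, min 15 per leaf) are backed by
`ranger`, whose `min.node.size`/`min.bucket` express the split/leaf minima;
XGBoost (eta 0.1, 280 rounds, depth 8, colsample 1, L1 alpha 0.05) is
backed by `xgboost`. All runs are single-threaded and seeded, so every
result is exactly reproducible.

Metrics are computed from the confusion counts: sensitivity TP/(TP+FN),
precision TP/(TP+FP), accuracy (TP+TN)/total, F1 as the harmonic mean of
precision and sensitivity, each reported as `NA` (undefined) when its
denominator is zero rather than coerced to 0. AUC is the Mann–Whitney
pairwise-ranking probability with midpoint tie handling, which equals the
trapezoidal area under the ROC curve; the test suite checks it against an
exhaustive O(n²) oracle to 1e-12.

## Channel importance and topomaps

For tree ensembles, impurity importances are mapped to channels and
normalised to sum 1; for score-only models a permutation importance (mean
metric drop under per-channel shuffling, negatives clipped) is provided.
Scores are interpolated over the unit head disc with a thin-plate-spline
radial basis ($r^2 \log r$ kernel plus affine term), which is exact at the
electrodes; the paper-style figure draws the head outline, electrodes and
colour scale. Electrode coordinates are a fixed azimuthal-equidistant
layout of the 19-channel 10–20 montage built into the package, so no
external montage file is needed. Score ties in rankings are broken by
montage order.

## The synthetic cohort generator

Real recordings of this kind cannot ship with a package, so the generator
produces labelled 19-channel recordings carrying the statistical structure
the pipeline assumes. Each channel is the sum of:

* a $1/f$ background (exponent 1.0, the canonical resting spectrum), RMS 6 µV;
* narrowband-filtered Gaussian oscillations in delta (0.5–4 Hz, 6 µV),
  theta (4–8, 4 µV), alpha (8–12, 9 µV) and beta (12–30 Hz, 3 µV), with
  alpha posterior-weighted (eyes-closed topography);
* white sensor noise, RMS 1.5 µV.

Oscillations are filtered noise rather than sinusoids because pure tones
make several complexity measures degenerate across windows. Group effects
multiply band amplitudes: AD ×1.8 delta/theta globally with alpha ×0.6; FTD
×1.6 delta/theta with a smooth frontal weighting (quadratic in the
electrode's frontality); HC is baseline. A per-subject ±10% gain jitter
correlates windows within a subject, which is what makes the
subject-leakage tests meaningful. Every sample is a deterministic function
of (cohort seed, group, subject index). Default recording length is 60 s —
long enough for stable window statistics at both overlaps while keeping a
30-subject study under two minutes of feature extraction on one CPU.

What the generator does **not** emulate: volume conduction and inter-channel
correlation, artefacts (ocular, muscular — the reference dataset was
artefact-cleaned upstream), non-stationarity over minutes, within-group
clinical heterogeneity, and any quantitative claim about real AD/FTD
spectra — the effect sizes are pipeline-testing devices chosen to make the
three tasks learnable but not trivial. Passing tests therefore demonstrate
the pipeline's correctness and leakage-safety, not clinical performance.

## Numerical and degenerate-input choices

* EDF output is 16-bit with a declared ±800 µV physical range (~0.024 µV
  quantisation step); out-of-range samples are clipped; round-trip equality
  is asserted to 0.05 µV.
* The band-pass option is implemented as cascaded zero-phase Butterworth
  sections — high-pass order 4 at 0.5 Hz, low-pass order 6 at 45 Hz —
  because a single high-order band-pass transfer function with a 0.5 Hz
  edge at 500 Hz sampling is numerically unstable, and a 4th-order
  prototype would leave ~8% of a 60 Hz mains component where the package
  contracts < 5% RMS. It is off by default for synthetic cohorts (already
  band-limited) and on for BIDS input.
* Constant windows: SVD entropy 0, Higuchi 1, ZCR 0 by definition; Hjorth
  and DFA refuse with informative errors (mobility undefined, zero
  fluctuation). Windows failing extraction on any channel are dropped with
  a reported count.
* `make_split` refuses degenerate splits where a group would be absent from
  train or test.

## Problem sizes in the test suite

The packaged tests run the full pipeline at deliberately desk-friendly
sizes: unit fixtures use 3–12 subjects with 4–10 s recordings; the
qualitative reproduction uses 10 subjects per group, 60 s recordings, five
split seeds and both overlaps (~21 000 windows through SVD entropy); the
analytic feature limits use 50 seeded replicates each. These sizes give
stable means (seed-to-seed accuracy sd ≈ 0.01) and are stated here as the
package's chosen experiment scale.

## Known limitations

* With the default synthetic conditions, mean test accuracy of the SVD/KNN
  configuration at 90% overlap is not above its 50% counterpart — the two
  differ by about one seed-standard-deviation, with 50% slightly ahead.
  The 50%-overlap windows are a subset of the 90% ones, so higher overlap
  only adds near-duplicate training windows; for a memory-based learner the
  denser same-subject duplicates dominate neighbourhoods without adding
  cross-subject information. An overlap benefit of the kind reported on
  clinical data is therefore not an intrinsic property of the method but a
  dataset-dependent one, and the synthetic cohort does not reproduce it.
* The 15-fold subject-wise CV yields single-subject validation folds at
  small cohort sizes, making per-fold AUC frequently undefined; fold means
  skip undefined entries.
* KNN distances are computed on raw feature scales (all five measures are
  dimensionless and of comparable magnitude; no standardisation is
  applied).
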