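---
title: "Microstate segmentation and developmental trajectory modelling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate segmentation and developmental trajectory modelling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures `microdev` implements, the
assumptions behind them, the numerical choices that were genuinely open, and
what validation on synthetic data does and does not establish.

## The microstate model

The working assumption of microstate analysis is that the average-referenced
scalp field at any instant is, up to noise, a scalar multiple of one of a
small number of fixed topographies ("maps"), and that the active map switches
on a ~60–120 ms timescale. Because cortical generators reverse polarity
within an oscillation cycle, a map and its sign flip are the same state:
every operation in this package is polarity-invariant.

**Global field power.** `compute_gfp()` returns the spatial standard
deviation of each average-referenced sample,
$\mathrm{GFP}(t) = \sqrt{\tfrac1C \sum_c (v_c(t) - \bar v(t))^2}$. Samples at
GFP maxima have the highest topographic signal-to-noise and are the input to
clustering. Peak picking (`pick_gfp_peaks()`) takes interior local maxima
within each epoch — a plateau of tied samples counts once, at its first
sample, because a smooth envelope sampled symmetrically produces exact
two-sample ties — thins them greedily from the highest GFP downward so that
surviving peaks are at least 10 ms apart, and finally takes a seeded uniform
subsample if more than the requested 1000 remain. The subsampling rule is a
package decision (the choice among surplus peaks is not specified anywhere
authoritative); uniform sampling avoids biasing the peak set toward
high-amplitude episodes.

**Modified k-means.** `modified_kmeans()` clusters the peak maps $v_t$ into
$K$ unit-norm prototypes $a_k$. Assignment maximizes the squared projection
$(a_k^\top v_t)^2$ — equivalently squared spatial correlation, since both
maps and prototypes are zero-mean — and the update sets $a_k$ to the
principal eigenvector of $\sum_{t \in k} v_t v_t^\top$, the maximizer of
explained squared projection. The fit functional is the residual noise
variance
$\hat\sigma^2 = \sum_t \left(\lVert v_t\rVert^2 - (a_{L(t)}^\top v_t)^2\right) / (T(C-1))$.
Iterations stop when the relative change of $\hat\sigma^2$ drops below
`tol = 1e-7` (the convergence tolerance is a package choice) or after 1000
iterations; 50 stochastic restarts are run and the restart with minimal
$\hat\sigma^2$ wins. The selection functional for the winning restart is
also a package decision — minimal $\hat\sigma^2$ equals maximal explained
variance on the peak maps. Ties in assignment go to the lowest class index;
an emptied cluster is re-seeded from the worst-fit map; a singleton cluster's
prototype is the member map itself.

**Fit criteria.** Global explained variance
$\mathrm{GEV} = \sum_t (\mathrm{GFP}_t \, r_t)^2 / \sum_t \mathrm{GFP}_t^2$
(with $r_t$ the spatial correlation to the assigned prototype) increases
with $K$; the cross-validation criterion
$\mathrm{CV} = \hat\sigma^2 \left(\frac{C-1}{C-1-K}\right)^2$ penalizes
complexity, and its minimum over $K = 2\ldots 8$ selects the number of
classes. A single forced $K$ (e.g. 4) reproduces a fixed-class sensitivity
analysis. Group-level segmentation in `run_pipeline()` pools peaks across
participants within a visit (1000 per participant) and fits one prototype
set per visit; per-visit fitting is the default because microstate
inventories change over development, and a shared-template mode would trade
that sensitivity for cross-visit comparability.

## Backfitting, smoothing, statistics

`backfit_labels()` labels every continuous sample with the prototype of
maximal absolute spatial correlation and retains the full per-sample
|correlation| matrix. `smooth_short_segments()` then iteratively removes
runs shorter than 30 ms *within* each epoch (epochs are discontinuous
excerpts, so runs never span epochs): the shortest offending run is
processed first (the processing order is unspecified in the toolbox
tradition this mirrors; shortest-first makes the procedure deterministic),
and each of its samples is reassigned to the next-best prototype by absolute
correlation — equivalently minimal global map dissimilarity
$\mathrm{GMD} = \sqrt{2(1 - |r|)}$ — excluding labels already rejected for
that sample. If every label is exhausted the run merges into the
neighbouring run with the higher boundary correlation. Each sample can be
rejected at most $K$ times, so the procedure terminates.

`compute_microstate_stats()` computes, per class, the mean run duration
(ms), the occurrence (runs per second of labelled data), the coverage
(fraction of samples) and the per-class GEV. Runs truncated by epoch
boundaries **are** counted by default: that convention makes
$\mathrm{occurrence}_k \times \mathrm{duration}_k / 1000 = \mathrm{coverage}_k$
and $\sum_k \mathrm{coverage}_k = 1$ exact identities, which the test suite
asserts on arbitrary sequences; `count_truncated = FALSE` provides the
exclusion variant. A class that never occurs has missing duration and zero
occurrence/coverage.

`match_prototypes()` assigns found maps to reference maps one-to-one,
maximizing summed |correlation| via the Hungarian algorithm (validated
against exhaustive permutation search in the tests). The canonical A–G
templates are idealized dipolar fields built from verbal descriptions of the
classes (A right-frontal→left-posterior, B left-frontal→right-posterior,
C anterior–posterior, D fronto-central→occipital, E centro-parietal radial,
F/G left/right-lateralized); matching against them is advisory, a surrogate
for visual labelling.

`trim_feature_outliers()` removes, within each cohort × visit × class ×
feature group, values more than 3 SD from the group mean (mean and SD
include the candidate). Only the offending feature value is dropped, not the
whole subject-visit record — the narrower reading of an ambiguous rule, and
the one that discards least data. Zero-SD groups remove nothing; groups
smaller than 3 are skipped with a warning.

## Trajectory models

`fit_random_intercept_lmm()` fits
$y_{ij} = \beta_0 + \beta_1\,\mathrm{age}_{ij} + \beta_2\,g(\mathrm{age}_{ij})
+ \beta_3\,\mathrm{sex}_i + \beta_4\,\mathrm{segments}_{ij} + u_i +
\varepsilon_{ij}$, with $u_i \sim N(0, \sigma_u^2)$,
$\varepsilon \sim N(0, \sigma_e^2)$, by maximum likelihood (lme4,
`REML = FALSE`) so that log-likelihoods are comparable across the three age
models: $g$ absent (linear), $g = \mathrm{age}^2$ (quadratic, raw scale by
default; a centering option tames collinearity at the cost of changing the
coefficient scale), or $g = \log(\mathrm{age})$ (natural log; age in
months). Sex is coded female = 0, male = 1. Fixed-effect inference is
Wald-z; the reference distribution for mixed-model fixed effects is a known
open question and z is the simplest defensible choice at these sample
sizes. BIC is computed as $-2\ell + p\log n$ with $p$ counting fixed effects
plus both variance components.

`select_age_model()` applies the parsimony rule: a nonlinear model is
preferred only when it beats the linear model's BIC by at least 6 points;
when both nonlinear models qualify the lower BIC wins; otherwise linear is
retained. `effect_sizes()` computes Cohen's
$f^2 = (R^2_{\mathrm{full}} - R^2_{\mathrm{reduced}})/(1 - R^2_{\mathrm{full}})$
per predictor from full-vs-reduced ML refits, using the **marginal**
$R^2 = \operatorname{var}(X\hat\beta) / (\operatorname{var}(X\hat\beta) +
\sigma_u^2 + \sigma_e^2)$ — the common mixed-model adaptation; conditional
$R^2$ would credit the random intercepts to every predictor. Thresholds
0.02 / 0.15 / 0.35 label small / medium / large. No multiple-testing
correction is applied; p-values are reported as-is.

With one observation per subject, $\sigma_u^2$ and $\sigma_e^2$ are only
jointly identified; the fit then degenerates to ordinary least squares in
the fixed effects, with the total variance matching the ML residual
variance (asserted in the tests).

## The synthetic-data generators

`simulate_subject_eeg()` emulates a cleaned infant resting recording:
64 channels on a unit sphere (upper-hemisphere-biased golden spiral),
500 Hz, 120 s — long enough for well over 1000 GFP peaks, small enough for
seconds-scale tests. Prototypes are random dipolar fields (projections of
the montage onto rejection-sampled orientations with pairwise
|corr| ≤ 0.6): smooth, realistic rank-1 topographies that need no forward
head model. State dwell times are geometric with 80 ms mean — the
memoryless law is the simplest consistent with a mean-duration
parameterization; a gamma option would be the natural extension — and the
next state is uniform over the others. The signal is the active map scaled
by a 15 µV rectified 10 Hz sine (GFP peaks every 50 ms), plus spatially
white Gaussian noise scaled so signal-RMS / noise-RMS equals the requested
SNR, both measured after average referencing. Default SNR is 4.

What this emulates: topographic discreteness, polarity ambiguity,
envelope-driven GFP peaks, realistic dwell statistics, controlled noise.
What it does not: 1/f background spectra, artifacts, volume-conduction
structure in the noise, spatially correlated sensor noise, or drifting
prototypes. Passing tests therefore establish the correctness of the
algorithms under the stated model, not robustness to every failure mode of
real infant EEG.

`simulate_longitudinal_features()` draws a four-visit cohort with visit ages
N(3.74, 0.879²), N(8.72, 1.49²), N(14.1, 1.24²), N(21.5, 1.20²) months —
the package's default study conditions — with ~20–30% of visits missed
per wave, retained-segment counts uniform on 16–91 (the retention-gate floor
and the 100%-retention ceiling for a 3-minute recording cut into 2-s
epochs), and responses from the random-intercept model above with known
coefficients.

## Measuring dynamics recovery

One subtlety deserves emphasis. The 30 ms minimum-duration rule is part of
the *measurement*, and under a geometric dwell law with an 80 ms mean about
30% of true runs are shorter than 30 ms. Smoothing therefore merges them,
and the post-smoothing duration statistic estimates a larger quantity than
the raw dwell parameter — even with noise switched off entirely (noise-free
and SNR-4 smoothed durations agree to within ~1%, both well above 80 ms,
while unsmoothed backfit at SNR 4 deflates durations several-fold through
mislabels at envelope troughs). Recovery of the dynamics is therefore
assessed like-for-like: `planted_dynamics()` computes the statistics of the
*planted* label sequence under the identical smoothing convention (via a
noise-free backfit), and the pipeline's estimate from noisy data is compared
against that reference. This is the only comparison that isolates what
recovery should mean — the effect of noise on the estimate — rather than
the deliberate bias of the smoothing operator.

## Numerical choices and problem sizes

- Amplitude rejection reads "±150 µV" as absolute voltage > 150 µV on any
  channel/sample (strict, so a sample at exactly 150 µV survives); a
  peak-to-peak reading is possible but not implemented.
- Trailing partial epochs are discarded; the retention gate is strict
  (> 15 segments).
- Convergence tolerance 1e-7 (relative change of $\hat\sigma^2$); assignment
  ties to the lowest index; restart winner by minimal $\hat\sigma^2$.
- Degenerate inputs: an all-zero sample ties every prototype and takes
  class 1; zero-SD outlier groups remove nothing; $K > n_\mathrm{peaks}$,
  single-channel referencing, and $C - 1 \le K$ (CV undefined) raise errors.
- Every generator and the pipeline derive all randomness from explicit
  seeds; identical configuration + seed reproduces numeric outputs byte for
  byte.
- Validation problem sizes: full study conditions (120 s, 64 channels,
  K = 5, SNR 4) for prototype recovery, dynamics recovery (10 seeds) and CV
  K-selection (20 seeds); 100 random 8-map instances for the
  exhaustive-enumeration oracle; 1000 random sequences for the statistics
  identities; 300 subjects × 4 visits × 100 replicates for model selection.
  The standalone acceptance script reports the same quantities at reduced
  replicate counts, which it records alongside each value.

## Known limitations

Segmentation quality degrades gracefully but measurably below SNR ≈ 2 under
the default montage; the CV criterion's penalty depends on channel count and
prefers larger K on small montages; canonical-template matching is advisory
only; and the mixed-model layer supports random intercepts only — random
age slopes, non-Gaussian responses and cross-cohort pooled models are out of
scope.
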