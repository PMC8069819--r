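---
title: "Gaussian-kernel functional connectivity for motor-related EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian-kernel functional connectivity for motor-related EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfconn)
```

## The problem

Decoding motor imagery or motor execution from EEG is limited by strong
between-subject variability: a sizeable fraction of users never exceeds a
usable accuracy ("BCI inefficiency"). Channel-wise band power is the
classical feature family; functional connectivity (FC) — the statistical
dependency between pairs of channels — captures complementary network
structure, but common single-trial FC estimators (Pearson correlation,
phase-locking value) are noisy and sensitive to the analysis window.

`gfconn` implements a single-trial, kernel-based FC measure with a sparse
supervised selection layer on top. For a band-filtered, windowed pair of
channel series $x_c, x_{c'} \in \mathbb{R}^L$, the Gaussian functional
connectivity (GFC) is

$$\kappa_G(x_c, x_{c'}; \sigma)
  = \exp\!\left(-\frac{\lVert x_c - x_{c'} \rVert_2^2}{2\sigma^2}\right)
  \in (0, 1],$$

a stationary positive-definite kernel whose value decays with the
Euclidean distance between the two windowed series. Unlike correlation it
is sensitive to amplitude-profile similarity as well as waveform shape,
and the single length-scale $\sigma$ adapts it to each subject's overall
signal scale. Computed for every trial $r$, frequency band $n$, window
$t$ and channel pair $(c, c')$, these values form the feature tensor of
the pipeline; an elastic-net regression of the trial labels on the
vectorized features estimates one relevance weight per
(band, window, pair) split, realizing the weighted time–frequency
combination as a supervised fit rather than a fixed quadrature.

## Pipeline stages

1. **Filter bank + sliding windows** (`filter_bank()`, `preset_bank()`,
   `apply_bank()`, `segment()`). Zero-phase (forward–backward) order-5
   Butterworth band-passes; the motor-imagery preset is 17 bands covering
   4–40 Hz (4 Hz wide, 2 Hz steps), the motor-execution preset is the four
   canonical bands 8–12, 12–30, 30–50, 50–125 Hz. Windows of length
   $\tau$ seconds slide with 75 % overlap by default
   ($\tau \in \{0.5, 1, 1.5, 2\}$ s is the conventional grid).
2. **Single-trial connectivity** (`connectivity_tensor()`). GFC as above;
   Pearson cross-correlation (CCF) and the time-averaged phase-locking
   value (PLV, modulus of the mean complex phase difference of the
   analytic-signal phases) as baselines. Matrices are symmetric with unit
   diagonal; only the strict upper triangle is stored
   (`pair_index()` fixes the order).
3. **Feature representation**. Either the vectorized upper triangle
   concatenated over bands and windows (`vectorize()`, band-major, then
   window, then pair), or a CSP-style pattern vector: per (band, window)
   split the generalized eigendecomposition
   $\Sigma_1 w = \lambda(\Sigma_1+\Sigma_2)w$ of the class-mean FC
   matrices, keeping the $K{=}3$ leading eigenvectors and projecting each
   trial's matrix to its $K(K{+}1)/2$ upper triangle
   (`fit_csp()`, `project_features()`).
4. **Sparse relevance + decoding** (`fit_relevance()`,
   `cross_validate()`). Elastic-net regression of the 0/1 labels on the
   standardized features; the nonzero coefficients are the relevance
   weights. Classification uses a linear discriminant on the selected
   features (thresholded elastic-net prediction available), scored by
   stratified 10-fold cross-validated accuracy
   $(TP+TN)/(TP+TN+FP+FN)$.
5. **Interpretation** (`embed_subjects()`, `cluster_subjects()`,
   `channel_relevance()`, `top_links()`, `topography_report()`). Subjects'
   normalized relevance vectors are embedded in 2D with exact t-SNE,
   concatenated with their accuracy and k-means-clustered into
   performance groups I/II/III (ranked by decreasing mean accuracy);
   per-pair relevance is accumulated onto channels for scalp topographies
   and the links strictly above the 99th percentile are reported.

## Key parameters

* **Kernel bandwidth $\sigma$** (signal amplitude units). The averaged
  median heuristic: for each (trial, band, window) split the median of
  the $C(C-1)/2$ pairwise Euclidean distances is taken, and $\sigma$ is
  the mean of those medians. One $\sigma$ per subject and fit; inside
  cross-validation it is recomputed from the training folds only, which
  costs nothing because the squared-distance tensor is precomputed and
  the kernel is an elementwise transform of it. Scope alternatives (per
  band or per window) are possible but not default; the global scope
  keeps kernel values comparable across splits.
* **Window length $\tau$** (seconds, default 1) and **overlap**
  (fraction, default 0.75). Window starts are multiples of
  `round(L(1-overlap))` samples; a trailing partial window is dropped, so
  the window count is `floor((T-L)/step)+1`.
* **Elastic-net grid**. The penalty is
  $\alpha_1\lVert v\rVert_1 + \alpha_2\lVert v\rVert_2^2$, parameterized
  by the ratio $\alpha_2/\alpha_1 \in \{0.1, 0.3, 1, 3, 10\}$ and ten
  log-spaced overall strengths per ratio, selected by seeded stratified
  5-fold inner cross-validation. The grid deliberately spans l1- to
  l2-dominated penalties: connectivity features from overlapping bands
  and windows form highly correlated blocks, and an l1-dominated fit
  keeps an arbitrary representative per block while an l2-dominated fit
  spreads weight across the block (the grouping property), which is what
  the interpretation layer needs.
* **CSP components** $K = 3$; ridge `1e-6 * trace/C` added to each class
  mean so indefinite FC matrices (PLV) stay numerically safe; eigenvector
  signs fixed by making the largest-magnitude entry positive.
* **Cluster count** $k = 3$ (groups I/II/III), configurable; t-SNE
  perplexity 5 by default for small cohorts.

## Model selection and the null gate

Among grid points whose inner-CV error is within one standard error of
the minimum, `fit_relevance()` selects the most l2-dominated mix (ties
broken by the larger penalty). The candidates are statistically
equivalent by construction; preferring the grouping-stable fit makes the
relevance weights reproducible across resamples instead of flipping
between correlated columns.

Because the winner is the minimum over ~50 grid points, its CV error is
optimistically biased, and on label-permuted data that bias alone can
"select" dozens of spurious features. The selected model is therefore
accepted only if it beats the intercept-only baseline on the paired
per-fold error differences at a Bonferroni-corrected level
($0.05/\text{grid size}$); otherwise the empty model is returned.
Pairing over shared folds removes the common fold variance, and the
multiplicity correction accounts for the winner having been picked from
the whole grid. In simulation this gate empties essentially every
permuted-label fit while never triggering on plantedly informative data.

Degenerate inputs are handled explicitly: constant feature columns are
dropped with a warning (an all-constant matrix is an error); a constant
response returns the zero model; an empty support falls back to the ten
largest-magnitude coefficients (larger first, then lower column index)
with a warning; an all-tied pair-relevance vector is reported as uniform
rather than all-zero, and with all-tied weights nothing lies strictly
above the link percentile, so the link list is empty.

## The synthetic generator

`generate_synthetic()` produces the ground-truth data every stage is
validated against. Each channel carries independent band-limited
background rhythms (defaults: 8–12 and 16–24 Hz, i.e. mu-like and
beta-like bands) on top of 1/f-shaped plus white noise at a given SNR
(rhythm power over noise power, dB). In class-1 trials the channels of
each planted effect share a common band-limited source inside the
effect's band and time window, mixed as
$\sqrt{1-g^2}\,\text{own} + g\,\text{shared}$ with a 50 ms ramp on $g$,
which raises amplitude-profile similarity and phase alignment
simultaneously so that GFC, CCF and PLV can all, in principle, detect
it. `resolve_truth()` maps each effect to the vectorized feature columns
whose band and window overlap it with positive length.

The default effect is sustained over the whole trial. This is a
deliberate property of the validation design: with a time-confined
effect, overlap-based ground truth includes feature columns whose
physical effect is negligible (a window overlapping the effect by a
quarter second, largely consumed by the mixing ramp), and then no
estimator — not even an oracle ranking by true class separation — can
recover "the truth", which makes recovery scores meaningless. With a
sustained effect every ground-truth column genuinely carries the effect
and recovery measures estimator quality. Time-confined effects remain
available through `synthetic_spec(effects = ...)` for sensitivity
studies.

The reference study condition used throughout the tests
(`strong_coupling_spec()`) is: 8 channels, 100 trials per class, 128 Hz,
3 s trials, SNR 5 dB, one 8–12 Hz effect on channels 1–2 with coupling
gain 0.9, analysed with the 5-band bank `filter_bank(4, 16, 4, 2)` and
1 s windows. These sizes keep a full multi-seed validation run on one
CPU in minutes while leaving the planted effect clearly above the noise
floor. On these conditions the package's own checks find: planted-support
recovery about 0.9 (fraction of ground-truth columns among the top
$2\times$ truth-size coefficients, averaged over ten seeds), 10-fold CV
accuracy near 0.99 for all three measures, and permuted-label accuracy
statistically at chance.

What the generator does **not** emulate: volume conduction and common
reference (which induce spurious zero-lag connectivity on real scalp
EEG), artifacts (EOG/EMG), nonstationary rhythm power, realistic head
geometry. Passing tests therefore demonstrate correctness of the
estimators and of the selection/decoding machinery on data with known
structure — not that GFC overcomes the confounds of real recordings.

## Numerical choices

* Zero-phase filtering (`signal::filtfilt`) so that PLV phases are
  undistorted; filter edge handling follows the forward–backward
  default. Order-5 band-passes in polynomial form are stable at the
  sampling rates and bands used (verified 128–512 Hz); a runtime guard
  errors on non-finite filter output. Very narrow bands show
  conditioning-level roundoff (~1e-8) in the linearity of the operator.
* The analytic signal is computed by the frequency-domain Hilbert
  transform; PLV needs at least 8 samples, and constant channels are an
  error (undefined phase).
* Kernel underflow is clamped to the smallest positive double so the
  documented bound $\kappa_G \in (0, 1]$ survives numerically.
* Stratified folds: per class, a seeded shuffle dealt round-robin with a
  per-class rotated start, so fold sizes differ by at most one trial and
  per-fold class proportions are within one trial of exact.
* The link threshold is the linear-interpolation percentile
  (`quantile(type = 7)`) with strict inequality, so ties at the
  threshold are excluded.
* t-SNE is an exact $O(n^2)$ implementation (per-point perplexity
  calibration by binary search, early exaggeration 4 for 100 iterations,
  momentum 0.5 then 0.8, seeded Gaussian initialization), appropriate
  for cohort sizes of tens of subjects and deterministic given the seed.
* k-means uses 20 seeded restarts, best inertia kept; embedding
  coordinates and accuracy are standardized before concatenation so
  neither dominates the metric.

## Serialization

One self-contained file per subject (`save_epochs()` / `load_epochs()`)
holding the named datasets `data`, `fs`, `labels`, `channel_names`,
`montage`, `subject_id`; the round trip is bit-exact. Pipeline runs
serialize to JSON with the full configuration and seed embedded
(`summary_json()`), so a run is reproducible from its own output.

## Known limitations

* Binary classification only; the multi-class extension is out of scope.
* Undirected, zero-lag dependency measures only — no lagged or directed
  connectivity (Granger, partial directed coherence) and no source-space
  analysis.
* The elastic-net target treats 0/1 labels as a regression response
  (class-probability reading); calibrated probabilities are not a goal.
* The ME preset's 50–125 Hz band requires a sampling rate above 250 Hz.
* Relevance weights are selection weights, not effect sizes; between-
  subject comparisons use the min–max-normalized magnitudes.
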