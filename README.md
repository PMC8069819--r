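# gfconn

Single-trial Gaussian-kernel functional connectivity for motor-related
EEG decoding.

## What problem this solves

Motor-imagery and motor-execution EEG decoding suffers from strong
between-subject variability — a sizeable fraction of users never reach a
usable accuracy ("BCI inefficiency"). Functional connectivity (FC), the
statistical dependency between channel pairs, carries network
information that channel-wise band power misses, but the common
single-trial FC estimators (Pearson correlation, phase-locking value)
are noisy and sensitive to the choice of analysis window.

`gfconn` implements a kernel-based single-trial FC measure and the full
decoding pipeline around it, for researchers working on EEG
brain–computer interfacing. For a band-filtered, windowed pair of
channel series `x_c, x_c'` (length `L`), the Gaussian functional
connectivity is

```
GFC(c, c') = exp( -||x_c - x_c'||^2 / (2 * sigma^2) )   in (0, 1]
```

with the bandwidth `sigma` set by an averaged median heuristic over the
pairwise channel distances. Computed per trial, frequency band (a
Butterworth filter bank), sliding window and channel pair, these values
are vectorized and fed to an elastic-net regression of the trial labels,
whose sparse coefficients are per-(band, window, pair) relevance
weights; a linear discriminant on the selected features is scored by
stratified 10-fold cross-validation. An interpretation layer embeds
subjects' relevance patterns with t-SNE, clusters them (with accuracy)
into performance groups I/II/III, and renders channel topographies with
the top-percentile connectivity links. Pearson cross-correlation (CCF)
and phase-locking value (PLV) baselines, and CSP-style pattern-vector
features, are included for comparison. A synthetic coupled-oscillator
EEG generator with planted class-dependent coupling makes every stage
testable without external recordings.

## Worked example

Simulate a subject with one planted coupling (channels 1–2, 8–12 Hz,
gain 0.9, SNR 5 dB) and run the Gaussian-kernel pipeline:

```r
library(gfconn)

sim <- generate_synthetic(strong_coupling_spec(seed = 1, trials_per_class = 30))
sim$epochs
#> <epochs_set> subject SYN001
#>   60 trials x 8 channels x 384 samples @ 128 Hz
#>   labels: 30 x class 0, 30 x class 1
#>   montage: 8 positions

run <- run_pipeline(
  sim$epochs,
  run_config(measure = "gfc", bank = filter_bank(4, 16, 4, 2),
             tau = 1, folds = 5, seed = 1))
glance(run)
#> # A tibble: 1 × 9
#>   subject measure   tau csp   mean_accuracy sd_accuracy support sigma  seed
#>   <chr>   <chr>   <dbl> <lgl>         <dbl>       <dbl>   <int> <dbl> <int>
#> 1 SYN001  gfc         1 FALSE             1           0     157  6.43     1
```

The planted coupling is decoded perfectly (5-fold CV accuracy 1.0; the
kernel bandwidth fitted for this subject was `sigma = 6.43`), and the
relevance weights land on the planted pair — the five largest
coefficients all belong to channel pair (1, 2) in the 6–10 / 8–12 Hz
bands:

```r
head(dplyr::arrange(tidy(run$relevance), dplyr::desc(abs(v))), 5)
#> # A tibble: 5 × 8
#>   column      v relevance  band window  pair    c1    c2
#>    <int>  <dbl>     <dbl> <int>  <int> <int> <int> <int>
#> 1    477 0.0288     1         2      9     1     1     2
#> 2    729 0.0272     0.946     3      9     1     1     2
#> 3    449 0.0238     0.826     2      8     1     1     2
#> 4    701 0.0237     0.824     3      8     1     1     2
#> 5    505 0.0229     0.794     3      1     1     1     2

run$topography
#> <topography_report> 8 channels, 1 link(s) above the 99th percentile
```

`autoplot(run$topography)` draws the scalp map with that link;
`sweep_pipeline()` compares measures across window lengths; and
`embed_subjects()` + `cluster_subjects()` group a cohort of subjects by
their relevance patterns and accuracy. Everything is deterministic given
the config and seed, and `summary_json()` embeds both in the output.

A thin command-line wrapper with `simulate`, `run` and `sweep`
subcommands is installed at `inst/cli/gfconn.R`.

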