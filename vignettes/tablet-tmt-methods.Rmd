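---
title: "Methods: simulated tablet TMT and split-half activation mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated tablet TMT and split-half activation mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tabletTMT)
```

This vignette documents the models, the parameter choices and the
numerical decisions behind `tabletTMT`. It is a design document, not a
tutorial; the README holds a worked example.

## 1. The task model

A Trail Making Test (TMT) trial is 25 circles of radius `r` on a canvas,
labelled `1..25` (part A) or alternating `1, A, 2, B, ..., 13` (part B).
The subject connects them in label order with a stylus. The block
paradigm is a lead-in "dead" block followed, per trial pair, by
alternating task and fixation-baseline blocks with the two parts
interleaved (A, baseline, B, baseline, repeated). With the default
four trials per part, 60 s task blocks, 10 s baselines and a 10 s
lead-in at TR 2 s, one run is

```
10 + 4 * (60 + 10 + 60 + 10) = 570 s = 285 scans.
```

These defaults are the package's reference configuration; all of them
are ordinary function arguments (`build_paradigm()`), and none of the
analysis code assumes them.

## 2. The stylus generator and its realism limits

`simulate_stylus_log()` produces, per link, a stationary dwell of
duration `N(dwell_mean, dwell_sd)` (truncated at zero) inside the
current circle, followed by a constant-speed polyline to the next
circle with optional perpendicular path noise. Samples are drawn at a
nominal rate (default 40 Hz) with Gaussian timestamp jitter, force
samples are `N(force_mean, force_sd)` clipped at zero, and the log is
truncated at the block ceiling, so slow profiles yield censored trials
with fewer than 24 completed links. Part-B layouts add a constant
`dwell_part_b_shift` (default +300 ms) to every dwell, which is the
generator's model of the extra cognitive set-shifting cost.

What the generator deliberately does *not* model: curvature and
velocity profiles of real reaching movements (movements are piecewise
linear at constant speed), pen lifts, corrections or perseverative
errors, and learning across trials. These omissions are intentional —
the generator's purpose is to provide data with *known closed-form
ground truth* (every dwell, move duration and link arrival time is
stored in `log$truth`), so that the scoring code can be tested for
exact recovery rather than plausibility. One numerical consequence: a
truncated dwell of exactly zero would duplicate a breakpoint timestamp,
so breakpoints are deduplicated before interpolation.

The hand-overlay segmentation rule (`segment_hand_pixels()`) is the
classic uniform-daylight RGB skin rule (`R > 95, G > 40, B > 20,
max − min > 15, |R − G| > 15, R > G, R > B`), applied strictly per
pixel with all thresholds exposed as arguments.

## 3. Behavioral metrics

From a raw log and its layout, `segment_links()` computes, per
completed link *k*:

- **Dwell time (DT)**: the duration of the first maximal run of samples
  whose forward-difference speed `|dx/dt|` is below 0.1 px/ms, starting
  inside circle *k*. The forward difference was chosen over a centered
  one so that the dwell boundary is decided by the *upcoming* movement,
  making hand-constructed logs exactly recoverable; a centered
  difference would smear the boundary across one sample.
- **Link length (L)**: the inked (force above `ink_thr`) polyline
  length from the last sample inside circle *k* to the first inked
  sample inside circle *k+1*. By construction `L >= d − 2r` for center
  distance `d`.
- **Seconds per link (Spl)**: analysis time over completed links.
  Completed trials use the completion time; censored trials use the
  full block duration, so Spl remains defined and conservative when a
  subject fails to finish.
- **Contact force (F)**: the pooled mean force over the first 20 s of
  each block (window exposed as an argument), pooling across blocks
  before averaging so blocks with more samples weigh more.

Group statistics use a mode × part ANOVA with subject as the repeated
factor (`aov` with an `Error(subject)` stratum), Bonferroni correction
over the four metrics, Shapiro–Wilk checks per cell, and a rank-sum
test for force that enumerates the exact tie-safe permutation null for
small samples and falls back to `wilcox.test` for large ones.
`standard_vs_tablet()` relates paper-and-pencil completion times to
tablet Spl via an explicit per-link denominator (default 24), paired
t-tests and per-mode correlations.

## 4. BOLD simulation and the two seeds

`simulate_bold_run()` builds
`signal = baseline + sum_c truth_c * (boxcar_c ⊛ HRF) + drift + motion
coupling + cardiac/respiratory sinusoids + global fluctuation + white
noise`, with one contiguous ground-truth blob per task condition. The
HRF is the standard double-gamma (peak 5 s, undershoot 15 s, ratio 6),
normalized by its peak on a dense reference grid so that the regressor
scale does not depend on the sampling times. Drift uses Legendre
polynomials on [−1, 1], which are numerically orthogonal on the scan
grid and therefore make "order-k drift is removed exactly by order-k
detrending" a clean test.

Activation placement uses a separate `truth_seed` from the noise seed:
varying the noise realization while holding the truth fixed is what a
bias/variance test of amplitude recovery needs, and conflating the two
seeds would make that impossible.

## 5. Preprocessing and task protection

`apply_pipeline()` applies, in fixed order: phase-based physiological
regression (sine/cosine pairs of the first two cardiac and respiratory
phase harmonics, phases linearly interpolated between detected trace
peaks), motion regression (raw parameters or motion PCs up to a
cumulative variance threshold), global-signal PC1 removal, Legendre
detrending, and Gaussian smoothing (separable 1D kernels, truncated at
4σ and renormalized, so constants are preserved exactly even at the
boundary).

With `task_protect = TRUE`, nuisance regression residualizes the
nuisance design against the task regressors first, so the fit cannot
remove variance in the task subspace. For *model-based* nuisance
(polynomials, motion, physiological harmonics) this preserves the task
amplitude exactly. For *data-driven* nuisance (the global PC1) it
cannot be exact: when the run's dominant structure is the task itself,
the estimated PC1 already contains task variance, and no projection
performed afterwards can undo that mixing. Protection still makes the
difference between an annihilated effect and a mostly-preserved one,
and the tests encode precisely that contract rather than a false
exactness claim. Rank-deficient designs are QR-pruned; a nuisance
column that exactly duplicates a protected column is dropped silently
(the protected copy survives), while a collision *inside* the protected
block is an error naming the lost column.

## 6. Split-half evaluation

`build_split_design()` assigns trials 1–2 to split 1 and trials 3–4 to
split 2; each task block contributes the scans of a 20 s analysis
window with the first two discarded for hemodynamic rise, and each
baseline inherits the split of the task block it follows. Task-vs-task
contrasts exclude baselines entirely.

`fit_lda_pca()` centers, reduces to `n_pcs` right singular vectors,
and takes the Fisher discriminant of the pooled within-class scatter
(ridge fallback with a warning when the scatter is singular). The sign
convention makes the first *contrast level's* mean score positive —
the levels of the label factor, not their order of appearance in the
run, define the map polarity, so a B-vs-A map has B positive by
construction. Each half is trained and evaluated on the other half;
prediction `P` is the mean posterior probability of the true class
under a two-Gaussian equal-prior model of the training scores
(computed in logistic log-odds form for numerical stability),
reproducibility `R` is the Pearson correlation of the two half maps,
and `D = sqrt((1 − P)^2 + (1 − R)^2)` is minimized over the pipeline
and PC grids with first-wins tie-breaking. The two half maps combine
into a z-scored map with signal `(m1 + m2)/2` and noise
`sd((m1 − m2)/sqrt(2))`, either globally or per voxel; degenerate
(zero) noise estimates are floored and flagged rather than producing
infinities.

## 7. Group maps

Group analysis stacks subjects' z-maps and takes an *uncentered* SVD:
the shared activation pattern is a common mean direction across
subjects, which centering would remove — with mean removal the first
component would describe between-subject differences instead of the
common pattern. Component signs are fixed by making the mean subject
loading positive. Stability is assessed by split-half resampling of
subjects: each iteration recomputes the component on two disjoint
halves, matches components to the reference by maximal absolute
correlation, and the per-voxel z-score is the mean over iterations of
the component values scaled by their split disagreement. FDR uses the
Benjamini–Hochberg step-up on two-sided normal p-values; clusters are
connected components (6/18/26-connectivity, positive and negative
voxels labelled separately) reported with size, peak and millimetre
coordinates; mode agreement is the Jaccard index of the FDR masks plus
a conjunction (AND) mask with the mean map over it.

## 8. Problem sizes and open-design choices

The package's reference problem sizes — 11 subjects per mode, 25-item
layouts, 285-scan runs, `12 × 12 × 6` demonstration grids — are the
package's own choices, selected so that the full demonstration runs in
minutes on a laptop while leaving every size a plain argument. The
test suite runs the same code on smaller grids and shorter paradigms;
nothing in the implementation is specialized to the defaults.

Wherever a methodological constant was needed but not uniquely
determined by the problem (skin-rule thresholds, the 20 s force window,
the per-link denominator of Spl, the 2-scan hemodynamic discard, the
4σ kernel truncation, the variance floor of the z-map), it is exposed
as a documented argument with the default stated here, so a user can
audit and override every such decision.
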