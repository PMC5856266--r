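---
title: "Simulated ROI MVPA: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated ROI MVPA: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roimvpa)
```

`roimvpa` implements a complete multivoxel pattern analysis (MVPA) pipeline
for task fMRI in which every input is simulated with known ground truth:
epoch designs, BOLD time series, the general linear model (GLM), group
localization of regions of interest (ROIs), linear-SVM decoding under
leave-one-run-out cross-validation, permutation-null inference,
cross-session transfer, feature-count curves, and the group statistics that
accompany them. Because the data generator and the analysis share one
forward model, every stage can be tested against the effects that were
planted. This vignette explains the models, the tunable parameters, the
numerical choices, and what the simulations do and do not establish about
real data.

## The task model

The simulated experiment mirrors a two-session rule-discovery design:
13 subjects, 2 sessions, 4 runs per session. Nine conditions exist: four
rule-discovery conditions of interest crossing *domain* (verbal, spatial)
with *search type* (separate, parallel), two confirmation conditions, two
working-memory control conditions, and one error condition. Each run lays
out one epoch per condition (plus a rare error epoch, at most a few per
session, so the GLM must tolerate runs without an error regressor).
Epoch durations are drawn uniformly around a per-session mean — 17 s in
session 1 and 10 s in session 2 — and epochs are separated by blank gaps
jittered between 2 and 8 s on a 250 ms grid. `generate_design()` is
deterministic given its seed, and every run contains all four conditions of
interest, which the four-fold cross-validation requires.

## The ground-truth scene

`generate_scene()` plants three kinds of effects in ellipsoidal or
exact-size voxel blobs (`roi_spec()`):

* **localizer-only** regions respond to the task (discovery amplitude 1.0,
  confirmation 0.6, control 0.2, error 0.3, in noise-SD units) but carry no
  domain information;
* **pattern-carrier** regions additionally carry a *multivoxel domain
  code*: a zero-mean voxel-wise offset vector per domain, SD
  `sigma_pat` (default 0.5), identical across runs within a session and —
  when `session_remap = TRUE`, the default — drawn independently per
  session, so the code remaps between sessions;
* **magnitude-confound** regions add a spatially uniform
  verbal-minus-spatial offset `confound_delta` (default 0.48) to the
  discovery conditions: a mean-activation difference with no pattern
  structure, which a classifier can nevertheless exploit.

Every region also receives a per-voxel multiplicative gain, uniform on
[0.5, 1.5], shared across conditions. This response heterogeneity is what
makes class-mean patterns in a confound region almost perfectly correlated
across classes (the diagnostic signature of a magnitude artifact) while
keeping the uniform offset exactly `confound_delta` per voxel. Outside all
regions every condition's amplitude is zero, and overlapping regions are
rejected because overlap would confound the localizer contrast.

The default six-region scene mimics the cluster sizes a
discovery-versus-control localizer typically produces (463, 167, 102, 32,
27, 300 voxels), with one pattern carrier and one magnitude confound among
them.

## Forward model and GLM

Each voxel's time course is the sum over conditions of its amplitude times
the condition's boxcar convolved with the canonical double-gamma
haemodynamic response function (gamma shapes 6 and 16, rate 1, undershoot
ratio 1/6, 32 s support, unit peak), plus Gaussian noise (`sigma`, default
1.0), optionally AR(1)-correlated (`ar1_rho`), with optional polynomial
drift and motion leakage. The repetition time (TR 2.0 s), grid
(36 x 36 x 30) and noise model are explicit stand-ins chosen as the
smallest model sufficient to exercise every analysis stage; they are not
reconstructions of any particular acquisition.

The GLM (`build_design_matrix()`, `fit_glm()`) concatenates runs with one
boxcar-convolved column per (condition, run) pair present in that run, six
motion regressors per run, and one constant per run, at microtime
oversampling 16. With all eight task conditions in four runs this yields
the 32 condition-by-run betas per session that decoding draws on. Because
the simulator and the design matrix share the convolution code, the
noise-free round trip recovers planted amplitudes to machine precision
(tested at 1e-6). Regressors are scaled so that a sustained epoch plateaus
at its amplitude, putting betas in the simulator's signal units. Rank
deficiency falls back to a pseudoinverse with a classed warning. Contrast
weights are per condition, split equally over that condition's run columns;
the localizer contrast weights the four discovery conditions +1 each and
the two controls -2 each.

The convolution itself uses an exact identity rather than an FFT: a boxcar
is a difference of unit steps, so its discrete convolution with the kernel
is a difference of shifted cumulative kernel sums. This is O(time) per
epoch and agrees with a full convolution to ~1e-15 (tested).

**Group model.** Per-subject localizer contrast effects enter a voxel-wise
one-sample t test (df = n - 1). A full factorial ANOVA over the eight task
conditions would test the same null for this single contrast with far more
machinery; the one-sample t is the equivalent inference for the quantity
actually used, so the factorial group model is deliberately out of scope.
Voxels with zero between-subject variance and a nonzero mean are flagged
infinite rather than NaN.

## ROI localization

ROIs are defined from **session 1 only** and reused for session 2:
one-tailed peak thresholding at p < 0.001 on the group t map (the localizer
is directional), 3D connected-component labeling (connectivity 18 by
default, SPM-like; 6 and 26 available), cluster-extent family-wise error
(FWE) correction at alpha = 0.05, and a minimum-extent filter of 25 voxels
(MVPA needs enough features).

Random-field-theory FWE is replaced by a **sign-flipping max-extent
permutation**: each of `n_perm` iterations flips the signs of whole subject
contrast images, recomputes the group map, thresholds, and records the
largest cluster. This is distribution-free, exact under symmetric errors,
and matches the same error-rate target. One numerical subtlety: on sparse
discrete nulls (where the max extent is usually 0 or 1 voxel) the
"(1 - alpha) quantile" itself can be exceeded far more often than alpha, so
the threshold is defined as the smallest integer extent whose null
exceedance probability is at most alpha. The calibration test (100 null
datasets) verifies the realized family-wise rate stays at or below
alpha within Monte-Carlo error.

Cluster labels are deterministic: numbered by decreasing size, ties broken
by the lexicographically smallest peak coordinate; peaks are
maximum-statistic voxels with the same tie-break.

## Decoding

`extract_patterns()` pulls the betas of the four conditions of interest
inside an ROI: 16 samples (4 conditions x 4 runs), split by search type
into two 8-sample subsets with exactly one verbal and one spatial sample
per run. Row order is run-major with a fixed condition order; voxel order
is mask scan order. **Betas are not normalized**: the package reports the
magnitude confound rather than removing it, because mean-centering
(`normalize_patterns()`, available as a sensitivity flag) would hide
exactly the artifact the confound table is designed to expose.

`loro_decode()` trains a soft-margin linear SVM (C = 1 by default, the
conventional choice where no value is otherwise specified; `e1071`/libsvm
backend) on three runs (6 samples) and tests on the held-out run's pair,
rotating over the four runs. Tied decision values (exactly zero) go to the
lexicographically first class label and are logged; with continuous betas
they have probability zero. Group summaries are mean and SEM = sd/sqrt(n)
over subject means.

**Permutation null.** Domain labels are permuted *within run within
subject*: each run's verbal/spatial pair is swapped or not, uniformly at
random, independently per subject and iteration; the full leave-one-run-out
analysis is re-run and the group mean recorded (default 1000 iterations;
below 100 a warning marks the percentile unstable). Within-run permutation
preserves the run structure the cross-validation relies on, and with four
runs gives 16 distinct relabelings per subject per subset — across 13
subjects the group null has 16^13 configurations. The critical value is
the empirical 95th percentile with *higher* interpolation, and significance
requires the observed accuracy to *strictly* exceed it; both choices make
the criterion conservative, never anti-conservative.

Because each fold's classifier depends only on the flip state of its three
training runs, and flipping the held-out pair maps a fold accuracy a to
1 - a, training the 4 x 8 fold-by-configuration classifiers once reproduces
the accuracy of all 16 relabelings exactly. `permutation_null()` uses this
memoization; the test suite verifies it equals literal relabel-and-rerun on
all 16 flip vectors.

**Cross-session transfer** trains on all 8 samples of one session's subset
and tests on the other's (no folds), in both directions separately. With
session-remapped codes the planted prediction is chance-level transfer;
with a session-stable magnitude confound, transfer persists.

**Feature-count curves** evaluate subset sizes 10 to 100 voxels in steps of
10, with 10 random without-replacement draws per size, averaged within then
across subjects; sizes exceeding the ROI are skipped with a classed
warning.

**Seed policy.** One master seed; every subject, run, permutation and draw
derives its own child seed through a documented integer recurrence
(`derive_seed()`), so any single unit is reproducible in isolation and full
pipeline runs are bit-reproducible on one platform.

## Group statistics

* `mean_beta_table()` averages betas over voxels, runs and subjects per
  (ROI, condition) and reports the absolute verbal-minus-spatial mean-beta
  difference per search type, flagging the table-wide maximum — the
  diagnostic that separates genuine pattern structure from magnitude
  artifacts. `beta_differences()` applies the same arithmetic to any
  cell-mean table.
* `rm_anova_2x2()` is the within-subject 2 x 2 repeated-measures ANOVA
  (e.g. hemisphere x session on accuracies), each effect tested against its
  subject-by-effect stratum via `stats::aov()` error strata. Two-level
  factors need no sphericity correction. Strata that are exactly 0/0 (no
  effect and no error variability) report F = 0 rather than noise. The
  "hemisphere" factor is operationalized as two named ROIs, the left/right
  pattern-analogue pair.
* `paired_t()` is the standard two-tailed paired t (df = n - 1);
  zero-variance differences return a degenerate flag instead of an error
  (equal vectors: t = 0, p = 1).
* `generate_behavior()` draws exemplars-to-discovery per cell as
  `1 + (mean - 1) * m_s * e` with mean-1 gamma multipliers (subject-level
  and cell-level, CV 0.25 each), so values never drop below one exemplar.
  Default cell means give session means 2.1 and 1.3 with the spatial domain
  and parallel search slightly harder, margins consistent to ~0.05 with
  the session/domain/search summaries they emulate.

## Problem sizes used by the test suite

Simulation-backed checks run at reduced but honest scales, chosen as the
smallest sizes at which the statistical property under test is
well-estimated: chance calibration uses 50 noise-only datasets
(13 subjects, 50-voxel region); the realized type-I error of the
permutation criterion uses 100 null datasets with 500-permutation nulls;
planted-effect recovery uses 50 two-session studies at
`sigma_pat / sigma = 0.5`; localizer recovery uses a six-region scene on a
20 x 20 x 14 grid with 13 subjects; oracle-equivalence checks (normal
equations, graph-components labeling, sums-of-squares ANOVA) use 100
random small instances each. `scripts/acceptance.R` re-runs the two
calibration studies from scratch at these sizes.

## What the simulations do and do not show

The generator reproduces the *statistical* structure the analysis assumes:
epoch-level condition regressors, a linearly separable (or chance-level)
domain code confined to known voxels, session-specific remapping, and a
uniform magnitude confound. It deliberately omits vascular and
physiological noise, spatial autocorrelation and smoothing, slice timing,
subject-specific anatomy, behavioral reaction times, and letter-level
stimulus content. Passing tests therefore establish that the pipeline's
bookkeeping, estimators and error rates are correct under its own model
assumptions — not that any particular real dataset satisfies those
assumptions. Printed accuracies from real studies depend on undeposited
human data and are not reproduction targets; the package's calibration
quantities (chance level, realized significance level, recovery rates) are
the reproducible analogues.

## A minimal run

```{r example, eval = FALSE}
cfg <- run_config(
  seed = 1,
  design = design_params(n_subjects = 6, mean_epoch_duration = c(10, 8)),
  scene_grid = c(14, 14, 10),
  roi_specs = list(
    roi_spec("L_IFG", c(4, 4, 4),  n_voxels = 40, role = "pattern-carrier"),
    roi_spec("R_IFG", c(10, 10, 7), n_voxels = 30, role = "localizer-only"),
    roi_spec("L_OG",  c(4, 11, 6), n_voxels = 26, role = "magnitude-confound")),
  n_perm_cluster = 100, n_perm = 500, min_voxels = 20)
report <- run_pipeline(cfg)
report$decoding
render_report(report, "mvpa-report")
```

The expected signature: the pattern carrier decodes above its critical
value within session but transfers at chance across sessions; the
magnitude-confound region decodes above chance in both and *does* transfer
(the offset is session-stable), while the confound table flags its
verbal-spatial difference as the table's maximum; localizer-only regions
hover at chance.
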