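---
title: "Cross-language semantic decoding: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-language semantic decoding: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`semdecode` implements a complete multi-voxel pattern analysis (MVPA)
pipeline for one scientific question: do concept-evoked brain activation
patterns generalise across the two languages of a bilingual, and across
stimulus modalities (picture naming, word reading, word listening)? Because
no real dataset ships with the package, a simulation module generates
multi-subject data with known ground-truth signal topography, so that every
downstream stage — first-level GLM, searchlight cross-classification,
group-level cluster statistics, ROI permutation inference — has a
parameter-recovery test.

## The experimental design being modelled

Each simulated subject performs up to three tasks (naming, reading,
listening) in two languages (L1, L2). Every task × language cell contains 5
runs; within a run each of 10 concepts is presented 6 times (60 trials),
with 1 s stimuli and inter-trial jitter drawn from a 1.0–5.2 s grid in
0.3 s steps with a pseudo-logarithmic (geometric) weight profile whose
decay rate is solved numerically so the mean interval is 2.6 s. TR is 2 s
and runs default to 143 analysed scans (a 152-volume acquisition minus 9
equilibration volumes). Concepts are decoded *across* languages: a
classifier trained on L1 patterns is tested on L2 patterns (and vice
versa), so above-chance transfer requires a representation shared between
languages. Chance is 1/10.

Stimulus lists for such designs must avoid lexical overlap between
translation equivalents, otherwise orthographic or phonological overlap
could drive cross-language transfer. The `stimuli` utilities score this
with the normalised Levenshtein distance (edit count divided by the longer
word length, case-folded, accent-preserving); the built-in pairs maan/lune
and paard/cheval both score 1.00, and `validate_stimulus_set()` flags any
pair below a configurable threshold (default: distance must be exactly 1).

## The generative model

`generate_beta_dataset()` produces per-run concept activation volumes
("betas") directly: for each subject, each `effect_region()` draws concept
patterns i.i.d. standard normal per voxel, scaled by the region's
`amplitude`; each (task, language, run, concept) volume is the noise-free
pattern plus i.i.d. Gaussian run noise (`noise_sd`). The sharing regime of
a region decides which conditions reuse the same pattern:

* **shared_semantic** — one pattern per concept, identical across both
  languages and all listed tasks. This is the generative analogue of a
  language- and modality-independent semantic code, and the only regime
  that supports cross-language *and* cross-modality transfer.
* **language_specific** — independent patterns per language (shared across
  tasks): transfers across tasks but not languages. Serves as the negative
  control for cross-language decoding.
* **modality_specific** — independent patterns per task (shared across
  languages within a task): the generative analogue of sensory/featural
  codes tied to one modality. Transfers across languages within a task but
  not across tasks.

Regions with different sharing regimes may not overlap (rejected);
same-regime contributions add. The per-voxel discriminability scale is
`amplitude / noise_sd`. Noise is white by default; `noise_fwhm_mm` smooths
the noise fields to add spatial autocorrelation when that matters to a
study. We deliberately did not model hemodynamic nonlinearity,
physiological noise or motion: the aim is a transparent testbed for the
statistics, not a biophysical simulator, and passing tests on this
generator demonstrates correctness of the analysis machinery, not
performance on real scanner data.

`generate_timeseries()` produces raw BOLD runs from the *same* generative
patterns (per-subject seeds are derived once from the config seed, so the
two generators agree): trial boxcars convolved with the canonical
double-gamma HRF scale each concept's pattern, plus low-frequency drift
confined to the sub-1/128 Hz discrete-cosine span and white noise. All
trials evoke responses; trial "correctness" (Bernoulli with
`correct_rate`, default 1) only affects which trials the GLM models,
mirroring the exclusion of incorrectly categorised trials at analysis
time.

## First-level GLM

`build_design()` assembles, per run: one canonical-HRF regressor per
concept (incorrect trials excluded), their temporal derivatives, optional
six motion regressors, a discrete-cosine high-pass set and an intercept.
The HRF is the canonical double-gamma (peak delay 6 s, undershoot delay
16 s, unit dispersions, undershoot ratio 1/6, 32 s window) — the de-facto
standard of the major fMRI packages; the parameters are exposed for
sensitivity analyses. High-pass filtering is implemented as DCT regressors
*inside* the model rather than pre-filtering; for ordinary least squares
the two are equivalent, and the regressor form makes the contract easy to
test (betas are provably invariant to any drift inside the span). The
column count follows the strict frequency rule: all k with
k/(2T) < 1/128 Hz, e.g. 4 columns for a 304 s run. `fit_glm()` is
voxel-wise OLS returning only the canonical concept betas; derivative,
motion and drift columns are nuisance. A concept whose trials are all
excluded yields an all-zero column: it is flagged unestimable, dropped
from the fit (betas `NA`), and the decoding stage drops those patterns
from affected folds while the chance level keeps the full concept count —
a conservative choice that avoids fold-dependent class counts.

On noise-free simulations the fitted betas reproduce the generative
amplitudes to below 1e-6 relative error, and at matched noise the decoding
accuracy of estimated betas tracks that of directly simulated betas within
two percentage points — both are enforced by tests.

## Cross-classification

`make_cross_language_scheme()` builds the leave-one-run-out transfer
design: train on 4 of 5 runs in one language, test on the held-out run of
the *other* language, rotate the test run, and mirror the direction; the
two direction maps are averaged. `make_cross_modality_scheme()` pairs two
tasks and always crosses languages as well, so neither lexical nor sensory
overlap can drive transfer; the default holds out the matching run of the
test task (preserving run-wise independence and comparability with the
within-task scheme), with an all-runs variant behind a flag. Within-language
schemes exist but are flagged `lexically_confounded`: with identical
stimuli in train and test, semantic and lexical overlap cannot be
distinguished.

The classifier is k-nearest-neighbour, defaulting to k = 1 with Euclidean
distance on features z-scored with training-fold statistics (no test
leakage); a correlation metric and larger k are configuration options.
Classifiers of this family are standard for small-n pattern transfer
problems, and the pipeline's conclusions should not hinge on the choice;
the pluggable settings make that checkable. All tie-breaks are
deterministic and documented: neighbour ties by training order, vote ties
by smallest concept index.

`run_searchlight()` scores every in-mask centre voxel over its radius-3
sphere (123 voxel offsets — verified against brute-force enumeration).
Spheres are truncated at mask edges to their in-mask voxels, keeping
cortex-edge coverage; centres with fewer than `min_voxels` (default 10)
in-mask voxels are marked undefined (`NA`), never zero. Accuracy is pooled
correct/total over folds within a direction, then averaged across
directions. Accuracy maps are smoothed only *after* decoding
(`smooth_map()`, 8 mm FWHM default) — smoothing first would blur away the
fine-grained pattern information the classifier uses. Smoothing is
mask-aware (convolved values renormalised by the convolved mask), so
constants are fixed points and edge voxels are unbiased.

## Group-level inference

`one_sample_t()` tests each voxel's mean accuracy against chance
(one-sided), with z-equivalents obtained by matching upper-tail
probabilities (capped at p = 1e-16 to avoid infinities). Zero-variance or
under-defined voxels are undefined rather than infinite.
`extract_clusters()` partitions suprathreshold voxels (voxel p < .001 by
default) under 26-connectivity (18 and 6 available) and reports peak world
coordinates, peak t/z and extents — anatomical labelling is out of scope.

For family-wise-error control, `cluster_correct()` uses a sign-flip
max-cluster-extent permutation test: under the null the subject deviations
(map − chance) are symmetric, so signs are exchangeable; each permutation
recomputes the t-map and records its maximal cluster extent, and an
observed cluster's corrected p is `(1 + #{null ≥ extent}) / (1 + n_perm)`.
We chose this over random-field-theory corrections deliberately: RFT's
smoothness estimation and Gaussianity assumptions are poorly matched to
accuracy maps, while the permutation test is distribution-free and carries
the same error-rate contract. Only the per-voxel mean changes under sign
flips (squares are invariant), so each permutation costs one matrix
product. With n subjects the permutation space is 2^n; below 5 subjects
(< 32 sign patterns) the function warns. Type-I calibration at the nominal
0.05 level is verified by simulation in the test suite.

## ROI inference

`builtin_rois()` provides five spheres around canonical semantic-network
coordinates (left IFG −45 23 12, left MTG −56 −44 4, cerebellum 20 −78
−35, left SMA −3 16 53, left MFG −27 13 52). The original region masks
come from prior work and are not published, so transparent 8 mm spheres
(radius configurable, explicit masks accepted) stand in for them.
`roi_accuracy()` classifies with *all* ROI voxels as one feature vector —
no searchlight — using the same direction-averaged schemes and classifier
settings as the whole-brain analysis (shared defaults; divergence is
configurable).

`permutation_bootstrap_p()` builds the group-level null in two stages:
within each subject, concept labels are permuted *within each run*
(permutations sampled uniformly with replacement — the full within-run
permutation group is astronomically large) and the cross-validated
accuracy recomputed P = 100 times; then B = 10000 bootstrap group means
are formed by sampling one chance accuracy per subject and averaging. The
observed group mean is referred to this distribution,
`p = (1 + #{bootstrap ≥ observed}) / (1 + B)`, so p-values are never
exactly zero and are seed-deterministic. Across ROIs,
Benjamini–Hochberg FDR at q = 0.05 (`fdr_correct()`, via
`stats::p.adjust`) controls the expected false-discovery fraction;
`roi_analysis()` assembles the per-region table.

## Numerical choices and degenerate inputs

* Distances are squared Euclidean (monotone-equivalent to Euclidean for
  ranking); the correlation metric is implemented by centring and
  unit-norming each local pattern, preserving the 1 − r neighbour order.
* Features with zero training variance are passed through unscaled
  (divisor 1) rather than producing NaNs.
* Convolution uses a 16× oversampled grid (dt = TR/16) with onsets snapped
  to the grid; generation and fitting share the routine, so noise-free
  recovery is exact to solver precision.
* `world_to_voxel()` rounds to the nearest voxel; ROI spheres include
  voxels whose centres lie within the radius.
* Empty ROIs, out-of-geometry regions, overlapping regions with
  conflicting sharing regimes, events beyond run end, rank-deficient
  designs (offending columns named) and empty training folds are all
  rejected with explicit errors.

## Problem sizes

The package defaults target desk-scale experimentation: a 20³ voxel grid
at 3 mm (the full 64 × 64 × 34 acquisition-like grid is supported and is
the default frame for the built-in ROIs, whose z-origin of −40.5 mm keeps
all five centres in-slab). The test suite exercises the full pipeline at
10 subjects × 20³ voxels × 5 runs × 10 concepts with
amplitude/noise = 1.5 for the implanted-region recovery check, 200
simulated null datasets for cluster-level error calibration, and reduced
permutation counts (P = 30–100, B = 300–10000) for the ROI calibration
checks; these sizes were chosen so a full run completes in minutes on one
CPU while keeping the statistical checks well-powered.

## Known limitations

The generator's i.i.d. Gaussian patterns and noise are favourable to
nearest-neighbour decoding; real data have spatially and temporally
correlated noise, inter-subject anatomical variability and hemodynamic
nonlinearity, none of which are modelled. Passing parameter-recovery tests
therefore validates the statistics and bookkeeping of the pipeline, not
expected effect sizes on real data. Whole-brain results report coordinates
only (no atlas labels), preprocessing (motion correction, slice timing,
normalisation) is assumed done upstream, and the within-language schemes
remain lexically confounded by construction and are labelled as such.
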