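---
title: "Decoding episodic memories from MTL voxel patterns: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding episodic memories from MTL voxel patterns: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtlmvpa)
```

## The question the pipeline answers

Multi-voxel pattern analysis (MVPA) asks whether the *joint* pattern of BOLD
activity across many voxels carries information that voxel-wise averages do
not. Applied to the medial temporal lobe (MTL) of a patient with unilateral
hippocampal sclerosis (HS), the question becomes concrete: can a classifier
tell, from a single recall trial's activity in a given region of interest
(ROI), *which* of three well-rehearsed autobiographical-like memories the
subject is recalling? A region whose patterns support above-chance
classification demonstrably represents the memories; a sclerotic hippocampus
is expected to fail this test even when its overall activation looks normal,
because activation and representation are different things. The contrast of
decodable versus non-decodable regions — summarised by a hemisphere-by-region
interaction — operationalises the *functional reserve* of the contralesional
MTL.

No patient data ship with this package. Instead, a synthetic-data generator
produces event-related BOLD runs whose statistical structure matches what the
decoding analysis assumes, including a "sclerotic" ROI mode that carries
evoked activity but no memory-specific pattern. Everything downstream —
preprocessing, decoding, group statistics — treats the data exactly as it
would treat real NIfTI + TSV inputs.

## The generative model

A session is `n_classes = 3` memories recalled `n_trials_per_class = 20`
times each, in a pseudo-random order constrained so the same memory never
repeats on consecutive trials (constrained sequential sampling with a
feasibility look-ahead; exact, no backtracking). Each trial is a cue
(2 s), a recall window (`recall_duration_s = 7`), and a single configurable
inter-trial gap (`inter_trial_gap_s = 12`, collapsing the press tail, the
fixation, two rating screens and rest — only the recall window is ever
analysed, so the gap's internal structure is irrelevant and the value is a
free parameter chosen to give a realistic ~21 s trial period). Volumes are
sampled at `tr_s = 3.5` with isotropic 1.5 mm voxels, and
`n_dummy_volumes = 6` equilibration volumes are prepended.

Each signal-bearing ROI gets one fixed spatial pattern per memory, i.i.d.
standard normal across its voxels (no spatial autocorrelation is claimed —
only that memories have distinct patterns across voxels). On each trial the
cued memory's pattern is added, scaled by `signal_amplitude` and by a
regressor: the boxcar over the recall window convolved with the canonical
HRF and sampled at volume times. The HRF is the usual double-gamma —
positive lobe with mode 6 s, undershoot with mode 16 s, peak:undershoot 6,
support ~32 s — normalised to peak 1 and overridable via `hrf_params`.
Because the boxcar integrates ~7 s of an HRF with peak 1, the convolved
regressor peaks near 3.9, so `signal_amplitude` is calibrated at the level
of the *unconvolved* pattern strength per unit HRF response, not at the
peak of the trial response; amplitude and noise SD default to 1.

Two deliberate asymmetries make the construct meaningful:

* **Silent ("sclerotic") ROIs and background voxels respond to every trial
  with a single class-independent pattern.** Activation is therefore present
  everywhere; only *information* differs between regions. A univariate
  contrast cannot distinguish a silent ROI from a signal ROI.
* **ROIs are axis-aligned ellipsoids spaced more than two voxels apart** on
  the default 24 × 24 × 12 grid. The gap matters: a 3 mm FWHM kernel has
  appreciable weight out to ~2 voxels, and during development we observed
  that a layout with sub-voxel gaps let smoothing carry a neighbouring
  region's class signal into the silent hippocampus (silent-ROI accuracy up
  to 74%). The layout, not the smoothing, was wrong: a sclerotic ROI must be
  silent by construction, not decodable through kernel bleed.

Per-voxel linear drift (`drift_slope` per volume) and i.i.d. Gaussian noise
(`noise_sd`) complete the run. Given a seed the whole simulation is
bit-reproducible; within a cohort, per-subject seeds are derived from the
master seed by an invertible affine hash modulo 2^31 − 1, so streams are
collision-free and changing decoding options can never alter the simulated
data.

Behaviour is simulated so that a fraction `exclusion_rate` (default 0.4) of
trials is excludable by exactly one of the three screening rules — press
before 5.5 s, press after 10 s or absent, rating below 3 — leaving on
average ~36 of 60 trials, the trial count the analysis is designed around.

## Preprocessing

The chain is: discard 6 dummy volumes → smooth each volume with an isotropic
3 mm FWHM Gaussian (sigma = FWHM/(2√(2 ln 2))/voxel size; nearest-neighbour
boundary replication so edge-of-ROI voxels are not deflated) → subtract each
voxel's least-squares line in volume index (a projection, hence idempotent)
→ convolve each voxel series causally with the canonical HRF sampled at the
TR, truncated to the run length (output at volume *t* depends only on
volumes ≤ *t*). Convolving data that already contain haemodynamic responses
roughly doubles the effective delay to ~12 s; onsets are therefore shifted
forward by `round(12 / 3.5) = 3` volumes (ties round away from zero). From
each included trial, 4 consecutive volumes starting at
`floor(onset/TR) + shift` are averaged voxelwise into one pattern row.

Choices worth stating explicitly:

* **Averaging the 4 volumes** (rather than keeping each as a sample) matches
  a design in which cross-validation folds are *trials*; a per-volume mode
  (`average = FALSE`) exists for exploration.
* **Onset→volume mapping** is `floor(onset/TR)`, the volume containing the
  onset; onsets are defined relative to the first post-dummy volume.
* **Boundary inclusivity**: a press at exactly 5.5 s or 10.0 s and a rating
  of exactly 3 are *included*; exclusion applies strictly beyond the bounds.
* Motion realignment and distortion correction are assumed already done
  (synthetic runs need neither); the chain passes volumes through untouched.

## The decoder

For an ROI with patterns `X` (trials × voxels), classification is
leave-one-trial-out (LOTO): *k*-fold with *k* = number of trials. Within
each fold:

1. **Searchlight feature selection on training trials only.** One candidate
   sphere per ROI voxel: all ROI voxels within lattice distance 3 of the
   centre (an interior sphere has 123 voxels; border spheres are clipped).
   Each sphere is scored by *nested* LOTO accuracy computed entirely within
   the training trials, using the same classifier as the final prediction.
   The best sphere wins; ties break to the lowest centre index (column-major
   order), making selection deterministic. Training-accuracy scoring is
   available (`score_mode = "training"`) but nested scoring is the default
   because it does not reward spheres that merely overfit.
2. **ECOC multiclass classification.** The exhaustive error-correcting
   output code for 3 classes (equivalently one-versus-rest; 3 dichotomies)
   relabels the training data per dichotomy; a soft-margin linear SVM with
   fixed C = 1 is trained on each. The held-out trial's predicted bits (sign
   of decision values; exactly 0 maps to +1) are compared to each class's
   codeword and the nearest in Hamming distance wins, ties to the lowest
   class label. Linear kernels are the near-universal MVPA choice at these
   dimensionalities (tens of voxels, tens of trials).

The SVM dual is solved by an SMO solver (second-order working-set selection)
operating on per-sphere Gram matrices. Nested scoring is the expensive part
— every (outer fold × sphere × nested fold × dichotomy) combination is a
fit — so the implementation caches leave-two-out models: the model trained
on all trials except {t, u} serves simultaneously as nested fold *u* of
outer fold *t* and nested fold *t* of outer fold *u*, and each is
warm-started from the all-trials solution of its dichotomy with the equality
constraint repaired. None of this changes the estimator; it is the same
nested LOTO, computed once instead of twice and started near its solution
(solver tolerance 1e-3, the LIBSVM default; `train_binary()` uses 1e-6).
A correctness test compares decision values against LIBSVM (via e1071) on
random problems.

Degenerate folds: if removing trials leaves a dichotomy one-sided (a class
with a single trial), that nested fold is skipped and the sphere's score
taken over the remaining folds; if *every* fold is degenerate (e.g. one
trial per class) scoring raises an error rather than inventing a number.
`loto_crossval()` requires at least two trials per class up front.

Leakage is structural, not incidental: fold *t*'s sphere scores average
predictions of models trained without trial *t* and tested on trials ≠ *t*,
so no quantity entering fold *t*'s selection or training touches the
held-out trial's features. The test suite mutates held-out trials and
asserts exact invariance of the fold's selection and classifier.

A calibration note: LOTO cross-validation is slightly pessimistic at small
trial counts (leaving out a class-c trial makes class c rarer in training),
biasing chance-level accuracy below 1/n_classes by ~0.02 at 36 trials for a
plain classifier. The full decoder with feature selection is calibrated on
no-signal data — permuting labels 200 times on fixed patterns gives mean
accuracy within sampling error of 1/3 — which is what the chance-level
t-tests assume.

## Group statistics

Per region × hemisphere, per-subject accuracies are compared to chance with
a one-tailed one-sample t-test against exactly 1/3 (the printed "33%" is
rounding; the test uses the exact value). Left-right contrasts use paired
two-tailed t-tests. The 2 (hemisphere) × 3 (region) design is analysed with
the classical univariate repeated-measures decomposition — each effect
tested against its own subject-interaction stratum, interaction df
(2, 2(n−1)) — without sphericity correction by default, Greenhouse–Geisser
optional. No multiple-testing correction is applied (a single p < 0.05
threshold throughout, mirroring the analysis being modelled). Accuracy is
correlated with ROI volume by Pearson's r with the usual t-based two-tailed
p. Dice overlap, 2|A∩B|/(|A|+|B|), is provided for segmentation QC; two
empty masks are defined to overlap perfectly, with a warning. Patient
versus control group comparisons use a classical (optionally Welch) one-way
ANOVA. All of these are implemented from their defining formulas and
cross-checked in the test suite against R's own `t.test`, `cor.test`,
`aov`/`Error()` strata and `oneway.test` to 1e-8 on randomly generated
inputs.

Cell-level degeneracies are tolerated: a cohort whose every subject decodes
a region perfectly has zero variance, so its chance test is reported as
absent (NULL) rather than aborting the report.

## Problem sizes and defaults

The package's own study conditions, used by the tests and the analysis
scripts: default cohorts are 9 subjects on a 24 × 24 × 12 grid of 1.5 mm
voxels with six ellipsoidal ROIs of ~35 voxels (semi-axes 2.5 × 2 × 1.5,
jittered ±15% per subject so ROI volumes vary and the accuracy–volume
correlation is defined), 3 × 20 trials with a 0.4 exclusion rate (~36
analysed), amplitude = noise SD = 1, drift 0.05/volume. The left-HS cohort
silences `HC_L`. Calibration checks run 30 no-signal seeds of a single-ROI
micro-configuration (16 × 16 × 8 grid, 36 trials); recovery and
dissociation checks run 20 cohort replicates each. At these sizes a full
subject simulates, preprocesses and decodes in ~2 s on one CPU.

With amplitude = noise = 1 the planted signal is strong: signal ROIs often
decode at 100%, a ceiling real MTL data never reach (reported hippocampal
accuracies in patients are in the 35–46% range). The generator is an
idealisation — no physiological noise, no motion, no spatial pattern
structure, perfectly stable patterns across 20 repetitions — so passing
tests demonstrate that the *pipeline* is correct and calibrated, not that
real-data effect sizes would be reproduced.

## Known limitations

* Ellipsoidal ROIs and unstructured patterns ignore anatomy; Dice QC against
  a jittered re-rasterisation stands in for true inter-rater variability.
* The single best sphere is used per fold; a union-of-top-k variant is a
  plausible alternative the interface does not currently expose.
* The RM-ANOVA is the classical univariate form; with n = 9 and 2 × 3 cells
  sphericity violations are plausible and only the optional
  Greenhouse–Geisser correction addresses them.
* Voxel indices are 1-based throughout, following R array conventions.
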