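---
title: "Parcellating the auditory voice area with acoustic equivalents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parcellating the auditory voice area with acoustic equivalents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaparc)
```

## The scientific question

A large region of human auditory cortex — the "voice area" (VA) — responds
more strongly to voices than to other sounds. Whether that preference
reflects genuine voice processing or merely sensitivity to the acoustic
features that happen to distinguish voices from nonvoices cannot be decided
from the voice-versus-nonvoice contrast alone. The strategy implemented here
attacks the confound with *acoustic equivalents* (AEs): synthetic control
sounds, derived from each original voice or nonvoice token, that preserve
exactly one acoustic property of the original while destroying its identity:

* **e_s** — envelope/spectrum chimeras: the original's Hilbert envelope
  imposed on white noise, summed with noise carrying the original's Fourier
  magnitude spectrum;
* **scr** — temporally scrambled sounds: short segments permuted within
  local windows, separately per frequency band, preserving long-run spectral
  content;
* **p_a** — pitch/amplitude sounds: a sinusoid following the original's F0
  contour plus noise modulated by its intensity envelope;
* **rip** — dynamic moving ripples matched to the original in jitter,
  shimmer and spectral-flux statistics;
* **tsp** — Gaussian sound textures matched to the original in
  harmonics-to-noise-ratio (HNR) statistics.

Each AE inherits the voice/nonvoice label of its source, so the same
[voice > nonvoice] contrast can be run on every sound set. Three subfields of
the VA are then defined:

* the **core VA**: voxels where the voice preference for original sounds
  exceeds the analogous preference for *every* AE class — a
  minimum-statistic conjunction over the five interaction contrasts
  [(ORIGvoice − ORIGnonvoice) − (AEvoice − AEnonvoice)], intersected with
  the VA;
* the **acoustic VA**: voxels where a linear classifier trained to decode
  voice vs nonvoice from local multivoxel patterns of the *original* sounds
  generalizes to the AEs (searchlight cross-classification, maps averaged
  over the five AE classes), restricted to the VA and excluding the core;
* the **accessory VA**: the remainder of the VA.

No public data exist for this design, so the package ships a synthetic-data
generator that emulates the statistical structure the analysis assumes, with
known ground truth; every downstream stage is exercised against it.

## The synthetic cohort

`gen_ground_truth()` places one blob per class per hemisphere on a
20 × 20 × 12 voxel grid (2.75 mm isotropic, split into hemispheres along the
first axis). Defaults: core 5%, acoustic 4%, accessory 8% of the grid, with
at least two voxels of empty space between blobs of different classes and
from the hemisphere split — the margin guarantees that a 5 mm searchlight
(which dilates detection by one voxel ring) cannot carry one region's
evidence into another region's mask, so recovery scores measure the pipeline
rather than geometry.

`gen_subject_betas()` turns the ground truth into run-level condition
amplitudes (12 conditions = 6 sound sets × voice/nonvoice):

* **core** voxels: amplitude `effect` for original voice only;
* **accessory** voxels: `effect/3` for original voice, `effect/6` for the
  e_s and scr voice conditions;
* **acoustic** voxels: signed weights `±(effect/2)·v_i` (with per-voxel
  `v_i ~ U(0.5, 1.5)`) on the voice/nonvoice conditions of the original,
  e_s and scr sets — the *same* pattern across the three sets. Because the
  weights are positive, these voxels also carry a univariate voice
  preference shared by the three sets: they sit inside the univariate VA,
  are excluded from the core (their interactions against e_s and scr vanish
  identically), and support cross-decoding — the dissociation that defines
  the acoustic subfield;
* **null** voxels: zero.

Each subject draws one Gaussian amplitude offset per class (SD
`subject_sd`, default 20% of `effect`) applied along the class profile, so
group t-tests and Cohen's d have realistic between-subject variance; run
noise is i.i.d. Gaussian (`noise_sd`, default 0.5). Defaults: 25 subjects,
8 runs. What the generator does *not* emulate: anatomical misalignment
across subjects, spatial and temporal noise correlations, scanner drift and
motion. Passing recovery tests therefore demonstrate the correctness of the
analysis logic under the assumed model, not robustness to real fMRI
artifacts.

A consequence of the effect profile worth stating plainly: accessory voxels
have *weaker but nonzero* interactions against every AE, so the
core/accessory boundary is a power criterion, not a structural one — exactly
as in the analysis it emulates, where the accessory field is defined as the
VA remainder at a fixed threshold. Recovery is therefore asserted under the
default study conditions; at arbitrarily high SNR the conjunction would
legitimately absorb accessory voxels.

## Experiment schedule and GLM

`build_schedule()` reproduces the block design: 8 runs of 315 s, 12
mini-blocks per run (one per condition, randomized order), 9 sounds of
500 ms per block, inter-sound gaps jittered in 0.8–1.2 s, 15 s silence
between blocks, and 24 of the 96 blocks containing one immediate sound
repetition (the 1-back task; a button-press event follows each). The stated
timing is mutually consistent only when the 15 s gaps fall *between* blocks
(11 per run) and each block averages 12.5 s; gaps are drawn antithetically
(pairs `u`, `2 − u`) so each block lasts exactly 12.5 s and each run exactly
315 s while individual gaps remain jittered.

`build_design()` convolves condition boxcars with the canonical two-gamma
haemodynamic response (gamma shapes 6 and 16, undershoot ratio 6) sampled at
TR 1.6 s over 197 volumes: 13 task columns (12 conditions + button press),
optional 6 motion columns, and 18 RETROICOR-style columns — sine/cosine
Fourier expansions of cardiac phase (order 3), respiratory phase (order 4)
and their sum/difference phases (order 1). `fit_glm()` is ordinary least
squares with rank checking.

Group inference replaces the original SPM factorial machinery with
per-voxel one-sample t-tests (one-sided) over subject-level contrast images,
Bonferroni family-wise correction over in-grid voxels (default α = 0.05),
uncorrected p < 0.001 and Benjamini–Hochberg FDR as alternatives. Random-field
theory and AR prewhitening are deliberately out of scope: the synthetic noise
is white and unsmoothed, so Bonferroni is exact (conservative only under
smoothing).

Smoothing defaults: `group_contrast()` uses the 8 mm FWHM kernel of the
mapping analyses (4 mm for the replication setting), but the end-to-end
recovery pipeline (`run_va_pipeline()`) uses 0 mm. The synthetic cohort has
no inter-subject misalignment, so smoothing could only dilate masks and bias
voxel-level recovery scoring; this was fixed at design time.

The voice-selectivity criterion is also implemented: per subject and voxel,
condition betas are rescaled so original nonvoice maps to 0 and original
voice to 1; a voxel is "voice-selective" when all ten AE conditions stay
strictly below 1/3 (the 66% criterion; strict inequality adopted — the
boundary convention is not documented in the source analyses). The scaling
is affine-invariant by construction; zero-denominator voxels are excluded
and counted rather than clipped.

## Searchlight MVPA

Patterns are run-level betas: one voice and one nonvoice pattern per run per
sound set (16 samples for 8 runs). `searchlight_indices()` enumerates, for
each voxel, all voxels within 5 mm of its centre (19 voxels in the interior
of a 2.75 mm grid). Decoding uses a linear support-vector machine with
C = 1; features are standardized per fold using training data only (this
makes accuracies invariant to voxel-wise affine rescaling). The inner solver
is a compact dual-coordinate-descent implementation in C++ (the bias handled
as an augmented regularized feature) — a full cohort needs on the order of a
million fits, and the test suite pins its predictions against an independent
SVM implementation. Ties at the decision boundary deterministically predict
the nonvoice class, so degenerate all-zero neighbourhoods score exactly
chance on balanced folds.

Cross-validation is leave-one-run-out (8-fold, balanced by construction);
cross-classification trains once on all original-sound patterns and tests on
one AE class. Group maps are one-sample t-tests of (accuracy − 0.5). The
five cross-classification group maps are averaged voxel-wise (t winsorized
at |t| ≤ 100 so zero-variance voxels stay finite) and the threshold applied
to the average using the component maps' t reference distribution — an
approximation adopted in place of the original random-field machinery; it is
conservative for the null voxels that matter (the mean of five null t-maps
has variance ≈ 1/5 of a single map's under independence).

ROI utilities mirror the region-level analyses: a packaged toy atlas (five
named slabs per hemisphere standing in for cytoarchitectonic maps — clearly
synthetic; real label volumes can be substituted), subject-level functional
patches (top-10 local maxima on 26-connectivity, each reference coordinate
assigned its nearest peak, fallback to the reference when no peak exists or
centres come closer than 10 mm, 5 mm spheres, every fallback logged), and an
accuracy table with BH-FDR across all ROI × scheme cells.

## Parcellation and scoring

`assemble_parcellation()` enforces the explicit set algebra: core and
acoustic must be disjoint subsets of the VA; accessory is the remainder;
when a voxel qualifies for both core and acoustic, core wins (the precedence
is not documented in the source analyses; the published accessory
percentages are inconsistent with the published counts, which suggests an
undocumented overlap convention — this package enforces the disjoint
partition and reports percentages as `100 × count / n_VA`, rounded half-up
to one decimal). Effect sizes are group Cohen's d of the per-subject mean
(voice − nonvoice) beta difference over each subfield's voxels.

## Worked sizes and numerical choices

* Grid 20 × 20 × 12 at 2.75 mm; searchlight radius 5 mm; 25 subjects ×
  8 runs for the full cohort. The full pipeline runs in roughly one to two
  minutes on one CPU; tests use a 12 × 12 × 8 grid with 12 subjects where
  full scale is not required, and permutation-null calibration uses a
  10 × 10 × 6 null grid over 20 seeds.
* Ripple pools sample velocity 1–30 Hz and density 0.25–4 cyc/oct
  log-uniformly, depth 0.2–1 uniformly (ranges are not documented in the
  source analyses; these cover the modulation ranges relevant to cortical
  tuning). Texture pools sample temporal and spectral correlation lengths
  log-uniformly in [0.01, 2]. The full-scale pools have 10,000 members;
  tests and the acceptance script use smaller pools since matching quality
  enters only through the feature space, whose dimensionality is fixed.
* Pool matching z-scores each feature over pool ∪ probe, making distances
  scale-free; ties break to the lowest member index.
* "Sine-wave rectified pitch contour" is read as the F0 contour with
  unvoiced gaps linearly interpolated, rendered as a sinusoid by phase
  accumulation; the alternative reading (half-wave rectified carrier) was
  rejected as inconsistent with a sine-wave rendering.
* 70 dB SPL has no absolute digital meaning; the package fixes the
  reference RMS 0.05 (full scale) ↔ 70 dB and scales other levels linearly.
  Finalization errors out rather than clip when the headroom check fails.
* Scramble defaults: 25 ms segments, 250 ms local windows, 8 log-spaced
  bands, quarter-segment raised-cosine crossfades with window-sum
  normalization (so the degenerate single-segment scramble is exact).
* The 88 acoustic features are this package's documented set (14 frame-wise
  descriptors × 6 functionals + 4 global descriptors), not a bit-for-bit
  replica of any external toolbox: the downstream claims depend on relative
  accuracies between sound sets, not absolute feature values. Frame
  statistics undefined on a frame are imputed as 0, with the voiced fraction
  recording the imputation rate for the periodicity family. HNR uses the
  autocorrelation-peak formula `10·log10(r/(1−r))` with the Hann window's
  own autocorrelation divided out (without the correction a pure tone
  saturates near 15 dB; with it, calibration against analytic
  harmonic-plus-noise constructions is within ±2 dB over the 4–12 dB range,
  degrading above ~15 dB where `r → 1`).
* The sound-level SVM uses the third-order polynomial kernel with default
  cost 1 and stratified folds; box constraint and feature scaling follow the
  library defaults since the source analyses do not document them.

## Known limitations

The generator's independence assumptions (white noise, no spatial
autocorrelation) make Bonferroni exact and recovery clean; real data would
require random-field or permutation-based correction and motion/physiology
preprocessing, all of which are out of scope. The averaged-cross-map
threshold is an approximation, conservative under the null. The accessory
subfield is defined relative to the chosen threshold, so its extent — unlike
the core and acoustic subfields at the default conditions — is inherently
power-dependent. Acoustic-equivalent synthesis aims at the statistical
structure of each control class, not perceptual indistinguishability from
any particular published stimulus set.
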