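# vaparc

Functional parcellation of the auditory cortical "voice area" (VA) into
core, acoustic and accessory subfields, with a fully synthetic, seeded test
bed.

## The problem

Auditory cortex responds more strongly to voices than to other sounds over a
large territory — but a voice-versus-nonvoice contrast cannot tell genuine
voice processing apart from sensitivity to the acoustic features that
distinguish the two sound classes. The approach implemented here derives,
for every original voice and nonvoice sound, five *acoustic equivalents*
(AEs) that each preserve a single acoustic property while destroying the
sound's identity — envelope/spectrum chimeras (`e_s`), temporally scrambled
sounds (`scr`), pitch/amplitude-contour sounds (`p_a`), dynamic moving
ripples matched on jitter/shimmer/spectral-flux (`rip`), and Gaussian sound
textures matched on harmonics-to-noise-ratio statistics (`tsp`) — and keeps
the voice/nonvoice label of the source, so the same contrast runs on every
sound set.

Three subfields of the VA are then defined:

* **core VA** — conjunction over the five interaction contrasts
  `(ORIGvoice − ORIGnonvoice) − (AEvoice − AEnonvoice)`: voice preference
  that no acoustic property explains;
* **acoustic VA** — searchlight cross-classification: local multivoxel
  patterns trained to decode voice vs nonvoice on original sounds
  generalize to the AEs (averaged over the five classes), within the VA and
  excluding the core;
* **accessory VA** — the remaining VA voxels.

The package covers the whole pipeline: sound synthesis and the five AE
transformations; an 88-slot acoustic feature set with polynomial-kernel SVM
(cross-validation and cross-classification); the block experiment schedule,
canonical-HRF design matrices with motion and RETROICOR-style physiological
regressors, and voxel-wise GLMs; group contrasts, conjunctions and the 66%
voice-selectivity criterion; fast linear-SVM searchlight decoding
(leave-one-run-out and cross-classification); ROI analyses; and the final
parcellation with per-hemisphere coverage and Cohen's d. Because no data
are deposited for this design, a seeded synthetic-cohort generator with
ground-truth voxel classes makes every stage testable end to end.

## Worked example

Generate the default synthetic study (20 × 20 × 12 grid at 2.75 mm,
25 subjects × 8 runs, effect 1.0, run noise 0.5) and run the full pipeline:

```r
library(vaparc)

gt <- gen_ground_truth(seed = 3)                       # 20 x 20 x 12 default grid
cohort <- gen_subject_betas(gt, effect = 1, noise_sd = 0.5,
                            n_runs = 8, n_subjects = 25, seed = 11)
res <- run_va_pipeline(cohort)

res$parcellation
#> <va_parcellation>
#>   hemisphere n_original n_core n_acoustic n_accessory percent_core
#> 1       left        381    120         96         165         31.5
#> 2      right        377    120         95         162         31.8
#>   percent_acoustic percent_accessory
#> 1             25.2              43.3
#> 2             25.2              43.0
```

Roughly a third of the detected VA survives the interaction conjunction
(core), a quarter carries AE-generalizable patterns (acoustic), and the
rest is accessory — percentages are per hemisphere, relative to the
original VA mask. Against the known ground truth:

```r
score_recovery(res$parcellation, gt)
#>       class   jaccard    recall precision
#> 1      core 1.0000000 1.0000000 1.0000000
#> 2  acoustic 0.9947917 0.9947917 1.0000000
#> 3 accessory 0.8467532 0.8489583 0.9969419
```

Core and acoustic voxels are recovered essentially exactly; accessory
recall (~0.85) is bounded by the weak `effect/3` amplitude of that class at
the family-wise threshold, and no null voxel is labeled. Effect sizes show
the signature dissociation — the core's voice preference collapses for the
AEs while the acoustic subfield's does not:

```r
subset(res$effect_sizes, sound_set %in% c("orig", "e_s"),
       c(subfield, sound_set, cohens_d))
#>    subfield sound_set     cohens_d
#> 1      core      orig  5.831933799
#> 2      core       e_s -0.009209319
#> 3  acoustic      orig  2.715885958
#> 4  acoustic       e_s  2.719228199
#> 5 accessory      orig  2.365163365
#> 6 accessory       e_s  2.354732757
```

Sound-side utilities work the same way:

```r
toks <- gen_sound_set(70, 70, seed = 1)     # 140 tokens, 500 ms @ 16 kHz
ae   <- synth_env_spec(toks[[1]], seed = 2) # envelope/spectrum chimera
feat <- feature_table(toks)                 # 140 x (4 + 88) tibble
classify_sounds_cv(feat[, -(1:4)], feat$category, n_folds = 5, seed = 1)
```

`autoplot(res$parcellation)` draws the subfield slices and
`plot_effect_sizes(res$effect_sizes)` the Cohen's d profile.

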