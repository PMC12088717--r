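---
title: "Auditing demographic bias in cardiac MR segmentation with ground-truth phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing demographic bias in cardiac MR segmentation with ground-truth phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

Convolutional segmentation models for short-axis (SAX) cine cardiac MR can
perform differently for different demographic groups when the training set is
imbalanced. Diagnosing *why* is hard on real cohorts: the distributional
differences between groups are unknown, entangled (body composition,
acquisition protocol, covariates), and the data are access-controlled. The
audit questions one wants to answer are:

1. Is the between-group shift carried by the images, the expert
   segmentations, or both?
2. Where in the image does the shift live — in the heart, in non-heart
   anatomy such as subcutaneous fat, or in acquisition artefacts?
3. Is group membership encoded in the internal representations of a trained
   segmentation model?
4. Does cropping the images tightly around the heart remove the bias?
5. Are apparent covariate confounders of segmentation quality genuine
   mechanisms or selection accidents?

`cmraudit` turns each question into a testable property by replacing the
real cohort with a synthetic two-group phantom cohort in which the location
and magnitude of **every** group-level difference is chosen by construction
(a `shift_config`). If the audit machinery is sound, it must recover the
injected answers; on a null configuration it must find nothing.

## The phantom generator

Each subject is a 2D SAX slice rendered at end-diastole (ED) and end-systole
(ES) on a square grid (default 96 x 96; geometry is defined in relative
units, so other sizes rescale proportionally):

* a body ellipse (intensity 0.35) with a subcutaneous **fat ring** at its
  boundary (0.72, the brightest extended structure after the blood pools),
* two lung fields (0.12),
* the heart: LV blood pool disc (LVBP, 0.85, label 1), myocardial annulus
  (LVM, 0.3, label 2), and an RV blood-pool crescent (RVBP, 0.8, label 3);
  at ES the blood pools contract radially (default factor 0.75) with the
  epicardial border fixed, emulating wall thickening,
* optional **ghosting artefacts**: `n` attenuated copies of the fat ring
  displaced by `k * spacing` pixels along the phase-encode axis with
  amplitude `a^k`, as produced by periodic acquisition errors,
* Rician noise (magnitude of a complex Gaussian, sigma 0.02), the correct
  noise model for MR magnitude images.

Ground-truth label masks and *auxiliary* masks (fat ring, body, ghost-echo
support) come out of the renderer for free; the auxiliary masks are what the
attribution taxonomy is scored against. Echo contributions that land back on
the ring itself are suppressed — they would be invisible against it, and
leaving them out keeps each image's intensity maximum (the min–max
normalization reference) on the same structure in every subject.

Covariates (age, height, weight, BMI, heart rate, LVSV, LVEF, LVEDM,
comorbidity flags, MRI year) are drawn from per-group tables whose
age/height/weight/BMI defaults follow published characteristics of
race-matched two-group population cine CMR cohorts; weight is derived from BMI and
height so records are internally consistent. Two linear couplings link
covariates to the image: BMI deviation (from the subject's own group mean)
to fat-ring thickness, and LVEDM deviation to myocardial thickness. Because
the couplings are group-centred, they create within-group variation and
Table-5-style confounding scenarios without silently adding between-group
image shifts — those are *only* produced by the explicit deltas of the
`shift_config`.

### The default shifted configuration

`shift_config_shifted()` encodes the study condition used throughout the
audits, chosen once while designing the generator:

* group B: fat ring +1.5 px thicker and +0.05 brighter (body-composition
  difference);
* both groups 90% ghosted, but with different phase-encode axes (A: columns,
  B: rows) and different severities (first-echo amplitude 0.65 vs 0.45) —
  an acquisition-protocol difference;
* identical heart geometry (`heart_shape_delta = 0`): every group signal is
  outside the heart.

Three properties of this choice matter and are worth stating explicitly:

* **The normalization reference is stable.** Fat stays below the LVBP
  intensity, so per-image min–max normalization always references the same
  structure. Shifts therefore survive heart-blurring (the blur sigma of 2 px
  removes heart texture without destroying the LVBP peak), which is what the
  blur intervention needs to demonstrate.
* **Each group has clutter the other lacks.** Artefact patterns that differ
  in axis and severity are mutually out-of-distribution. A model trained on
  one group degrades on the other in *both* directions, which is what makes
  the majority-group Dice advantage appear symmetrically at the 100%/0% and
  0%/100% imbalance extremes. A presence/absence artefact difference (one
  group clean, one ghosted) produces only a one-sided bias: models trained
  on the artefact-bearing group segment clean images perfectly well.
* **Everything is excluded by a tight heart crop.** Ring and echo bands are
  placed so that the union bounding box of the heart (plus a 2 px margin,
  rounded up to a multiple of 4) contains neither, so the crop intervention
  removes the shift essentially completely.

What the phantom deliberately does **not** emulate: 3D slice stacks,
realistic bSSFP contrast physics, k-space-accurate artefacts, anatomical
texture within tissues, or annotator variability in the ground-truth masks
(the segmentation channel is exactly the rendering geometry). Passing audits
on phantoms therefore validates the *machinery* — that each audit detects
exactly the mechanism injected and nothing under the null — not the claim
that any particular real-world cohort shifts in these ways.

## The audit components

**Channel-combination classification.** A small residual CNN (stem
average-pool, one residual block, 8/16 channels, global average pooling)
classifies group from 3-channel inputs assembled as Im-Im-Im, Im-Im-Seg,
Im-Seg-Seg or Seg-Seg-Seg, where Im channels are min–max-normalized images
and Seg channels encode labels \{0..3\} as \{0, 1/3, 2/3, 1\}. Each audit is
repeated (default 10 runs, 5 in the desk-scale acceptance settings) with
per-run train/validation resampling at subject level, and reported as mean
(SD) accuracy/sensitivity/specificity with group B as the positive class
(the convention is stated because sensitivity/specificity are otherwise
ambiguous). Arms are compared with a two-tailed Student's t-test on the
per-run accuracies; if both arms are constant with different means the
p-value is reported as 0 (the limit of the t statistic), and constant equal
arms are an error.

**Interventions.** `crop_to_heart()` cuts a fixed-size window — the
per-axis maximum bounding box over the *training* masks only, reused for
test data to avoid leakage — centred on each subject's ED∪ES heart box and
shifted (never shrunk) at image edges. `blur_heart()` writes a
Gaussian-blurred copy into foreground pixels only; background stays
bit-identical. Normalization is recomputed after the intervention, as it
would be in any real preprocessing pipeline; this matters, because in-crop
renormalization is precisely what removes reference-shift signal.

**GradCAM + region taxonomy.** GradCAM is computed from scratch: channel
weights are the spatial means of the target-class score gradient at the last
convolutional layer, the map is the rectified weighted activation sum,
bilinearly upsampled and max-normalized. Attribution targets each image's
*predicted* class by default (the standard convention; a fixed-class mode
exists). The peak pixel is classified against the generator's ground-truth
masks with precedence artefact > heart > non-heart body > other, ties broken
in row-major order; a mass-fraction criterion (≥ 50% of heatmap mass) is
available as an alternative. This replaces the visual inspection a human
reader would do, and is validated against an analytic closed form on a
one-layer toy model.

**Segmentation + imbalance sweep.** A small U-shaped encoder–decoder
(widths 8/16/32, skip connections, 1x1-conv head) is trained with combined
cross-entropy + soft-Dice loss under a poly learning-rate schedule, once per
imbalance fraction (100/75/50/25/0% group B) on nested subsets of fixed
pools, evaluated on a constant balanced test set. Subject-level DSC is the
mean over the six label-frame combinations (3 foreground labels x ED/ES; a
pooled-foreground option exists), groups are compared per fraction with a
two-sided Mann–Whitney U test (exact where applicable), and the whole sweep
runs on original or cropped inputs.

**Latent probe.** The decoder is discarded; bottleneck feature maps are
global-average-pooled to one vector per test image, reduced by PCA (default
10 components), and probed with logistic regression under stratified 5-fold
cross-validation within the test set. Folds are *subject-atomic*: a
subject's ED and ES latents are highly correlated, and letting them straddle
folds allows the probe to retrieve a subject's label through its other
frame, which inflates even null-cohort probe accuracy well above chance.
The probing protocol is stated in this detail because fitting and
evaluating probes on the same latents without (grouped) cross-validation
overstates decodability.

**Confounder statistics.** Per-covariate cohort tables with two-tailed
t-tests, and a single joint OLS of subject DSC on all covariates
(standardized betas = coefficient x SD(covariate)/SD(DSC), sample-SD
convention; binary covariates standardized like numeric ones; zero-variance
covariates flagged and dropped rather than fitted, mirroring what happens
when, say, no subject of one group has diabetes). A univariate mode exists
for comparison. Because regression validity is a statistical question, it is
validated on mechanism-simulated DSC outcomes
(`simulate_dsc_outcomes()`: DSC = base + sum of injected standardized
effects + noise) rather than on expensive end-to-end segmentation runs:
sign recovery of injected effects in ≥ 90% of replicates, and a nominal
false-positive rate under the null.

## Training at desk scale

There is no deep-learning framework in the dependency stack; convolutions,
pooling, upsampling and backpropagation are implemented in the package
(im2col + GEMM via RcppArmadillo) and verified against numerical
differentiation in the test suite. All randomness flows through R's RNG, so
every cohort, split, and trained model is bit-reproducible from a seed.

Scaled-down defaults are used so a full audit runs in minutes on one CPU:

| component | defaults |
|---|---|
| classifier | Adam, lr 0.002, 12 epochs, batch 16, decay x0.1 at 3/4 |
| segmenter | Adam, lr 0.005, 25 epochs, batch 4, poly decay (0.9) |
| augmentation | mirror + integer translate (±3 px); optional small rotations |
| cohorts | 100/group at 96 px (classification), 26/group at 64 px (sweeps) |

Adam is the default optimizer because within these small step budgets plain
SGD frequently stalls on its initial plateau; the published full-scale
recipes (SGD momentum, 100-epoch classifier, 500-epoch segmenter) remain
available through `classifier_hyper(optimizer = "sgd")` and
`segmenter_hyper(optimizer = "sgd")`. Classifier inputs are zero-centred at
the stem and zero-padded to a multiple of 8 internally, so tight crop
windows (multiples of 4) need no special handling.

## Numerical and design choices worth knowing

* Min–max normalization errors on constant images rather than guessing.
* Dice is 1 by convention when a label is absent from both masks (never
  triggered by default phantoms, which always contain all structures).
* Greedy nearest-age matching within sex (±1 year), ties broken at random
  under the caller's seed; unmatched subjects are reported and excluded.
  Odd group sizes assign the extra subject male.
* Fractional imbalance subset sizes round half away from zero with group A
  absorbing the remainder, keeping the total train size constant.
* Fat-ring thickness saturates at 9.5% of the grid so extreme BMI draws
  remain renderable with the ring clear of the heart.
* The crop reference box is the union over a subject's ED and ES masks, so
  both frames share one window.
* An all-zero attribution map is labelled "other".

## Limitations

The phantoms are 2D, piecewise-constant, and single-slice; absolute DSC or
accuracy values have no clinical meaning here — only the *contrasts* the
audits are designed around (images vs segmentations, original vs cropped vs
blurred, shifted vs null) are interpretable. The bias magnitudes produced by
the default `shift_config_shifted()` are free parameters of the simulation,
not estimates of any real cohort's shift. The confounder module validates
statistical recovery, not the full image-to-DSC causal chain at scale.

## Running the pieces

```{r}
library(cmraudit)

cohort <- generate_cohort(100, shift_config_shifted(), seed = 1)
pairs <- match_pairs(cohort$covariates)
split <- split_pairs(pairs$pairs, n_test_pairs = 24, seed = 1)

audit <- repeat_audit(cohort$subjects[split$train_ids],
                      cohort$subjects[split$test_ids],
                      combo = "iii", n_runs = 5, base_seed = 1)
audit

report <- run_full_audit(audit_config(seed = 1))
```

`run_full_audit()` chains every stage (cohort, channel audits, crop/blur,
attribution taxonomy, imbalance sweeps on original and cropped inputs,
latent probes, confounder tables) and records the config and all derived
seeds in the returned bundle, so rerunning with the same config reproduces
every number exactly.
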