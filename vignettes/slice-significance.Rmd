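---
title: "Mapping progression-informative brain regions from slice-level classifier ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping progression-informative brain regions from slice-level classifier ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slicesig)
```

## The scientific problem

In multiple sclerosis, a central clinical question is whether a patient's
disability will progress. Disability is measured with the Expanded Disability
Status Scale (EDSS), a 0--10 half-point scale, at a baseline visit and a
follow-up visit. The imaging question this package addresses is: *which parts
of the brain carry MRI-visible information that predicts progression?* Rather
than fitting one whole-brain model and inspecting it, the approach is
deliberately localized: the brain is cut into two-dimensional slices along the
three orthogonal projections, a classifier is trained on each group of
neighbouring slices, and a slice is declared *informative* only when its
classifier beats a matched label-permutation null model by a formal statistical
test. The informative slices from the three projections are then intersected
into a three-dimensional voxel map.

All coordinates in the package are **0-based voxel indices** on the 2 mm MNI
grid (91 × 109 × 91 voxels); `mni_affine_2mm()` gives the voxel-to-millimetre
mapping. The choice of 0-based indices is a design decision — slice coordinates
in the neuroimaging tooling this mirrors (FSL and friends) are 0-based, and
this way a reported coordinate can be pasted directly into standard viewers.

## Progression labels

A patient is labeled *progressed* when the follow-up EDSS exceeds the baseline
by a baseline-dependent threshold: 1.5 points from a baseline of 0, 1.0 point
for baselines 1.0--5.0, and 0.5 points for baselines of 5.5 and above.

```{r labels}
progression_threshold(c(0, 2.5, 6))
progression_label(edss_baseline = c(0, 3.5, 4.0), edss_followup = c(1.5, 4.5, 4.5))
```

A baseline of 0.5 sits between the stated branches of the rule. The package
assigns it the middle (1-point) threshold and emits a warning, so the case is
handled deterministically but never silently.

Comparisons are `increase >= threshold` with a tolerance of `1e-8`, because
EDSS values arriving through CSV round-trips can carry floating-point dust;
an exact half-point increment must count as reaching a half-point threshold.

## Volume preparation and slab geometry

Input volumes are assumed registered to MNI space. `normalize_intensity()`
rescales each volume linearly so its maximum is 255 (zero stays zero), which
removes scanner-dependent global intensity scale. `slice_volume()` then cuts a
volume along one projection into the analysis range of that projection — 79
coronal, 64 sagittal, and 62 axial slices — and assigns each slice to one of
four *slabs*, contiguous coordinate bands:

```{r slabs}
slab_definitions()
```

Slabs exist for a statistical reason: a single slice gives one training image
per patient, far too few to train an image classifier, while pooling a whole
projection would destroy localization. Four bands per projection is the
compromise — each slab-level classifier sees all of a patient's slices within
the band (tens of images per patient), yet its validation scores can still be
broken out per slice coordinate afterwards.

A slice enters the analysis only if **at least 10% of its own pixels are
non-zero**. The inclusion rule could also have been read as "10% of the
volume's non-zero voxels fall on this slice"; the per-slice reading is
implemented because it is scale-free (it does not depend on how many slices
the brain spans) and matches the intent of discarding near-empty edge slices.
The threshold is exposed as `min_nonzero` in `slice_volume()`.

`export_slices()` writes slices either as lossless tab-separated arrays (the
form the analysis consumes) or as 224 × 224 8-bit PNG images with bilinear
upsampling and a linear contrast stretch, the form consumed by pretrained
image-classification backbones.

## The replica ensemble

`fit_slice_ensemble()` is the modelling core. The cohort is split into many
*replicas* — stratified random train/validation splits with the class ratio
preserved on both sides (per class, `round(fraction * n)` patients go to
training). At the reference design, 181 patients (119 stable / 62 progressed)
yield training sets of 163 (107/56) and validation sets of 18 (12/6), and 100
replicas are drawn. Replicas overlap; the ensemble's purpose is to measure how
stable each slice's discriminative signal is under resampling, not to build
one best classifier.

Training is two-step:

1. **Slab-location pre-training.** A 4-class classifier is first trained to
   recognize which slab a slice comes from. Its class probabilities are
   appended to the pixel features of every slice. This injects coarse
   anatomical-position awareness into the binary discriminators — the analog
   of giving an image backbone a brain-specific warm start.
2. **Per-slab binary discriminators.** For every (replica, projection, slab)
   cell, a binary classifier is trained on the training patients' included
   slices and scored on the validation patients' slices.

Alongside every real discriminator, a **null twin** is trained: the same
images, the same architecture, the same split, but with the *training* labels
randomly permuted (class counts preserved). Validation labels are left intact,
so a null model's validation AUC estimates what the pipeline produces when the
images carry no usable class information.

The classifier backbone is pluggable via the `slice_classifier` interface (a
`fit(x, y)` / `prob(model, x)` pair). The default is a ridge-penalized
logistic model on 8 × 8 block-mean-pooled pixel intensities
(`ridge_classifier()`). A deep convolutional backbone can be dropped in
without touching any statistical machinery; the statistics downstream are the
contribution here, not the backbone.

## AUC, the admissibility band, and DeLong's test

Validation scores are summarized per slice by the area under the ROC curve,
computed by the Mann--Whitney midrank formula: tied score pairs count ½
(`auc_mw()`). `auc_table()` aggregates AUC per (replica, projection, slab,
coordinate, model kind); `summarize_distribution()` reports quartiles using
the standard type-7 quantile definition and flags outliers by the strict
1.5 × IQR rule.

With a small validation set the AUC is a coarse statistic. For $m$ positives
and $n$ negatives its smallest possible nonzero change is
$\delta = 1/(m \cdot n)$ — at 6/12 this is:

```{r delta}
auc_granularity(6, 12)
```

A null model is **admissible** only when its AUC lies within $0.5 \pm \delta$
(checked with a `1e-12` epsilon so boundary values on either side of a
floating-point representation artefact are not misclassified). An inadmissible
null — one that itself drifted away from chance — cannot serve as a reference,
so its real twin is not eligible for selection regardless of its own AUC.

The real-vs-null comparison uses **DeLong's test for paired (correlated) ROC
curves**, implemented from the placement-value formulation in
`delong_test()`. The statistic is kept **signed**, $Z > 0$ meaning the real
AUC exceeds the null AUC, and selection demands the towards-1 direction
explicitly: a real model *below* its null is never selected, however large
$|Z|$ is. Each real model is compared to its **index-matched** null twin (same
replica, same slab), not to a pooled null distribution — the pairing is what
makes the correlated-ROC test valid, since both models score the same
validation patients.

Degenerate pairs occur at desk scale: when the variance estimate of the AUC
difference collapses to zero while the difference itself is nonzero (e.g., a
perfect separator against a constant model), the test statistic is undefined.
Such pairs are flagged `untestable` and never selected; they are not silently
assigned $Z = \pm\infty$. Two models that agree exactly give $Z = 0$, $p = 1$.

`selection_records()` applies the full rule per (replica, projection, slab,
coordinate): selected ⇔ null admissible, $Z > z_{crit}$ (default 1.96), and
real AUC above null AUC. No multiple-testing correction is applied — the
permutation nulls and the replica ensemble are the error control, and the
final intersection across three projections is itself a conjunction that
suppresses isolated false positives.

## The three-dimensional intersection map

`intersect_slices()` takes the significant coordinates from the three
projections and forms the Cartesian product: a voxel is in the map when its
sagittal x, coronal y, and axial z coordinates are all individually
significant. Two counting rules are provided because they genuinely differ:

* `product_of_counts` multiplies the *lists'* lengths, counting a slice once
  per significant (replica, slice) combination hosted on it;
* `unique_voxels` deduplicates each projection's coordinates first.

When several replicas flag the same slice the two rules disagree, and
published voxel totals computed this way are typically of the combination
kind. The default is `product_of_counts` for comparability;
`unique_voxels` is the geometrically meaningful count and is what
`export_mask()` materializes as a binary NIfTI mask.

```{r intersect}
vm <- intersect_slices(sig_coronal = 77:81, sig_sagittal = 31:35,
                       sig_axial = rep(42:56, length.out = 15))
vm$count
```

## The synthetic-cohort generator

`generate_cohort()` exists so every stage above is testable without patient
data. Its defaults *are* the reference study conditions: 181 patients,
prevalence 62/181 (34%), the full 91 × 109 × 91 grid, one frontal cuboidal
signal region, and exactly `round(n * prevalence)` positives.

Each volume is zero outside an ellipsoidal brain mask inscribed in the grid.
Inside the mask, intensities are a smooth **anatomy field** — a low-frequency
sinusoidal modulation with distinct frequency and phase per axis — plus
Gaussian noise, clipped to 0--255. The asymmetric field matters: it gives
slices from different slabs distinguishable intensity profiles, as real
anatomy does, so the slab-location pre-training task is learnable (with a
symmetric mask, opposite slabs would be mirror images and location accuracy
would be capped near chance). Progressed patients get a constant intensity
elevation (`effect_size`) inside each signal region. EDSS baseline/follow-up
pairs are constructed to reproduce the truth labels under the progression
rule, so labeling can be exercised end to end.

What the generator does **not** emulate: lesion morphology, spatial noise
correlation, registration error, scanner/site effects beyond a site column,
or any realistic neuroanatomy. It is a statistical test harness — it plants a
known regional class signal and lets you verify the pipeline recovers it (and
recovers *nothing* when `effect_size = 0`) — not a simulator of MS brains.

### Generator and pipeline parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `n_patients` | 181 | cohort size |
| `prevalence` | 62/181 ≈ 0.343 | fraction progressed; positives = `round(n × prevalence)` |
| `grid_shape` | 91 × 109 × 91 | 2 mm MNI voxel grid |
| `signal_regions` | box (30,77,42)--(60,95,56) | 0-based voxel corners, inclusive |
| `effect_size` | 30 | intensity offset for progressed patients (0--255 scale) |
| `noise_sd` | 20 | additive Gaussian noise s.d. (0--255 scale) |
| `base_intensity` | 120 | anatomy-field scale (0--255 scale) |
| `n_replicas` | 100 | stratified train/validation splits |
| `train_fraction` | 163/181 ≈ 0.9 | per-class `round(fraction × n)` to training |
| `min_nonzero` | 0.10 | slice-inclusion pixel fraction |
| `z_crit` | 1.96 | one-sided selection threshold on the signed DeLong Z |
| `delta` | 1/(n_pos · n_neg) | null-AUC admissibility half-width |

## Running the pipeline

`run_pipeline()` chains the stages — labeling, normalization, slicing,
ensemble training, AUC analysis, selection, mapping — and writes a report
directory (predictions, AUC and selection tables as CSV, a JSON summary, and
the significant-voxel mask as NIfTI). A desk-scale run:

```{r pipeline, eval = FALSE}
cfg <- generator_config(n_patients = 90, prevalence = 1 / 3,
                        effect_size = 60, noise_sd = 15,
                        signal_regions = list(
                          signal_region(c(30, 40, 42), c(60, 70, 56))),
                        seed = 7)
cohort <- generate_cohort(cfg)
report <- run_pipeline(cohort,
                       config = pipeline_config(projections = "axial",
                                                n_replicas = 12, seed = 11))
summary(report)
```

The full 100-replica, three-projection design at n = 181 is the same code
with the defaults; the desk-scale sizes used throughout the examples and the
test suite are this package's own choice to keep a complete run in seconds.

## Numerical conventions, collected

* AUC by Mann--Whitney midranks; ties contribute ½ per tied pair.
* Quartiles and whisker statistics use the type-7 (default R) quantile;
  outliers by the strict `> 1.5 × IQR` rule.
* Threshold comparisons in the progression rule are `>=` with `1e-8`
  tolerance; the admissibility band uses `<=` with `1e-12` epsilon.
* The DeLong Z is signed; selection requires direction, magnitude, and an
  admissible, index-matched null simultaneously.
* Zero-variance, nonzero-difference DeLong pairs are `untestable`, flagged,
  and excluded from selection rather than resolved by convention.
* All slice coordinates are 0-based voxel indices; `intersect_slices()`
  validates them against the per-projection analysis ranges.

## Limitations

The default backbone is a linear model on pooled pixels — sufficient to
detect block-constant planted signal, not representative of what a deep
backbone extracts from real MRI. The generator's noise is i.i.d. per voxel,
which makes planted signals easier to detect than spatially correlated real
signal of equal amplitude. Selection applies no multiple-testing correction,
so isolated per-projection false positives are expected at rates the
permutation nulls quantify; the three-way intersection, replica multiplicity,
and the admissibility band are the intended safeguards. Finally, the slab
partition is fixed a priori; signal straddling a slab boundary is attributed
to whichever slabs host it, with no boundary refinement.
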