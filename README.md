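# slicesig

Slice-level classifier ensembles for mapping brain regions predictive of
disability progression in multiple sclerosis.

## The problem

Disability in multiple sclerosis is tracked with the Expanded Disability
Status Scale (EDSS, 0–10 in half points) at a baseline and a follow-up visit;
a patient has *progressed* when the increase reaches a baseline-dependent
threshold (1.5 points from EDSS 0, 1.0 point from EDSS 1.0–5.0, 0.5 points
from EDSS ≥ 5.5). The question this package answers is spatial: **which parts
of the brain carry MRI-visible information that predicts progression?**

Instead of one whole-brain model, the method is localized by construction.
MNI-registered volumes (2 mm grid, 91 × 109 × 91 voxels, 0-based coordinates)
are intensity-normalized to 0–255 and cut into slices along the three
orthogonal projections (79 coronal, 64 sagittal, 62 axial analysis slices),
grouped into four contiguous *slabs* per projection. For each of many
stratified train/validation *replicas* of the cohort (at the reference design:
100 replicas of 181 patients, 119 stable / 62 progressed, split 163/18 with
the class ratio preserved), a binary classifier is trained per
(replica, projection, slab) — preceded by a slab-location pre-training step
whose class probabilities augment the pixel features — together with a **null
twin** trained on permuted training labels.

Validation performance is summarized per slice by the Mann–Whitney AUC
(ties count ½). A slice–classifier pair is **selected** only when all of the
following hold for its index-matched real/null pair:

- the null AUC lies inside the admissibility band 0.5 ± δ, where
  δ = 1/(n_pos · n_neg) is the smallest nonzero AUC change the validation set
  can express (δ = 1/72 ≈ 0.0139 at 6 positives / 12 negatives);
- the paired DeLong test for correlated ROC curves gives a signed Z above the
  threshold (default 1.96);
- the real AUC exceeds the null AUC (direction is required, not just
  magnitude).

Finally, the significant coordinates of the three projections are intersected:
a voxel enters the 3D map when its sagittal x, coronal y and axial z are each
individually significant. Both voxel-counting conventions
(`product_of_counts` over slice–classifier combinations, and deduplicated
`unique_voxels`) are implemented, since they differ whenever several replicas
flag the same slice.

A synthetic-cohort generator with a planted regional class signal
(`generate_cohort()`) makes every stage testable end to end; its defaults are
the reference study conditions (181 patients, 34% prevalence, full MNI grid).

## Worked example

A desk-scale run: 90 synthetic patients, one planted signal box spanning
axial slices z = 42–56, axial projection only, 12 replicas.

```r
library(slicesig)

cfg <- generator_config(n_patients = 90, prevalence = 1/3,
                        effect_size = 60, noise_sd = 15,
                        signal_regions = list(
                          signal_region(c(30, 40, 42), c(60, 70, 56))),
                        seed = 7)
report <- run_pipeline(pipeline_config(input = cfg, projs = "axial",
                                       n_replicas = 12, seed = 11))
report
```

```
=== slice-ensemble pipeline report ===
cohort: 90 patients, 30 progressed (33%)
slice geometry:
 projection n_slices n_included
      axial       62         62
training: 48 discriminators (+48 null twins)
slab-location accuracy: axial 0.96
<slice_selection> 6 significant (slice, classifier) pairs of 744 tests
  axial: 6 slice(s) at 20, 25, 27, 47, 48, 55 | classifier(s) 4, 9 significant on >1 slice
```

Slices 47, 48 and 55 fall inside the planted z = 42–56 band. The selections at
20, 25 and 27 are isolated chance hits: selection applies no multiple-testing
correction (744 tests here), relying on the permutation nulls, the
admissibility band, replica multiplicity and — in a full three-projection
run — the 3D intersection to suppress them. Rerunning the same configuration
with `effect_size = 0` selects nothing.

The discrete AUC granularity at the reference validation split:

```r
auc_granularity(6, 12)
#> [1] 0.01388889
```

See the vignette source (`vignettes/slice-significance.Rmd`) for the complete
methods account: progression labeling, slab geometry, the replica ensemble,
null models, the δ band and DeLong test, the intersection map, the generator's
design and limitations, and every numerical convention.

## License

MIT (see `LICENSE`).
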