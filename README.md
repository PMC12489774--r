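# voxsift

Scale-invariant keypoint analysis and feature-overlap classification of
3D volumetric images.

`voxsift` is for researchers who want to classify subjects into two
groups from 3D images (its motivating application is sex classification
of registered, skull-stripped T1-weighted brain MRI) *and* to interpret
which local anatomical features drive the classification. Instead of a
fitted black-box model, the classifier is pure feature matching against
a labelled memory, so every decision decomposes into matches between
specific image regions of specific subjects.

## The method

1. **Keypoints.** Each image $I$ is reduced to keypoints — locations
   $(x, y, z)$ and scales $\sigma$ that locally maximize the
   spherically symmetric scale-normalized Laplacian-of-Gaussian
   $\nabla^2 I(x,y,z,\sigma) = \nabla^2 * G(\sigma) * I(x,y,z)$ —
   detected via a difference-of-Gaussians pyramid with sub-voxel and
   sub-scale refinement.
2. **Descriptors.** The neighbourhood of each keypoint is resampled to
   a fixed grid over a ±2σ window (scale normalization) and encoded as
   a 64-element gradient-orientation histogram whose bins are replaced
   by their ranks — invariant to scale and to any monotone intensity
   transform, and optionally to rotation.
3. **Soft-Jaccard overlap.** The similarity of a subject's feature set
   $A$ to a pooled labelled set $B$ is
   $J(A,B) = |A \cap B| / (|A| + |B| - |A \cap B|)$, with the soft
   intersection $|A \cap B| = \sum_i \exp(-d^2(a_i, b_{j(i)})/h^2)$
   summed over nearest-neighbour descriptor matches; geometric
   consistency (location, log-scale) can down-weight implausible
   matches.
4. **Prediction score.**
   $\mathrm{Score}(A) = \log J(A,\mathrm{Female}) - \log J(A,\mathrm{Male})$,
   computed leave-one-out and thresholded at 0. Per-feature affinities
   (log likelihood ratios under kernel densities on descriptors),
   cross-subject feature clustering, and cohort-level evaluation
   (accuracy grids, score continuum, conditional score distributions)
   complete the analysis.

Because real cohorts of this kind are under managed access, the package
includes a synthetic phantom generator (`phantom_spec()`,
`make_cohort()`) that plants ground-truth-known group structure — a
bilateral informative blob pair whose separation and scale differ by
group, weakly-informative blobs shared by random subject subsets, a
global size confound, and subject-private features — so the entire
pipeline is validated end to end against closed-form oracles and
planted effects. See the methods vignette
(`vignettes/feature-overlap-classification.Rmd`) for the model,
parameter choices and limitations.

## Worked example

```r
library(voxsift)

spec <- phantom_spec()
spec
#> <phantom_spec> 48x48x48 @ 2.50 mm; pair sep F/M 16.0/22.0 mm, scale F/M 3.88/4.00 mm; 6 common, 24 pool (p=0.60), 4 private

cohort <- make_cohort(spec, n_per_group = 10, mode = "rigid", seed = 42)
features <- extract_cohort_features(cohort$volumes)
dim(features)
#> [1] 1244   81

predictions <- classify_cohort(features, geometry = TRUE)
predictions[1:4, c("subject_id", "label", "j_female", "j_male", "score", "predicted")]
#>   subject_id label j_female  j_male score predicted
#> 1       F001     F   0.0131 0.00400 1.186         F
#> 2       F002     F   0.0149 0.00924 0.477         F
#> 3       F003     F   0.0153 0.00477 1.168         F
#> 4       F004     F   0.0119 0.00552 0.764         F

glance(predictions)
#>   n_subjects accuracy bandwidth geometry     orientation r2_continuum overlap_fraction crossing_threshold
#> 1         20      0.9     0.191     TRUE female_positive        0.985              0.1             -0.022
```

Each row gives the subject's soft-Jaccard overlap to the Female and
Male pooled memories (its own features excluded), the log-ratio score
(positive = more Female-typical under the default orientation) and the
predicted label. The one-line summary reports leave-one-out accuracy
(0.9 on this 20-subject toy cohort), the data-calibrated kernel
bandwidth, the near-linear score-continuum R², and the
score-distribution overlap statistics. `plot_score_continuum()`,
`plot_score_distributions()` and `plot_slice_overlay()` visualize the
results; `cluster_features()`, `feature_affinity()` and
`scale_ratio()` drill down to individual recurring features.

A thin command-line pipeline is installed at `inst/cli/voxsift`
(subcommands `simulate`, `extract`, `match`, `classify`, `evaluate`),
reading/writing NIfTI volumes, keypoint TSVs and JSON reports with the
full run configuration embedded as provenance.

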