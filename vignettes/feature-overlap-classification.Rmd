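---
title: "Scale-invariant keypoints and soft-Jaccard group classification of 3D images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scale-invariant keypoints and soft-Jaccard group classification of 3D images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxsift)
```

## The model

`voxsift` implements a memory-based group classifier for 3D volumetric
images (its motivating use is sex classification of registered,
skull-stripped T1-weighted brain MRI). Each image is reduced to a sparse
set of *keypoints*: locations $(x, y, z)$ and scales $\sigma$ that
locally maximize the spherically symmetric scale-normalized
Laplacian-of-Gaussian

$$\nabla^2 I(x, y, z, \sigma) \;=\; \nabla^2 * G(\sigma) * I(x, y, z),$$

where $G(\sigma)$ is a Gaussian kernel and $*$ denotes convolution. A
keypoint marks a blob-like region of bulging contrast, bright or dark,
whose size is selected automatically by the extremum over $\sigma$. The
neighbourhood of each keypoint is resampled to a fixed grid over a
window proportional to $\sigma$ — this is what makes the descriptor
scale-invariant — and encoded as a 64-element gradient-orientation
histogram (2×2×2 spatial subregions × 8 orientation octants) whose bin
values are replaced by their ranks and unit-normalized. The rank
transform makes the descriptor exactly invariant to any strictly
monotone intensity transform.

Classification requires no fitted model. A labelled *group memory*
pools the feature sets of training subjects. The similarity between a
subject's feature set $A$ and a pooled set $B$ is the soft Jaccard
overlap

$$J(A, B) \;=\; \frac{|A \cap B|}{|A| + |B| - |A \cap B|},
\qquad
|A \cap B| \;=\; \sum_{a_i \in A} e^{-d^2(a_i, b_{j(i)}) / h^2},$$

where $b_{j(i)}$ is the nearest neighbour of $a_i$ in $B$ by descriptor
distance and $h$ is a bandwidth (the literal form uses $h = 1$;
`calibrate_bandwidth()` sets $h$ to the median cross-subject
nearest-neighbour distance, so a typical match receives weight
$e^{-1}$). Optionally, matches are down-weighted by a geometric
consistency kernel on location and log-scale. The per-subject
prediction score is the difference of log overlaps to the Female and
Male memories,

$$\mathrm{Score}(A) = \log J(A, \mathrm{Female}) - \log J(A, \mathrm{Male}),$$

evaluated leave-one-out (a subject's own features never enter its
memory) and thresholded at 0. Under the package's default orientation a
higher score means more Female-typical; an orientation flag negates the
score for presentations that plot male on the positive side. Each
individual feature also receives a group affinity, the log likelihood
ratio $\log \hat p(f \mid \mathrm{Male}) - \log \hat p(f \mid
\mathrm{Female})$ under kernel density estimates on descriptors over
the label pools (the $1/|\mathrm{label}|$ normalization is kept so that
unequal pooled set sizes shift affinities just as they shift the
Jaccard overlap).

## The synthetic phantom generator

Real cohort data of this kind is under managed access, so the package
validates itself on synthetic cohorts with planted, ground-truth-known
structure (`phantom_spec()`, `make_cohort()`). A phantom is a smooth
ellipsoidal "head" envelope plus isotropic Gaussian intensity blobs:

* **common** blobs at canonical sites in every subject (uninformative
  shared anatomy);
* a bilateral informative **pair**, planted symmetrically about the
  midline, whose centre-to-centre separation (16 mm F vs 22 mm M) and
  scale (3.88 mm F vs 4.00 mm M, a ratio of 0.97) differ by group —
  the synthetic analogue of a bilateral deep-brain structure that sits
  closer together in one group;
* a pool of **shared** blobs, each present in a random ~60% of
  subjects, carrying a label-conditional amplitude bias (the unfavoured
  label renders the blob with inverted, weaker contrast) — weakly
  informative features shared by apparently random subject subsets;
* **private** blobs unique to each subject, and additive Gaussian voxel
  noise;
* a global isotropic **size factor** per subject, mean 1.06 for males
  and 1.00 for females (sd 0.02), applied by scaling blob geometry and
  the envelope about the head centroid in `"rigid"` mode and forced to
  1 in `"nonlinear"` mode, emulating size-preserving versus
  size-removing registration.

Blobs are isotropic Gaussians so every detector quantity has a closed
form: the scale-normalized LoG centre response of a blob of width
$\sigma_b$ is $3 A \sigma^2 \sigma_b^3 / (\sigma^2 +
\sigma_b^2)^{5/2}$, maximized at $\sigma^* = \sigma_b \sqrt{2/3}$,
which the test suite uses as a brute-force 1-D oracle. The size
confound scales geometry rather than resampling the grid, so oracle
tests are not contaminated by interpolation. Canonical sites keep a
minimum separation (12 mm by default) and clearance from the pair's
endpoints: without it, a randomly placed large blob can sit close
enough to the pair to absorb its detector response, which makes
construction-validity checks (e.g. per-subject pair detection)
ambiguous. Default grids are 48³ voxels at 2.5 mm (a 120 mm box), which
keeps a 100-subject cohort's generation and feature extraction in the
tens of seconds; the acceptance analyses use 50/group for
classification grids and 100/group for cluster geometry, sizes at which
the planted effects are comfortably resolved.

What the phantoms deliberately do **not** emulate: MRI tissue contrast,
bias fields, partial-volume effects, anisotropic structures, or
registration error. Passing tests demonstrate that the pipeline
recovers planted statistical structure of the kind the method targets;
they do not certify accuracy values on real MRI.

## Numerical and design choices

* **Detector.** Difference-of-Gaussians approximation of the
  normalized LoG on a geometric ladder $\sigma_k = 1.6 \cdot 2^{k/3}$
  mm, octaves downsampled by 2 until the grid drops below 16 voxels;
  the input is assumed to carry a native blur of half a voxel.
  Extrema are strict over the 80-voxel space–scale neighbourhood,
  refined by a quadratic fit, and filtered by (a) a contrast threshold
  of 0.08 of the maximum response magnitude and (b) a 3D Hessian test
  that discards saddles and responses whose extreme eigenvalue ratio
  exceeds 10. The contrast fraction is set above the ~6% ring lobe
  that surrounds every blob response, so an isolated blob yields
  exactly one candidate; the reference is the plain maximum because
  DoG smoothing already suppresses isolated hot voxels. Candidates
  within one voxel of the border, or outside an optional (eroded)
  region-of-interest mask, are discarded — on skull-stripped images the
  brain mask plays this role, and the phantom's analytic head mask
  removes envelope-rim responses the same way.
* **Keypoint scale.** Quadratic sub-scale interpolation on a 3-level
  ladder is noticeably quantized and systematically *shrinks*
  between-group scale differences (a planted scale ratio of 0.97 reads
  as ~0.99). `extract_features()` therefore refits each keypoint's
  scale by least squares against the analytic Gaussian-blob response
  curve sampled across all pyramid levels at the keypoint (on the
  native-blur-corrected scale axis). `scale_ratio()` additionally uses
  5%-trimmed label means, which makes the cluster-level ratio robust to
  the occasional mismatched member that greedy clustering admits.
* **Descriptor.** 16³ patch over a ±2σ window, Gaussian spatial
  weighting (sd = half the window), octants by the sign pattern of the
  gradient, trilinear spatial interpolation into 2×2×2 cells, average
  ranks for ties. Bins that agree within 0.1% of the maximum are
  snapped to their group mean before ranking: bins that are equal *by
  symmetry* (the octants of a rotationally symmetric blob) would
  otherwise receive arbitrary distinct ranks driven by interpolation
  noise, destabilizing the descriptor. Upright orientation is the
  default (inputs are registered); the optional local frame takes the
  dominant direction of a 26-direction gradient histogram, with the
  secondary direction voted by gradients projected onto the orthogonal
  plane (raw gradients of a smooth patch concentrate near the primary
  axis, leaving the orthogonal bins empty). Only *exact* ties are
  degenerate — noise rotates with the content and still defines an
  equivariant frame — and degenerate frames fall back to the identity
  with a flag.
* **Matching.** Exact nearest-neighbour search, directed $A \to B$,
  best match per query feature; ties break to the smallest index.
  Geometry weighting defaults: location sd 10 mm, log-scale sd
  $\ln 1.5$.
* **Balanced leave-one-out.** Plain leave-one-out removes the query
  from its own label pool only, so that pool is one subject smaller
  than the other; through the $|B|$ term in the Jaccard denominator
  this biases *every* subject towards its own label (label-shuffled
  cohorts classify at ~0.7 rather than 0.5 at 30/group). By default
  one deterministically chosen subject (the last of the opposite label
  in memory order) is excluded as well, so both pools shrink by one and
  the permutation null sits at chance. The per-subject *feature-count*
  asymmetry — the mechanism behind the crossing-threshold shift when
  one group's sets are padded — is unaffected.
* **Cluster analysis.** Greedy exemplar clustering in descending
  response order; each subject contributes at most its best
  within-radius member (descriptor distance ≤ 1.0, location ≤ 8 mm);
  members are consumed. The pair classifier sums the two member
  affinities and thresholds at 0, with missing members contributing 0
  and subjects missing both classified by the training majority.
* **Evaluation.** Accuracy uncertainty by subject-level bootstrap
  (1000 resamples). The score continuum statistic is the squared
  Pearson correlation of sorted scores against rank; a balanced binary
  step gives $\tfrac34 n^2/(n^2-1)$, the reference for "how linear" a
  continuum is. Conditional score densities use a Gaussian kernel with
  Silverman's bandwidth on 512 grid points; the crossing threshold is
  the grid point between the label means where the densities intersect,
  and the overlap range runs from the lowest score of the higher-mean
  label to the highest score of the lower-mean label.

## Known limitations

* The pipeline assumes approximately isotropic voxels and registered
  inputs; the optional rotation-invariant frame is exactly equivariant
  only under grid rotations (general rotations incur interpolation
  error).
* The scale refit assumes blob-like (locally Gaussian) structure; on
  strongly non-blob anatomy it degrades gracefully to the detection
  scale but is then only as good as the ladder. Even on phantoms, the
  recovered between-group scale ratio of the planted pair varies by
  roughly ±0.015 across independent 100-per-group cohorts (subject
  draws, neighbouring-structure interference, cluster-membership
  noise), so small planted ratios are resolved in expectation, not per
  cohort.
* Descriptor distances between near-identical symmetric blobs carry
  little identity information; cross-subject correspondence of such
  features rests on geometry (location/scale), which is why the
  geometric weighting and the cluster radius matter on phantom-like
  data.
* All validation is synthetic; see the generator section for what the
  phantoms do and do not emulate.
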