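---
title: "Vascular parcellation and lesion-symptom mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vascular parcellation and lesion-symptom mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models: what each stage
assumes, which parameters matter, what the synthetic-data generator does and
does not emulate, and where the design was genuinely open.

## 1. Imaging model

All analysis operates on `volume` objects: one 3-D scalar field plus a 4x4
voxel-to-mm affine and a role tag (`abnormality` in [0, 1], `binary`,
`label`, or untyped statistic). Coordinates are 0-based voxel indices; all
reported peaks and centres of mass are in mm through the affine.

**Smoothing.** Gaussian smoothing is specified by its full-width at half
maximum in mm; the per-axis sigma in voxels is `fwhm / sqrt(8 log 2)` divided
by the voxel size of that axis, so anisotropic grids are handled through the
affine. The filter is applied separably with kernels truncated at six sigma
and *reflective* boundaries. Reflection was chosen (over zero-padding)
because it preserves total abnormality mass near the brain edge; the kernel
normalisation makes the impulse response match the continuous normal density
to well below 1e-6, which the test suite asserts against the closed form.

**Abnormality maps.** Patients are compared voxel-wise to a control cohort:
abnormality `= 2 * pnorm(|x - mu_c| / max(sigma_c, floor)) - 1`, a value in
[0, 1] monotone in the deviation. The SD floor (1e-6 of the control
intensity range) guards voxels where controls are homogeneous. This
control-referenced deviation map is this package's own outlier-scoring rule;
it produces the same two products a full lesion-identification pipeline
yields (an abnormality likelihood map and a binary lesion map), which is all
the downstream stages consume.

**Binarization.** Candidate lesion voxels exceed the U-threshold
(default 0.5 - at least 50% likelihood of abnormality); candidate clusters
must then have *strictly more than* `min_cluster_voxels` voxels
(default 100). Connectivity defaults to 26 (the most inclusive standard
neighbourhood; configurable to 6 or 18). The operation is idempotent on its
own output.

**Cluster tables** report voxel count, mm^3 volume, signed peak, and the
unweighted centre of mass of each cluster in mm. When a significance mask
contains several clusters, the displacement analyses use the centre of mass
of *all* significant voxels pooled by default; a largest-cluster-only option
exists because the choice is not forced by any principle (both are defensible
readings of "centre of mass of the significant cluster").

## 2. Lesion decomposition

The patients x voxels abnormality matrix is column-centered (voxel means
removed). Centering-only - no voxel-wise rescaling - was chosen because the
abnormality scale is already common across voxels; a `center` switch exists.

The eigendecomposition runs on the patients-side Gram matrix `X Xᵀ`
(identical non-null spectrum, tractable at ~10-60k voxels). Loadings are the
orthonormal voxel coefficients of the top-k eigenvectors; varimax with
Kaiser row-normalisation (tolerance 1e-12) rotates them toward simple
spatial structure. Because loadings keep orthonormal columns,
`scores %*% t(loadings)` is exactly the rank-k reconstruction and the
residual variance equals the discarded eigenvalue mass - both asserted in
tests. Rotating the *spatial* side (and deriving patient scores after
rotation) was chosen over rotating patient-side factors because the spatial
maps are the scientific object of interest and per-patient "component
scores" are reported separately. The sign of each component is fixed so its
largest-|loading| voxel is positive; the sign convention is applied to
loadings and scores, while the `rotation` field stays the pure varimax
rotation (so a k = 1 solution reports the 1x1 identity).

**Model order.** MDL and KIC are computed on the eigenvalue spectrum: for
candidate order q, the sphericity log-likelihood of the trailing
eigenvalues, `N (p - q) log(arithmetic/geometric mean)`, plus a penalty -
`m(q)/2 log N` for MDL and `3 m(q)` for KIC, with `m(q) = q(2p - q) + 1`
free parameters (the standard eigenvalue-sphericity family). One spectrum
point is dropped for the rank lost to centering. Ties break toward the
smaller order; a flat spectrum returns order 0 with a warning. MDL is the
default (`k = k_mdl`), KIC is reported alongside, matching the practice of
preferring the more parsimonious of the two estimates.

**Component maps.** Loadings are standardized across in-mask voxels to z,
thresholded two-sided at |z| > 3.29 (p < 0.001), and extent-filtered
(clusters > 500 voxels by default). The 500- and 200-voxel extent defaults
correspond to 4 cm^3 and 1.6 cm^3 at 2-mm voxels; the evaluation
experiments translate these extents through their mm^3 equivalents so the
same physical rule applies on the package's 4-mm simulation grid. Note the
z-threshold interacts with territory size: a component loading uniformly on
a fraction f of the mask plateaus near `z = sqrt(1/f - 1)`, so |z| > 3.29
resolves territories only when each covers less than ~8% of the mask (true
for the 14-territory default; tests on coarser partitions lower the cut).

**Stability.** `stability_analysis` re-estimates the MDL order on random
patient subsamples (default 100 per size) and reports medians - the
convergence of the estimated order with sample size is the package's
evidence that an order estimate is data-supported rather than
sample-size-limited.

## 3. Behavioural factor decomposition

Test batteries are converted to percentages of the published maximum (or
the observed group maximum for open-ended tests). The factor analysis is
deliberately *component-based*: PCA of the tests x tests correlation
matrix, eigenvalue > 1.0 retention (Kaiser rule), varimax rotation, and
regression-method patient scores `Z R^-1 A`. Maximum-likelihood common
factor analysis is intentionally out of scope - the modelled procedure is
PCA with the eigenvalue rule throughout. Missing scores raise an error
(complete batteries are assumed); a near-singular correlation matrix gets a
1e-8 ridge with a warning.

## 4. Lesion-symptom mapping

**VBCM.** Abnormality at every voxel is regressed jointly on all behavioural
factor scores (they are near-orthogonal by construction; a warning fires
above |r| = 0.3). Per-factor t statistics are converted to partial
correlations `r = t / sqrt(t^2 + df)` - partial rather than zero-order r
was chosen because the factors enter one joint model. Cluster-level
correction is by permutation: factor rows are permuted jointly
(n = 1000 by default), the maximum suprathreshold cluster size forms the
null, and observed clusters survive if they exceed the (1 - alpha) null
quantile (alpha = 0.01, voxel p < 0.001). This replaces Monte-Carlo
smoothness-based correction with an exchangeability argument that needs no
smoothness estimate while targeting the same cluster-wise error rate; its
false-positive calibration is verified empirically in the acceptance suite.
Two caveats are documented rather than hidden: (i) the Monte-Carlo critical
value is tied to the seed and patient ordering (observed statistic maps are
order-invariant, the null quantile is re-drawn); (ii) with exactly
orthogonal factors the joint-model *betas* equal the simple-regression
betas, but partial r exceeds zero-order r whenever other factors absorb
response variance, so the joint model is not numerically identical to four
separate correlation maps.

**Component-factor screen.** Pearson r and two-sided p for every component
x factor pair, Bonferroni-controlled at `0.05 / (n_components x n_factors)`
(0.000625 for 20 x 4).

**Stepwise regression.** Classical forward-entry (p <= 0.05) /
backward-removal (p >= 0.10) on partial-F p-values, iterated to a fixed
point - the defaults of the statistics package tradition this procedure
comes from, since no other values are canonical. An empty model is a valid
outcome. Selected models are back-projected as the beta-weighted sum of
component loading maps, standardized to z, thresholded |z| > 3.29 with the
200-voxel (1.6 cm^3) extent rule.

## 5. Ground-truth simulation and evaluation

**The deficit rule.** A region-level ground truth labels a patient
"damaged" when at least 20% of the region is lesioned; damaged patients
show a deficit with probability 0.9; intact patients never do. Voxel-level
truths are deterministic (deficit iff damaged) by default - the natural
reading of splitting a sample by single-voxel damage - with the
probabilistic rule available by configuration. Eligibility requires
*strictly more than* `min_damaged_patients` (default 3) damaged patients.

**Mapping step.** Mass-univariate two-sided Fisher exact tests (vectorised
over voxels via a hypergeometric lookup, validated against enumeration),
then Benjamini-Hochberg FDR at q = 0.01.

**Displacement.** The Euclidean distance between the centre of mass of the
significant voxels and the reference point (the ground-truth voxel, or the
region's centre of mass - the region reference is this package's choice, as
only the voxel case is forced). Truths with no significant voxels are
reported as non-localized and excluded from means, with their count shown.
Component-level truths are the thresholded component maps (|z| > 3.29 after
the 4 cm^3 extent rule). Because a finite component set caps the number of
truths, region-kind experiments can draw multiple independent label
simulations per region (`label_draws`), letting each arm accumulate 100+
ground truths.

**Sparse CCA.** A rank-1 penalized decomposition between the voxel matrix
and the label vector: the voxel weight vector is `X'y`, hard-thresholded to
retain the top `ceiling(sparseness x n_voxels)` absolute weights and
normalized, alternated with the (scalar) label-side sign until convergence.
Sparseness is the *fraction of voxels allowed nonzero* - fixed at 0.045 by
default, or selected on a log-spaced grid in [0.005, 0.9] by 5-fold
cross-validated held-out correlation. No sign constraint is imposed.

**Method comparison.** Per ground-truth region, five significance masks are
scored by Dice against the truth: Fisher/FDR, sparse CCA (fixed and CV),
PCA + stepwise back-projection, and PCA + Bonferroni-screened component
correlations (union of the significant components' thresholded maps).

## 6. The synthetic cohort: what it emulates, and what it does not

The generator realizes the covariance structure that motivates the whole
approach: a sampled binary arterial tree whose leaves seed a Voronoi-style
partition of an ellipsoidal brain mask (farthest-point seeding keeps
territory sizes comparable; on a convex mask every territory is connected).
Per patient, an occlusion node is drawn proportional to node weights and
every downstream territory receives voxel-wise damage from Beta(6, 2)
(mean 0.75 - mostly destroyed tissue with partial-damage tails); territory
boundaries are jittered by a smooth random displacement field of RMS 2 mm
(watershed variability); Gaussian background noise (SD 0.05) is added
in-mask and the map is clipped to [0, 1]. The default grid is 32 x 38 x 32
at 4-mm voxels (~15k in-mask voxels, a desk-scale stand-in for a 2-mm
hemisphere grid), 14 terminal branches (the order of the major cortical MCA
branches plus deep territories), 80 patients. These defaults *are* the
study conditions of the package's simulation claims; experiments state
deviations (e.g. noise 0.01 and leaf-only occlusion for the
parameter-recovery claim, where distal occlusions are the identifiable
regime) explicitly.

Behavioural batteries use the canonical 21-test x 4-factor loading pattern
of the published aphasia battery (salient loadings >= 0.5 kept at their
printed values, 0.2 elsewhere): factors are either driven by lesions
(`f = 1 - mean abnormality` over critical territories) or, for standalone
batteries, drawn uniformly on [0, 1] - chosen once to mirror the range
lesion-driven factors take. Scores are `100 x clip(W f + noise, 0, 1)` with
unique noise SD 0.1.

Not emulated: haemodynamics, realistic T1 intensities, lesion growth
dynamics, non-MCA or right-hemisphere anatomy, and behavioural floor/ceiling
artefacts beyond clipping. Passing recovery tests therefore demonstrates
that the *algorithms* recover territorial structure and calibrated error
rates under the stated covariance model - not that real cohorts of any
particular size would yield the same component count or displacement
magnitudes.

## 7. Numerical choices and degenerate inputs

- Eigen/SVD paths guard zero eigenvalues with machine-epsilon floors;
  the order estimator warns and returns 0 on a flat spectrum.
- Varimax runs to eps = 1e-12; its attained criterion matches an exhaustive
  0.01-degree planar search to < 1e-6 (asserted in the acceptance suite).
- Fisher p-values use the conventional `<= observed x (1 + 1e-7)` mass
  inclusion rule, matching `fisher.test`.
- Stepwise ties and stability: the final model is a fixed point of its own
  entry/removal criteria; re-running selection from the selected set changes
  nothing.
- Constant loading columns, single-class labels, zero-variance factors,
  empty regions, all-damaged voxels and rank-deficient designs raise typed
  errors rather than propagating NaN.
- Problem sizes in the test and acceptance suites (desk-scale grids,
  100-250 permutations, 100-seed Monte-Carlo loops) were chosen so the full
  suite completes in minutes while leaving every statistical tolerance
  comfortably wide of its Monte-Carlo noise.

## 8. Known limitations

- The abnormality scorer assumes voxel-wise normal control intensities; it
  is a scoring rule, not a tissue model.
- ICA, oblique (promax) rotation, covariate adjustment (lesion volume, age)
  and out-of-sample projection of new patients are out of scope.
- The permutation cluster correction assumes exchangeable patients under
  the null (no covariate structure).
- On very coarse parcellations the fixed |z| > 3.29 component threshold can
  sit above the loading plateau (see section 2); users working with few,
  large territories should lower the cut or use the mm^3-translated extent
  interface.
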