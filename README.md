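# lesionparc

Data-driven vascular parcellation and lesion–symptom mapping of stroke
lesions, with a ground-truth simulation framework for measuring the spatial
error of competing lesion models.

## The problem

After a middle-cerebral-artery stroke, damage is not spatially random: the
arterial tree constrains which voxels fail together, so lesions have a
strong territorial covariance (occlusion of a superior branch damages
prefrontal and motor cortex but spares the temporal lobe; watershed zones
between territories vary across individuals). Classical voxel-wise
lesion–symptom mapping ignores this covariance. `lesionparc` implements the
alternative: decompose a cohort of lesion maps into data-driven *vascular
territory components* and relate those components to behaviour — and then
quantify, by simulation, how much spatial error each lesion model (single
voxel, anatomical atlas, vascular components) induces.

For cohort analysts the package covers the full pipeline:

1. **Imaging model** — NIfTI I/O, FWHM-specified Gaussian smoothing,
   control-referenced abnormality maps in [0, 1], binarization by the
   U-threshold (0.5) with a >100-voxel cluster-extent rule, overlap maps,
   cluster tables with mm coordinates.
2. **Lesion PCA** — the patients × voxels abnormality matrix is decomposed
   by PCA with a varimax rotation of the voxel loadings; model order is
   estimated from the eigenvalue spectrum by MDL and KIC information
   criteria; component maps are standardized to z, thresholded at
   |z| > 3.29, and reported with cluster tables; order stability is probed
   by patient subsampling.
3. **Behaviour PCA** — a 21-test battery (percentage scores) is reduced by
   PCA of the correlation matrix, eigenvalue > 1 retention, varimax
   rotation, and regression-method patient factor scores.
4. **Mapping** — voxel-based correlational mapping (joint regression on all
   factors, partial-r maps, permutation max-cluster-size correction at
   cluster α = 0.01 / voxel p < 0.001); Bonferroni-screened
   component–factor Pearson correlations; forward/backward stepwise
   regression of factors on component scores with brain back-projection.
5. **Evaluation** — simulated critical substrates at voxel, region or
   component level; the 20 % damage-fraction / 90 % deficit-probability
   labelling rule; mass-univariate Fisher exact mapping with
   Benjamini–Hochberg FDR (q = 0.01); centre-of-mass displacement error and
   Welch t comparison across lesion models; sparse canonical correlation
   (fixed sparseness 0.045 or cross-validated in 0.005–0.9); Dice-based
   method comparison.
6. **Synthetic data** — arterial trees, Voronoi-grown territory atlases,
   lesion cohorts with territorial covariance and watershed jitter,
   behavioural batteries with a planted 4-factor loading structure, and
   deficit labels: every stage of the pipeline is testable without any
   patient data.

## The core statistic

With `X` the column-centered patients × voxels abnormality matrix, the
lesion decomposition solves the eigenproblem of `X Xᵀ` (patients side, since
voxels ≫ patients), maps the top-k eigenvectors to orthonormal voxel
coefficients `V`, and rotates them by the varimax criterion

    max_R  Σ_j [ mean(a⁴_j) − mean(a²_j)² ],   A = V R,  RᵀR = I

(Kaiser row-normalized). Patient component scores are `X A`. The order k is
the arg-min of the MDL curve

    MDL(q) = N (p − q) log(a_q / g_q) + m(q)/2 · log N,   m(q) = q(2p − q) + 1

where `a_q`, `g_q` are arithmetic/geometric means of the trailing
eigenvalues, `p` the spectrum size and `N` the voxel count (KIC analogous
with penalty `3 m(q)`).

## Worked example

```r
library(lesionparc)

# synthetic study: 14-territory atlas, 80-patient cohort
va   <- make_vascular_atlas(n_terminal_branches = 14, seed = 1)
les  <- simulate_patient_lesions(va$tree, va$atlas, cohort_spec(seed = 2))
mask <- default_brain_mask()

lm  <- assemble_lesion_matrix(les, mask)
est <- estimate_order(lm)
est
#> <order estimate: MDL 48, KIC 72 (79 spectrum points)>

sol <- pca_varimax(lm, est$k_mdl)
sol
#> <component solution: k = 48, 97.6% variance explained>

m <- match_components_to_territories(pca_varimax(lm, 14), lm, va$atlas)
median(m$dice)
#> [1] 0.8939913
```

The order estimate says how many lesion components the eigenvalue spectrum
supports (with watershed jitter each territory contributes several
boundary modes, so the estimate exceeds the 14 generating territories); the
component–territory matching shows that a 14-component solution recovers
the generating territories with high spatial overlap (median Dice 0.89,
each territory matched to a distinct component).

A command-line interface wraps the same functions
(`inst/cli/lesionparc simulate-atlas | simulate-cohort | decompose-lesions |
decompose-behaviour | map-symptoms | eval-displacement | eval-methods |
report`); every command logs its parameters and seed and is
byte-reproducible.

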