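---
title: "Multimodal lesion and connectome prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal lesion and connectome prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionconn)
```

## The scientific problem

In chronic post-stroke aphasia, behavioural impairment is routinely related
to the anatomy of the lesion, but network accounts of language predict that
structural disconnection and functional network disruption should carry
information too. `lesionconn` implements a complete analysis framework for
asking whether they do: leave-one-out cross-validated (LOOCV) lesion-symptom
models, connectome-based predictive models over functional (FC) and
structural (SC) connectivity features, formal model comparison on squared
prediction errors, residual-variance analyses (can connectivity explain what
the lesion leaves unexplained?), nodal-degree summaries of predictive
connections, and healthy-control seed-network overlap.

Because multimodal patient cohorts of this kind are not openly available,
the package ships a synthetic-cohort generator with planted ground truth.
Every analysis can therefore be exercised end to end, and — more
importantly — scored: the generator knows which regions drive behaviour,
how much variance lesions explain, and whether the structural connectome
carries any information that the lesion does not.

## The generative model

A cohort is defined by `sim_config()`. Its components:

**Parcellation.** `make_atlas()` partitions the grid into K connected,
near-equal box regions (a stand-in for a functional parcellation of a few
hundred regions; K is configurable and kept small at desk scale). The first
voxel axis is the left-right axis; "left" means x-index at most
`floor(nx/2)`. Any fixed laterality convention would do; this one is simple
and testable.

**Lesions.** Each patient receives one ellipsoidal lesion confined to the
left half of the grid, emulating the left-hemisphere arterial-territory
strokes typical of aphasia cohorts. Volumes are drawn uniformly from
`lesion_volume_range_mm3`; random axis ratios (0.7-1.4) vary the shape. The
continuous "abnormality" image is the binary mask smoothed with a Gaussian
kernel (`lesion_fwhm_vox`, default 2 voxels), mimicking the smoothed tissue
abnormality maps that lesion-symptom analyses consume. Defaults
(24&sup3; voxels at 2 mm, volumes 1,000-10,000 mm&sup3;) make a lesion
occupy roughly 2-18% of the left half, a plausibly scaled range for
middle-cerebral-artery strokes on this miniature brain.

**Behaviour.** Each of F latent factors has one planted critical region in
the left half. The factor equals
`sqrt(effect_r2) * z(1 - damage fraction of the critical ROI) + noise`,
so with `noise_sd = 1` the planted lesion term explains exactly `effect_r2`
of factor variance in expectation. Test scores are a linear image of the
factors through an orthogonal block loading matrix (disjoint test support
per factor) plus test noise, clipped to `[0, 100]`; a quarter of tests carry
no stated maximum, so percentage conversion must fall back to the observed
group maximum.

**Time series.** ROI signals mix a community latent series with
idiosyncratic noise; the latent share is `0.85 * (1 - damage)`. Damaged
regions therefore decouple from their community, which is the mechanism by
which lesions leave a functional-connectivity signature. Controls use zero
damage. Communities are spatial (k-means on region centroids).

**Structural connectomes.** The base connectome decays with inter-centroid
distance. A subject's matrix is `base * (1 - damage_i) * (1 - damage_j)` —
with `sc_collinear = TRUE` this is *exactly* the subject's connectome, an
operationalization of the claim that lesion and disconnection information
are collinear. With `sc_collinear = FALSE` and `sc_independent_r2 > 0`,
designated right-hemisphere (never lesioned) region pairs additionally carry
a per-subject latent tied to the first factor: connectivity information that
no lesion feature can recover.

What the generator does *not* emulate: haemodynamics, realistic anatomy or
atlas geometry, tractography biases, registration error, multi-lesion or
bilateral damage, and test batteries with non-linear difficulty. Passing
tests therefore demonstrate that the *machinery* is correct and calibrated
under the stated generative assumptions, not that any particular empirical
cohort will behave this way.

## The analysis pipeline

### Behavioural factors

`normalize_battery()` converts scores to percentages (stated maximum, else
group maximum). `fit_varimax_pca()` performs PCA on the correlation matrix —
tests remain on heterogeneous scales even after percentage conversion, so
the covariance matrix would let high-variance tests dominate — retains
components with eigenvalue at least 1.0 (the boundary value is retained),
and varimax-rotates the retained loadings (Kaiser row normalization, the
convention of the classical implementations). Factor scores use the
regression method, `Z R^{-1} L`: for rotated principal components this
yields exactly unit-variance, zero-mean scores on the fitting sample. Each
factor is sign-flipped so its dominant test loads positively. These choices
(correlation input, regression scores) are stated here because the
conventional descriptions of this procedure leave them open.

### Lesion-symptom mapping

`loocv_lesion_model()` runs, inside every leave-one-out fold:

1. voxelwise Pearson correlation of the continuous abnormality image with
   the target over the training subjects only, with two-tailed p-values
   from the t transform (voxels with zero variance across subjects are
   excluded, not reported as zero correlation);
2. Benjamini-Hochberg FDR selection at `fdr_q` (default 0.05) over the
   valid voxels;
3. connected-component clustering (face connectivity by default —
   conservative and standard for volumetric statistics) and removal of
   clusters not strictly exceeding `min_cluster_volume_mm3` (default
   2,000 mm&sup3;, i.e. clusters must be larger than 2 cm&sup3;);
4. a multiple linear regression of the target on the per-cluster lesion
   loads (mean abnormality within the cluster; for binary masks this is
   the damaged proportion), with rank deficiency resolved by the
   singular-value pseudoinverse;
5. prediction of the held-out subject from their lesion loads.

Folds with no surviving cluster predict the training mean. Accuracy is the
Pearson correlation between out-of-fold predictions and targets;
significance comes from a permutation test that reruns the *entire*
procedure — voxel statistics, FDR, clustering, regression — on each
shuffled target, `p = (1 + #{null r >= observed}) / (n_perm + 1)`.
`stability_map()` counts, per voxel, the folds whose surviving clusters
contain it. Two-tailed voxel tests and no lesion-volume covariate are
deliberate defaults; both are configurable points in the code rather than
hidden constants.

### Connectivity features

Time series are linearly detrended and bandpass filtered (0.01-0.08 Hz) with
an ideal rectangular frequency-domain filter — the behaviour of the standard
resting-state preprocessing tools, and the reason a pure sinusoid inside the
band survives essentially unchanged while out-of-band power is removed.
`fc_matrix()` computes pairwise Pearson correlations, clamps them to
±(1 − 10⁻⁷) (identical series would otherwise produce infinite z) and
applies the Fisher z transform. `lesion_mask_fc()` zeroes every pair
incident to a region overlapping the lesion by *at least one voxel* —
the strict reading under which no connection emanating from lesioned tissue
is trusted, however small the overlap. For SC, `symmetrize_and_mask_sc()`
averages the two directed streamline probabilities and zeroes regions whose
damaged fraction strictly exceeds 0.95. `vectorize_lower()` takes the
strictly-lower-triangle entries in a fixed column-major scan (K = 200 gives
19,900 features); `pair_index_map()` documents the feature-to-pair
bijection so model weights map back to connections deterministically.

### Elastic-net prediction

The predictive model is elastic-net regression,

$$\min_{\beta_0,\beta}\; \frac{1}{2n}\sum_i (y_i - \beta_0 - x_i'\beta)^2
 + \lambda\Big[\alpha\|\beta\|_1 + \tfrac{1-\alpha}{2}\|\beta\|_2^2\Big],$$

with features standardized internally and coefficients reported on the
original scale. The solver is a compiled coordinate-descent path algorithm
(warm starts down a descending λ path; convergence when the largest squared
coefficient update falls below `thresh` scaled by the response variance;
active-set iteration between full sweeps). Its solutions are verified in the
test suite against an independent reference implementation across the α
range, against closed-form least squares in the ridge λ→0 limit, and
against the analytic all-zero point at λ_max.

Hyperparameters are tuned by *nested* LOOCV (`tune_alpha_nested()`): for
each α in the grid, the λ path is computed on the training set (default 100
log-spaced values down to 0.001 λ_max) and the mean squared leave-one-out
error is evaluated along it; the (α, λ) pair with minimum inner error wins,
with exact ties broken toward larger α and then larger λ (prefer the
sparser, more regularized model). No one-standard-error rule is applied —
minimum CV error is the simplest defensible reading of nested tuning. The
default α grid is {0.01, 0.05, …, 1}: pure ridge (α = 0) is excluded only
because its λ path has no finite null point; it can be requested
explicitly. Each training fold standardizes with its own rows; the held-out
subject never touches tuning, standardization or fitting — a property the
suite checks by perturbing held-out targets on every fold. Permutation
significance re-tunes the hyperparameters on every shuffle; this is the
conservative choice where conventions differ, and it is why the compiled
solver exists: a single significance test is ~10⁵ path fits. The per-target
sparsity summary is the chosen α averaged over outer folds (`mean_alpha`).

### Model comparison and residual analysis

`compare_squared_errors()` takes two models' out-of-fold predictions on the
same subjects and applies the Wilcoxon signed-rank test to the paired
squared-error differences `d_i = errA_i^2 - errB_i^2`. Conventions: zero
differences dropped (the classical treatment), mid-ranks for ties, and a
tie-corrected normal approximation with continuity correction for the z
statistic; for n ≤ 25 the p-value comes from the exact distribution of the
signed-rank statistic, computed by dynamic programming over the observed
(possibly tied) ranks. z is negative when model B's errors dominate in rank
mass. The sign convention is ours and documented, not asserted as anyone
else's. `residual_targets()` exposes a lesion model's out-of-fold residuals
as targets for connectivity models — only test-set residuals give
leakage-free targets, so train-set residuals are never used.

### Network summaries

`average_weights_z()` averages per-fold weight vectors, z-scores the means,
and marks |z| > 3.29 (two-sided p < 0.001) as significant. The
standardization population defaults to features with a nonzero fold-mean
weight: sparse models would otherwise have a spread dominated by structural
zeros; the all-features alternative is available. `nodal_degree()` sums
*absolute* incident significant weights per node — the quantity actually
plotted in this literature — with the signed variant behind a flag, and
reports each node's proportion of positive connections. `top_nodes()`
breaks ties by lower node id, and `filter_by_nodes()` is explicitly a
visualization aid, not a refitted model.

### Healthy seed networks

`seed_fc_map()` correlates a seed region's mean series with every
grey-matter voxel in control data (Fisher z). `group_tmap()` applies a
one-sample t-test across controls. The cluster-extent threshold comes from
`montecarlo_cluster_threshold()`: white-noise fields smoothed to the
requested FWHM, standardized within the mask, thresholded two-sided at
`voxel_p`; the threshold is the smallest integer cluster size whose null
exceedance probability is at most `cluster_p`. This Monte-Carlo procedure
is calibrated by its own family-wise-error property (checked in the suite
on fresh null fields) rather than against any particular legacy
implementation, whose parameterizations are not reproducible. Node overlap
uses the ≥ 1 voxel criterion by default (a centroid-inside-mask alternative
is provided), evaluated on the positive tail — the networks of interest are
positive correlations — with the negative-tail mask also returned.

## Orchestration

`run_study()` executes the full design — simulate, factor scores, lesion
models, feature matrices, connectivity models (FC, SC and the
column-concatenated FC+SC through the identical pipeline), squared-error
comparisons, residual models, network summaries, optional seed networks —
from one `study_config()`. A global seed fans out to per-stage seeds through
a fixed counter scheme, so stages are individually reproducible without
coupling. Failures are recorded per cell and independent cells continue.
The report records the n actually used per cell; comparisons restrict to
subjects with both predictions.

## Numerical choices

- Correlations are clamped to ±(1 − 10⁻⁷) before `atanh`.
- Voxels with (numerically) zero variance are excluded from correlation
  maps, FDR and group t-maps rather than mapped to zero.
- Gaussian smoothing is an FFT convolution on a zero-padded grid; roundoff
  can leave ±10⁻¹⁷ outside [0, 1], which the lesion generator clips.
- The BH step-up selection is implemented via adjusted p-values
  (equivalent to the textbook largest-k rule, which the tests verify by
  hand evaluation).
- Cluster volume and damage thresholds are strict (`>`): a 2,000 mm³
  cluster is dropped at a 2,000 mm³ threshold; a region exactly 95% damaged
  is kept.
- Ties in nested tuning, top-node ranking and component relabelling all
  have documented deterministic resolutions.

## Problem sizes used by the test suite

The suite runs the complete pipeline repeatedly, so its simulation studies
use deliberately small study conditions, chosen once as the package's
desk-scale defaults: recovery cohorts of n = 60 patients on a 16³ grid with
K = 16 regions (planted regions of 2,048 mm³, lesions 200-1,600 mm³,
cluster threshold 400 mm³, `effect_r2 = 0.5`, 20 seeds, 99 permutations);
type-I cohorts of n = 16 with `effect_r2 = 0` (40 seeds); residual-model
arms of n = 24 with `effect_r2 = 0.65` so that the structural latent
(`sc_independent_r2 = 0.3`) dominates what the lesion model leaves
unexplained — the power-demonstration condition — against a collinear null
arm differing only in the collinearity switch; and cluster-threshold
calibration on a 24³ grid (FWHM 2.5 voxels, voxel p = 0.005, 2,000
simulated fields, 1,000 fresh fields for the check). Reduced α grids and
shorter λ paths are used where the permutation design multiplies costs;
they are configuration choices of the simulation studies, not changes to
the methods.

## Known limitations

- The generator plants one critical region per factor; distributed or
  overlapping substrates are not modelled, so recovery metrics are
  interpretable but optimistic relative to real anatomy.
- Lesion-independent SC signal is implemented as a single latent shared by
  designated right-hemisphere pairs; richer independent structure would
  dilute the power of the residual analysis.
- LOOCV accuracy estimated as a correlation over out-of-fold predictions
  is noisy at small n, and folds without informative features predict the
  training mean, which biases the correlation downward (visibly to −1 in
  fully null models). The permutation test remains exact under
  exchangeability because the null replicates the same procedure.
- Residual targets are only as lesion-free as the lesion model that made
  them: at small n the lesion model underfits, its out-of-fold residuals
  retain lesion-driven variance, and a connectivity matrix that is itself a
  lesion function can then predict them "significantly" without carrying any
  independent information. This is a genuine property of residual analyses,
  not a test artifact, and it is why the collinearity contrast is evaluated
  as a paired design (identical cohorts with the switch on and off) rather
  than by the null arm alone.
- The Monte-Carlo cluster threshold assumes stationary Gaussian smoothness;
  it inherits the known limitations of that assumption.
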