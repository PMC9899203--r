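---
title: "Radiomic phenotyping of the lung parenchyma: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic phenotyping of the lung parenchyma: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lungpheno)
```

## The problem

Low-dose CT (LDCT) screening produces volumetric images of the lung whose
parenchymal texture carries information about diffuse disease processes —
emphysematous destruction, inflammation, fibrotic change — that a nodule-
centred reading ignores. `lungpheno` implements an unsupervised phenotyping
pipeline for this setting: it quantifies parenchymal texture with a fixed
panel of 26 three-dimensional radiomic features computed over a lattice of
non-overlapping windows, removes the technical variation induced by the CT
reconstruction kernel, groups scans into phenotypes by hierarchical
clustering, and asks two scientific questions of the result: *how many
phenotypes does the cohort support?* (consensus clustering) and *are the
phenotypes robust to the reconstruction kernel?* (dendrogram entanglement).

Because screening CT archives cannot be redistributed, the package ships a
synthetic phantom and cohort generator with the statistical structure the
analysis assumes, so every stage is exercisable and testable from code
alone. What passing tests on phantoms do and do not say about real data is
discussed at the end.

## Lung-field segmentation

`segment_lung()` is an intensity-based 3D procedure:

1. **K-means on HU values** (k = 2 by default) separates the air/lung
   attenuation mode from soft tissue. The 1D K-means is deliberately
   deterministic: centers start at the 10th and 90th HU percentiles and
   Lloyd iterations run to a 1e-3 HU tolerance, so segmentation is a pure
   function of its input rather than of a random initialization.
2. **Border removal**: 26-connected components of the low-attenuation
   candidate set that touch the volume border are exterior air and are
   dropped; components smaller than `min_component_fraction` (default 1%)
   of the candidate set are noise and are dropped too.
3. **Morphological closing** with a spherical element (default radius 2 mm,
   converted to anisotropic voxel offsets) fills small gaps.
4. **Vessel exclusion**: voxels above `vessel_hu_threshold` (default
   -300 HU) are removed; contiguous hyperattenuating structures (vessels,
   nodules) are thereby excluded from the texture domain.

The defaults in step 1, 3 and 4 are conventional for lung CT rather than
derived quantities; all are exposed in `segmentation_params()`. Voxels on
the outer face of the grid are never part of a mask.

## Lattice feature extraction

The texture descriptor is computed per *lattice window*: the bounding box
of the lung mask is tiled with non-overlapping cubes of physical edge `W`
(defaults 4, 8 and 20 mm; voxel edge = `round(W / spacing)` per axis,
minimum 1 voxel, so anisotropic spacing gives windows cubic in mm). A
window is evaluated only if at least `min_occupancy` (default 50%) of its
voxels are inside the lung mask — the handling of partial windows at the
lung boundary is a design choice, not a derived rule. Per-window features
are averaged (unweighted) into one 26-vector per scan per `W`.

The 26 features are the canonical members of the three families:

* **Histogram (6)** — mean, variance, skewness, excess kurtosis (population
  moments of the raw HU values; zero-variance windows return 0 skewness
  and kurtosis by convention), Shannon entropy and uniformity of the
  quantized gray-level distribution.
* **GLCM (9)** — contrast, correlation, energy, homogeneity, entropy,
  dissimilarity, cluster shade, cluster prominence, maximum probability,
  from one symmetric co-occurrence matrix accumulated over all 13 unique 3D
  directions at distance 1 voxel. Accumulating counts before computing
  features (rather than averaging per-direction features) is chosen for
  stability in small windows; zero-variance matrices return correlation 0.
* **GLRLM (11)** — SRE, LRE, GLN, RLN, RP, LGRE, HGRE, SRLGE, SRHGE,
  LRLGE, LRHGE with the Galloway/Chu definitions, runs accumulated over
  the same 13 directions and broken at mask/window boundaries. The run
  percentage denominator is the in-mask voxel count per direction summed
  over directions.

Quantization is **fixed-range**: HU values are clamped to `[-1024, 200]`
and binned into 32 equal-width levels over that fixed interval, so level
`g` means the same attenuation in every window, scan and kernel. A
window-local min–max scheme would maximize per-window dynamic range but
make levels incomparable across windows; comparability is what the
downstream clustering needs. A consequence worth knowing: a constant HU
offset changes the histogram mean by exactly that offset, and changes
quantized-domain features only if it pushes values across bin boundaries
(bin width 38.25 HU at the defaults).

The GLCM/GLRLM accumulators are implemented in C++ (a window is small but
a scan contains thousands of windows); both are validated in the test
suite against brute-force pair- and run-enumeration oracles written
independently in R, to 1e-10 on random windows with and without masked-out
voxels.

## Harmonization across reconstruction kernels

Reconstruction kernels act as a classic batch effect on radiomic features.
Before harmonization, scans with aberrant feature values are screened: for
each feature and each of age, BMI and pack-years, the feature is
residualized in a univariable OLS regression (fit pooled over the dataset)
and any scan whose residual leaves `median ± 2.5 × IQR` of that residual
vector is flagged (`flag_outliers()`). The pipeline default drops flagged
acquisitions — both kernel renderings, so the per-kernel cohorts stay
aligned for the entanglement comparison.

`combat_fit()`/`combat_apply()` implement standard parametric
empirical-Bayes ComBat: per feature, batch and protected-covariate effects
are estimated by least squares; data are standardized by the pooled
residual variance; per-batch location (gamma) and scale (delta) estimates
are shrunk toward parametric priors (normal for location, inverse-gamma
for scale, moments matched across the 26 features) by the iterative
posterior solution, to a 1e-4 relative tolerance. Sex, Lung-RADS group,
smoking status, age, BMI and pack-years are protected by default: their
design columns are estimated jointly and re-added unchanged, so
covariate-feature associations survive harmonization (verified in tests:
a planted slope is recovered within 10% at n = 500).

Two properties of the EB machinery deserve explicit mention because they
bound what "perfect harmonization" can mean:

* When every feature carries the *same* batch shift, the across-feature
  prior is nearly degenerate and the posterior shrinks each feature's
  estimate toward the common mean; the per-feature residual shift after
  harmonization then has a floor of roughly `(d/(t2·n + d))·sqrt(2/n)` in
  standardized units (a few percent at n = 200/batch). With
  feature-specific shifts the prior is diffuse and removal is essentially
  exact. The reference implementation behaves identically; our
  implementation matches it to ~1e-5 on random problems.
* A single-batch fit returns gamma* = 0 exactly but delta* ≈ n/(n−1)
  (the location/scale estimates use the unbiased variance while the pooled
  standardization uses the MLE), so applying it is the identity only up to
  that factor.

Residual kernel separation is quantified by `ks_batch_assessment()`: a
two-sample Kolmogorov–Smirnov test per feature between the two batches
(asymptotic p-values, switching to the exact computation below 25 scans
per batch) and the count of features significant at 0.05. On synthetic
kernel pairs this count drops from near 26 to near 0 after harmonization.

## Phenotype derivation and robustness

`hierarchical_cluster()` z-scores features by the dataset's own mean/SD
(stored, and reused verbatim for centroid mapping), computes Euclidean
distances and applies Ward linkage (`ward.D2`). The linkage/metric choice
is a design decision — compactness-seeking Ward is the natural partner of
nearest-centroid mapping — and the merge heights are validated against an
exhaustive Lance–Williams oracle for small n.

The number of phenotypes is selected by Monti consensus clustering
(`consensus_select_k()`): 250 resamples of 80% of scans without
replacement, the same Ward clustering on each resample, cuts at each K in
2..6, and a consensus matrix per K (co-clustering count over co-sampling
count per scan pair). K is chosen by the delta-area criterion on the
consensus CDF (K = 2 scored by its raw area, larger K by the relative
area increase, maximizer wins). The resampling settings are design
defaults, exposed in the API. On two-population synthetic cohorts with
a 4-pooled-SD separation on 8 of 26 features this recovers K = 2
essentially always; on single-population nulls the criterion defaults to
the scanned minimum with near-uniform consensus, which is logged, not
asserted, because the null behavior of delta-area selection is known to
be weakly determined.

`cut_clusters()` orders cluster labels by descending size, breaking ties
by ascending centroid norm — the published tables do not define a label
order, so one convention is fixed and documented. An optional permutation
test (`cluster_separation_test()`) compares the between/within
sum-of-squares ratio of the chosen partition with the same statistic on
re-clustered Gaussian null data; it is an interpretation of "significant
clusters", not a reproduction of a published test, which is unnamed in
the source analysis.

**Entanglement.** Given the medium- and sharp-kernel dendrograms over the
same scans, `entanglement()` measures alignment of the displayed leaf
orders: with `x_i`, `y_i` the positions of scan i in the two orders, the
coefficient is `sum(|x_i − y_i|^L)` normalized by its maximum over
worst-case orderings, which for the default L = 1.5 (a convex power) is
attained by the reversed order; the result lies in [0, 1], 0 meaning
perfectly aligned. Before measuring, the two-sided step heuristic
(`untangle = "step2side"`) greedily flips subtrees of either tree while
the coefficient decreases; `"none"` measures the trees as built and is
the symmetric, definition-level quantity used in the oracle tests.

**Mapping.** `fit_centroids()` stores per-cluster means in the training
set's standardized space together with the standardization parameters;
`map_clusters()` standardizes an independent cohort *with the training
parameters* (required for centroid comparability — standardizing the new
cohort by its own statistics would silently shift the centroids) and
assigns each scan to the Euclidean-nearest centroid, ties to the lower
label.

## The synthetic-data generator

`make_phantom_volume()` builds a 64×64×64 voxel, 1 mm isotropic phantom
(small enough that a cohort runs in minutes): exterior air at −1000 HU, an
ellipsoidal soft-tissue body at +40 HU, and two ellipsoidal lung lobes of
parenchyma at −850 HU mean with Gaussian noise (SD 40 HU). Texture is a
Poisson field of hyperattenuating Gaussian blobs (+150 HU peak, truncated
at 2.5 sigma): phenotype 1 has 2 blobs/cm³ of radius 2 mm, phenotype 2 has
6 blobs/cm³ of radius 3 mm — denser and larger, hence coarser and more
heterogeneous texture with controllable GLCM/GLRLM consequences. The blob
field is deliberately *dense and mild* rather than sparse and strong: a
dense field has a small between-scan count coefficient of variation, so
heavy-tailed fourth-moment features (cluster shade/prominence) stay within
the residual-outlier fences and the phenotype contrast lands at a
realistic one-to-two pooled SDs per feature at cohort level, instead of a
caricatured separation that the outlier screen would mistake for artifact.
The within-lung mean is recentred to the configured parenchyma HU after
blob placement, so the phenotype contrast is purely textural rather than
a bulk attenuation shift; the blob peak keeps even overlapping blobs below
the −300 HU vessel-exclusion threshold. Lobe geometry keeps a ≥4 mm
soft-tissue shell everywhere so exterior air cannot leak into the lung
field through the 26-neighborhood.

The kernel pair is emulated minimally: "medium" is Gaussian smoothing
(sigma 1 mm), "sharp" is an unsharp mask (amount 1, radius 1 mm) of the
*same* seeded anatomy, reproducing the smooth/sharp reconstruction
contrast that drives the feature-distribution batch shift.

`generate_cohort()` draws covariates from the screening demographics the
generator emulates — age ~ N(64.8, 5.84), BMI ~ N(27.08, 6.04),
pack-years ~ N(52.47, 24.85), Lung-RADS group B at rate 46/308, cancer at
15/308, sex and smoking status Bernoulli(0.5) — clipped to plausible
ranges (age ≥ 40, BMI ≥ 15, pack-years ≥ 0). Phenotype 2 receives an
additive BMI shift (`bmi_effect`, default 4 kg/m², the order of the
published phenotype separation); this is a stand-in that makes
phenotype–covariate association recoverable, not a claim about biological
mechanism. The default phenotype-2 fraction (111/308) mirrors the
published cluster sizes at W = 4 mm.

`generate_feature_table()` bypasses imaging entirely: two multivariate
normal populations separated by a configurable shift, with per-batch
location/scale distortions following the ComBat generative model. It is
the workhorse for harmonization and clustering tests at realistic n.

**What the phantoms do not emulate:** airway trees, vessels (beyond the
exclusion threshold), nodules, dose/slice-thickness effects, scanner
drift, or spatially correlated noise. Tests passing on phantoms
demonstrate that the algorithms implement their definitions and recover
planted structure; they do not certify phenotype validity on patient
scans.

## Numerical choices and degenerate inputs

* Deterministic everywhere: every stochastic routine takes a seed and
  restores the caller's RNG state; identical (config, seed) reruns of the
  pipeline produce bit-identical artifacts and manifests.
* Zero-variance features are excluded from clustering distances (with a
  warning); zero-variance windows return the documented conventions
  (skewness/kurtosis/correlation 0); windows with no valid voxel pair are
  skipped.
* The 2.5 × IQR outlier rule carries a small numerical tolerance so
  exactly-constant residual vectors (IQR = 0) never self-flag.
* Chi-square tests on 2×2 tables apply the Yates continuity correction by
  default — the R default, and the convention under which the published
  contingency tables reproduce their printed p-values. Kruskal–Wallis
  uses the tie-corrected asymptotic statistic; at n = 8 the asymptotic
  p tracks the exact permutation p to about ±0.1 (the permutation null is
  lumpy at that size), which the tests assert at that honest level.
* Consensus pairs never co-sampled are treated as consensus 0 with a
  warning suggesting a higher subsample fraction.

## Problem sizes used in the shipped tests

The test suite runs the full pipeline on a 10-scan two-kernel cohort with
a 4-scan mapped validation cohort (64³ phantoms, all three window sizes),
consensus-clustering recovery on 20 replicates of the n = 120
feature-level cohort, and the harmonization/mapping simulations at
n = 200–500. These sizes were chosen so the whole suite completes in
about a minute while every assertion retains a comfortable margin; all of
them scale up through the exported configuration objects.

## Known limitations

* The lattice origin is anchored at the mask bounding box; features can
  shift slightly under sub-window translations of the anatomy.
* Entanglement depends on displayed leaf order, which is
  convention-dependent; the step2side heuristic is greedy and not
  guaranteed to find the global minimum over subtree flips.
* The association report treats covariates marginally (one test per
  covariate, flat 0.05 threshold, no multiplicity correction) —
  deliberately matching the published analysis style rather than best
  inferential practice.
* ComBat assumes additive location / multiplicative scale batch effects
  per feature; kernel effects that change feature *shape* beyond two
  moments are only partially removed, which is why the KS report is part
  of the pipeline output rather than an afterthought.
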