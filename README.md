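# lungpheno

Unsupervised radiomic phenotyping of the lung parenchyma from low-dose CT
(LDCT), for imaging scientists who want to ask: *does a screening cohort
contain distinct parenchymal texture phenotypes, are they robust to the CT
reconstruction kernel, and do they associate with clinical covariates?*

The pipeline:

1. **Lung-field segmentation** — deterministic intensity K-means on HU,
   border/exterior-air removal by 26-connected components, morphological
   closing, vessel exclusion above −300 HU.
2. **Lattice feature extraction** — the lung field is tiled with
   non-overlapping windows of edge *W* ∈ {4, 8, 20} mm; each window yields
   26 features (6 gray-level histogram, 9 co-occurrence/GLCM over the 13
   unique 3D directions, 11 run-length/GLRLM with the Galloway–Chu
   definitions, 32 fixed-range gray levels over [−1024, 200] HU); per-scan
   vectors are the unweighted window means.
3. **Harmonization** — residual outlier screening (median ± 2.5 × IQR of
   each feature residualized on age, BMI, pack-years), then parametric
   empirical-Bayes ComBat with kernel as batch and sex, Lung-RADS group,
   smoking status, age, BMI and pack-years protected; residual batch
   separation is reported as the count of features with a significant
   two-sample Kolmogorov–Smirnov test (α = 0.05).
4. **Phenotype derivation** — Ward (`ward.D2`) hierarchical clustering on
   z-scored features; the number of phenotypes K selected by Monti
   consensus clustering (250 resamples, 80% subsampling, delta-area
   criterion over K = 2…6).
5. **Robustness and validation** — cross-kernel dendrogram *entanglement*
   (leaf-order misalignment normalized to [0, 1] with norm exponent
   L = 1.5, two-sided step untangling; 0 = perfectly aligned) and
   nearest-centroid *cluster mapping* of independent cohorts in the
   training set's standardized space.
6. **Association reporting** — per-phenotype covariate tables:
   Kruskal–Wallis for continuous covariates, chi-square (Yates-corrected
   for 2×2) for categorical ones.

Patient LDCT cannot ship with code, so the package includes a synthetic
generator: two-lobe lung phantoms whose texture phenotypes are Poisson
fields of Gaussian blobs, paired "medium"/"sharp" kernel renderings of the
same seeded anatomy, and covariate tables drawn from screening-cohort
demographics (age 64.8 ± 5.84 y, BMI 27.08 ± 6.04 kg/m², pack-years
52.47 ± 24.85, Lung-RADS-positive rate 46/308, cancer rate 15/308), with a
BMI shift linked to the coarse-texture phenotype.

## Worked example

A small synthetic two-kernel cohort, end to end:

```r
library(lungpheno)

cfg <- pipeline_config(
  mode      = "synthetic",
  cohort    = cohort_config(n_scans = 20),
  cluster_k = 2,          # or "auto" for consensus selection
  seed      = 5L)
man <- run_pipeline(cfg, "run1")

unlist(man$entanglement)
#>         W4         W8        W20
#> 0.02277483 0.01235580 0.24339280
unlist(man$harmonization$W4)
#>        n_outlier_scans  ks_significant_before  ks_significant_after
#>                      3                     26                    22
unlist(man$clusters$medium_W4)
#>     k sizes1 sizes2
#>     2     13      4
```

Reading these numbers: the two kernels' phenotype dendrograms are nearly
perfectly aligned at W = 4 and 8 mm (entanglement 0.02, 0.01) and much
less so at W = 20 mm (0.24) — the small-window extractions are the ones
robust to the reconstruction kernel. At W = 4, the outlier screen dropped
3 of 40 renderings and ComBat reduced the count of kernel-separated
features. The medium-kernel cut at K = 2 splits 13 vs 4 scans, which here
matches the generator's planted phenotype labels exactly; its association
table (`run1/reports/association_medium_W4.csv`) shows the planted BMI
contrast, cluster 1 25.69 (5.88) vs cluster 2 31.65 (3.79) kg/m².

Consensus selection of the phenotype count, on the fast feature-level
simulator (two populations separated by 4 pooled SDs on 8 of 26 features):

```r
ft <- generate_feature_table(120, cluster_shift = c(rep(4, 8), rep(0, 18)),
                             seed = 1)
consensus_select_k(ft$features, k_range = 2:6, n_resamples = 250,
                   subsample_frac = 0.8, seed = 1)
#> <consensus_result> K scanned 2-6; selected K = 2
#>                 2      3      4      5      6
#> cdf_area   0.5042 0.6223 0.7279 0.7779 0.8160
#> delta_area 0.5042 0.2343 0.1696 0.0687 0.0489
```

Published screening contingency tables are exactly recomputable; e.g. the
cancer-by-phenotype table 183/14 vs 110/1:

```r
chi_square_2x2(matrix(c(183, 14, 110, 1), 2, byrow = TRUE))$p_value
#> [1] 0.03127081
```

A thin command-line front-end wraps the same functions:

```sh
phenotyper=$(Rscript -e 'cat(system.file("cli/phenotyper", package = "lungpheno"))')
Rscript $phenotyper run --config cohort.yaml --out run1 --seed 5
Rscript $phenotyper segment --in scan.nii.gz --out mask.nii.gz
Rscript $phenotyper extract --scan scan.nii.gz --mask mask.nii.gz \
        --windows 4,8,20 --out features.csv
```

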