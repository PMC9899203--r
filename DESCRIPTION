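Package: lungpheno
Title: Lattice Radiomic Phenotyping of the Lung Parenchyma from Low-Dose CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for unsupervised radiomic phenotyping of
    the lung parenchyma on segmented low-dose CT. Extracts 26 three-dimensional
    texture features (gray-level histogram, co-occurrence and run-length
    descriptors) over non-overlapping lattice windows of configurable physical
    size, harmonizes feature distributions across CT reconstruction kernels
    with parametric empirical-Bayes ComBat while protecting clinical
    covariates, derives parenchymal phenotypes by Ward hierarchical clustering
    with Monti consensus selection of the number of clusters, quantifies the
    robustness of phenotypes across kernels with a dendrogram entanglement
    coefficient, maps phenotypes to independent cohorts by nearest-centroid
    assignment, and reports per-phenotype covariate associations
    (Kruskal-Wallis and chi-square). Includes a synthetic CT phantom and
    cohort generator so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    sva
Config/testthat/edition: 3
RoxygenNote: 7.3.3
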