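#' Canonical radiomic feature names
#'
#' The 26 texture features computed per lattice window: 6 gray-level
#' histogram (first-order) statistics, 9 gray-level co-occurrence (GLCM)
#' features and 11 gray-level run-length (GLRLM) features.
#'
#' @return Character vector of length 26.
#' @export
feature_names <- function() {
  c(paste0("hist_", c("mean", "variance", "skewness", "kurtosis",
                      "entropy", "uniformity")),
    paste0("glcm_", c("contrast", "correlation", "energy", "homogeneity",
                      "entropy", "dissimilarity", "cluster_shade",
                      "cluster_prominence", "max_probability")),
    paste0("glrlm_", c("sre", "lre", "gln", "rln", "rp", "lgre", "hgre",
                       "srlge", "srhge", "lrlge", "lrhge")))
}

#' Synthetic cohort configuration
#'
#' Defaults encode the screening-cohort demographics the generator emulates:
#' age ~ N(64.8, 5.84) years, BMI ~ N(27.08, 6.04) kg/m2, smoking pack-years
#' ~ N(52.47, 24.85), positive Lung-RADS (group B) with probability 46/308
#' and confirmed cancer with probability 15/308. Phenotype 2 (the coarser,
#' more heterogeneous parenchymal texture) receives an additive `bmi_effect`
#' (kg/m2) so phenotype-covariate associations are recoverable downstream.
#'
#' @param n_scans Number of acquisitions (>= 4); each is rendered under both
#'   reconstruction kernels.
#' @param phenotype_fraction Probability that a scan carries phenotype 2
#'   (denser, larger hyperattenuating blobs); must lie in (0, 1\], and 1 means
#'   all scans are phenotype 2.
#' @param texture_params Per-phenotype texture model: blob density (1/cm3),
#'   blob radius (mm), parenchyma mean HU and noise SD (HU).
#' @param kernel_pair Reconstruction-kernel emulation: `medium` is Gaussian
#'   smoothing (sigma, mm); `sharp` is an unsharp mask (amount, radius mm).
#' @param covariate_means_sds Means/SDs of age, BMI and pack-years.
#' @param bmi_effect Additive BMI shift (kg/m2) for phenotype-2 scans.
#' @param lungrads_b_prob,cancer_prob Bernoulli rates of Lung-RADS group B
#'   and cancer diagnosis.
#' @param emit_obstruction Emit an `obstruction` flag column (for
#'   PFT-style validation cohorts)?
#' @param obstruction_prob Bernoulli rate of obstruction when emitted.
#' @param dim Phantom grid size in voxels.
#' @param spacing Voxel spacing in mm.
#' @param seed Integer seed; identical (config, seed) pairs reproduce
#'   identical cohorts.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_scans = 60,
                          phenotype_fraction = 111 / 308,
                          texture_params = list(
                            `1` = list(blob_density = 2.0, blob_radius = 2,
                                       parenchyma_hu = -850, noise_sd = 40),
                            `2` = list(blob_density = 6.0, blob_radius = 3,
                                       parenchyma_hu = -850, noise_sd = 40)),
                          kernel_pair = list(
                            medium = list(sigma = 1.0),
                            sharp = list(amount = 1.0, radius = 1.0)),
                          covariate_means_sds = list(
                            age = c(64.8, 5.84),
                            bmi = c(27.08, 6.04),
                            pack_years = c(52.47, 24.85)),
                          bmi_effect = 4,
                          lungrads_b_prob = 46 / 308,
                          cancer_prob = 15 / 308,
                          emit_obstruction = FALSE,
                          obstruction_prob = 0.5,
                          dim = c(64, 64, 64),
                          spacing = c(1, 1, 1),
                          seed = 1L) {
  cfg <- list(n_scans = n_scans, phenotype_fraction = phenotype_fraction,
              texture_params = texture_params, kernel_pair = kernel_pair,
              covariate_means_sds = covariate_means_sds,
              bmi_effect = bmi_effect, lungrads_b_prob = lungrads_b_prob,
              cancer_prob = cancer_prob, emit_obstruction = emit_obstruction,
              obstruction_prob = obstruction_prob, dim = dim,
              spacing = spacing, seed = seed)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (!is_count(cfg$n_scans) || cfg$n_scans < 4)
    stopf("`n_scans` must be an integer >= 4")
  if (!(cfg$phenotype_fraction > 0 && cfg$phenotype_fraction <= 1))
    stopf("`phenotype_fraction` must lie in (0, 1]")
  for (ph in c("1", "2")) {
    tp <- cfg$texture_params[[ph]]
    if (tp$noise_sd <= 0) stopf("noise SD must be > 0")
    if (tp$blob_radius <= 0) stopf("blob radius must be > 0")
    if (tp$blob_density < 0) stopf("blob density must be >= 0")
  }
  for (cv in cfg$covariate_means_sds)
    if (cv[2] <= 0) stopf("covariate SDs must be > 0")
  invisible(cfg)
}

# Lung lobe geometry of the phantom (fractions of the grid extent). Two
# ellipsoidal lobes inside a soft-tissue body; tuned so a 20 mm lattice
# window still fits inside a lobe on the default 64 mm grid.
phantom_geometry <- function(dim, spacing) {
  extent <- dim * spacing
  ctr <- extent / 2
  list(
    body_center = ctr,
    body_semi = extent * c(0.47, 0.46, 0.47),
    lobe_centers = list(ctr + c(-0.19, 0, 0) * extent[1] * c(1, 0, 0),
                        ctr + c(+0.19, 0, 0) * extent[1] * c(1, 0, 0)),
    lobe_semi = extent * c(0.17, 0.29, 0.33)
  )
}

ellipsoid_mask <- function(dim, spacing, center, semi) {
  cx <- (seq_len(dim[1]) - 0.5) * spacing[1]
  cy <- (seq_len(dim[2]) - 0.5) * spacing[2]
  cz <- (seq_len(dim[3]) - 0.5) * spacing[3]
  ux <- ((cx - center[1]) / semi[1])^2
  uy <- ((cy - center[2]) / semi[2])^2
  uz <- ((cz - center[3]) / semi[3])^2
  outer(outer(ux, uy, `+`), uz, `+`) <= 1
}

#' Generate a synthetic lung CT phantom
#'
#' Builds an ellipsoidal two-lobe "lung" of low-attenuation parenchyma
#' (mean ~ -850 HU plus Gaussian noise) inside a soft-tissue shell (+40 HU)
#' surrounded by exterior air (-1000 HU). Texture is controlled by randomly
#' placed hyperattenuating Gaussian blobs (Poisson count per cm3 of lung):
#' phenotype 2 carries denser, larger blobs, i.e. coarser and more
#' heterogeneous texture. The same seeded anatomy is then rendered through a
#' reconstruction-kernel emulator: kernel `"medium"` applies Gaussian
#' smoothing, kernel `"sharp"` an unsharp mask, so renderings of one seed
#' share their anatomy (and truth mask) but differ in voxel values.
#'
#' @param phenotype 1 or 2.
#' @param kernel `"medium"` or `"sharp"`.
#' @param spacing Voxel spacing in mm (all > 0).
#' @param seed Integer seed controlling anatomy and noise.
#' @param dim Grid size in voxels.
#' @param texture_params Blob density (1/cm3), blob radius (mm), parenchyma
#'   mean HU, noise SD; defaults from [cohort_config()] for the phenotype.
#' @param kernel_pair Kernel filter parameters, as in [cohort_config()].
#' @param scan_id Identifier recorded in the volume.
#' @return A `synthetic_scan`: list with `volume` ([ct_volume()]),
#'   `truth_mask` ([lung_mask()]), `phenotype_label`, `kernel_label`,
#'   `scan_id`.
#' @export
make_phantom_volume <- function(phenotype, kernel = c("medium", "sharp"),
                                spacing = c(1, 1, 1), seed = 1L,
                                dim = c(64, 64, 64),
                                texture_params = NULL,
                                kernel_pair = NULL,
                                scan_id = NULL) {
  kernel <- match.arg(kernel)
  if (!phenotype %in% c(1, 2)) stopf("`phenotype` must be 1 or 2")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("`spacing` must be 3 strictly positive mm values")
  defaults <- cohort_config()
  if (is.null(texture_params))
    texture_params <- defaults$texture_params[[as.character(phenotype)]]
  if (is.null(kernel_pair)) kernel_pair <- defaults$kernel_pair
  if (is.null(scan_id))
    scan_id <- sprintf("phantom-p%d-s%d", phenotype, seed)

  geom <- phantom_geometry(dim, spacing)
  body <- ellipsoid_mask(dim, spacing, geom$body_center, geom$body_semi)
  lung <- ellipsoid_mask(dim, spacing, geom$lobe_centers[[1]],
                         geom$lobe_semi) |
    ellipsoid_mask(dim, spacing, geom$lobe_centers[[2]], geom$lobe_semi)
  lung <- lung & body

  base <- with_rng_seed(seed, {
    v <- array(-1000, dim)
    v[body] <- 40
    v[lung] <- texture_params$parenchyma_hu +
      rnorm(sum(lung), sd = texture_params$noise_sd)
    lung_cm3 <- sum(lung) * prod(spacing) / 1000
    n_blobs <- rpois(1, texture_params$blob_density * lung_cm3)
    if (n_blobs > 0) {
      lung_idx <- which(lung, arr.ind = TRUE)
      centers <- lung_idx[sample.int(nrow(lung_idx), n_blobs,
                                     replace = TRUE), , drop = FALSE]
      v <- add_blobs(v, centers, texture_params$blob_radius,
                     amplitude = 150, spacing = spacing, lung = lung)
    }
    # `parenchyma_hu` is the realized within-lung mean: recentre so the blob
    # load contributes texture (variance), not a bulk attenuation shift
    v[lung] <- v[lung] - mean(v[lung]) + texture_params$parenchyma_hu
    v
  })

  filtered <- if (kernel == "medium") {
    gaussian_blur3d(base, kernel_pair$medium$sigma, spacing)
  } else {
    blur <- gaussian_blur3d(base, kernel_pair$sharp$radius, spacing)
    base + kernel_pair$sharp$amount * (base - blur)
  }

  structure(list(
    volume = ct_volume(filtered, spacing, scan_id),
    truth_mask = lung_mask(lung),
    phenotype_label = as.integer(phenotype),
    kernel_label = kernel,
    scan_id = scan_id), class = "synthetic_scan")
}

# Add Gaussian hyperattenuating blobs (fixed +150 HU peak) at voxel-index
# centers; each blob is truncated at 2.5 sigma and confined to the lung.
add_blobs <- function(v, centers, radius_mm, amplitude, spacing, lung) {
  sig <- radius_mm / 2
  half <- ceiling(2.5 * sig / spacing)
  d <- dim(v)
  for (b in seq_len(nrow(centers))) {
    c0 <- centers[b, ]
    rng <- lapply(1:3, function(a)
      max(1L, c0[a] - half[a]):min(d[a], c0[a] + half[a]))
    dx2 <- ((rng[[1]] - c0[1]) * spacing[1])^2
    dy2 <- ((rng[[2]] - c0[2]) * spacing[2])^2
    dz2 <- ((rng[[3]] - c0[3]) * spacing[3])^2
    r2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    patch <- amplitude * exp(-r2 / (2 * sig^2))
    patch[r2 > (2.5 * sig)^2] <- 0
    sub <- v[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    inl <- lung[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    sub[inl] <- sub[inl] + patch[inl]
    v[rng[[1]], rng[[2]], rng[[3]]] <- sub
  }
  v
}

#' Generate a synthetic screening cohort
#'
#' Draws `n_scans` acquisitions with phenotype labels sampled by
#' `phenotype_fraction` (the probability of phenotype 2), renders each under
#' both reconstruction kernels via [make_phantom_volume()], and draws the
#' covariate table: age, BMI (plus `bmi_effect` for phenotype-2 scans) and
#' pack-years from the configured normals, sex and smoking status
#' Bernoulli(0.5), Lung-RADS group B and cancer at their configured rates.
#' Values are clipped to plausible ranges (age >= 40, BMI >= 15,
#' pack-years >= 0).
#'
#' @param config A [cohort_config()].
#' @return List with `scans` (list of `synthetic_scan`, two kernel renderings
#'   per acquisition) and `covariates` (data.frame, one row per rendering
#'   with columns scan_id, kernel, age, bmi, pack_years, sex, smoking_status,
#'   lungrads_group, cancer, optionally obstruction, true_phenotype).
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  n <- config$n_scans
  cm <- config$covariate_means_sds
  drawn <- with_rng_seed(config$seed, {
    phenotype <- 1L + rbinom(n, 1, config$phenotype_fraction)
    list(
      phenotype = phenotype,
      scan_seed = sample.int(.Machine$integer.max %/% 2, n),
      age = pmax(40, rnorm(n, cm$age[1], cm$age[2])),
      bmi = pmax(15, rnorm(n, cm$bmi[1], cm$bmi[2]) +
                   config$bmi_effect * (phenotype == 2L)),
      pack_years = pmax(0, rnorm(n, cm$pack_years[1], cm$pack_years[2])),
      sex = ifelse(rbinom(n, 1, 0.5) == 1, "male", "female"),
      smoking_status = ifelse(rbinom(n, 1, 0.5) == 1, "current", "former"),
      lungrads_group = ifelse(rbinom(n, 1, config$lungrads_b_prob) == 1,
                              "B", "A"),
      cancer = ifelse(rbinom(n, 1, config$cancer_prob) == 1, "yes", "no"),
      obstruction = ifelse(rbinom(n, 1, config$obstruction_prob) == 1,
                           "yes", "no"))
  })

  scan_ids <- sprintf("S%03d", seq_len(n))
  scans <- list()
  for (i in seq_len(n)) {
    for (k in c("medium", "sharp")) {
      sc <- make_phantom_volume(
        phenotype = drawn$phenotype[i], kernel = k,
        spacing = config$spacing, seed = drawn$scan_seed[i],
        dim = config$dim,
        texture_params =
          config$texture_params[[as.character(drawn$phenotype[i])]],
        kernel_pair = config$kernel_pair,
        scan_id = scan_ids[i])
      scans[[paste(scan_ids[i], k, sep = "_")]] <- sc
    }
  }

  cov1 <- data.frame(
    scan_id = scan_ids, age = drawn$age, bmi = drawn$bmi,
    pack_years = drawn$pack_years, sex = drawn$sex,
    smoking_status = drawn$smoking_status,
    lungrads_group = drawn$lungrads_group, cancer = drawn$cancer,
    stringsAsFactors = FALSE)
  if (config$emit_obstruction) cov1$obstruction <- drawn$obstruction
  cov1$true_phenotype <- drawn$phenotype
  covariates <- rbind(
    cbind(data.frame(kernel = "medium"), cov1),
    cbind(data.frame(kernel = "sharp"), cov1))
  covariates <- covariates[order(covariates$scan_id, covariates$kernel),
                           c("scan_id", "kernel",
                             setdiff(names(cov1), "scan_id"))]
  rownames(covariates) <- NULL
  list(scans = scans, covariates = covariates)
}

#' Fast feature-level cohort simulator
#'
#' Bypasses the imaging stages: draws a 26-feature matrix from two
#' multivariate-normal populations separated by `cluster_shift`, then applies
#' per-batch location/scale distortions following the ComBat generative model
#' (y = location + scale * x). Used to exercise harmonization and clustering
#' at scale.
#'
#' @param n Number of rows (>= 4). The first `n - round(n*cluster_fraction)`
#'   rows are population 1, the rest population 2.
#' @param cluster_shift Scalar or length-26 additive mean shift (in SD units,
#'   the base populations being standard normal) applied to population 2.
#' @param batch_effects Named list, one element per batch, each a list with
#'   `location` and `scale` (scalar or length 26, scale > 0). Batches are
#'   assigned by cycling over rows. `NULL` for a single unlabelled batch.
#' @param seed Integer seed.
#' @param cluster_fraction Fraction of rows in population 2.
#' @return List with `features` (n x 26 matrix, rownames = scan ids),
#'   `batch` (factor), `cluster` (integer truth labels), `scan_id`.
#' @export
generate_feature_table <- function(n, cluster_shift = 0,
                                   batch_effects = NULL, seed = 1L,
                                   cluster_fraction = 0.5) {
  if (!is_count(n) || n < 4) stopf("`n` must be an integer >= 4")
  p <- 26L
  shift <- rep_len(cluster_shift, p)
  n2 <- round(n * cluster_fraction)
  cluster <- rep(c(1L, 2L), c(n - n2, n2))
  if (!is.null(batch_effects)) {
    if (is.null(names(batch_effects)) || any(names(batch_effects) == ""))
      stopf("`batch_effects` must be a named list")
    for (be in batch_effects)
      if (any(rep_len(be$scale, p) <= 0))
        stopf("batch scale effects must be > 0")
    batch <- factor(rep_len(names(batch_effects), n),
                    levels = names(batch_effects))
  } else {
    batch <- factor(rep("batch1", n))
  }
  x <- with_rng_seed(seed, matrix(rnorm(n * p), n, p))
  x[cluster == 2L, ] <- sweep(x[cluster == 2L, , drop = FALSE], 2, shift, `+`)
  if (!is.null(batch_effects)) {
    for (b in names(batch_effects)) {
      rows <- which(batch == b)
      loc <- rep_len(batch_effects[[b]]$location, p)
      scl <- rep_len(batch_effects[[b]]$scale, p)
      x[rows, ] <- sweep(sweep(x[rows, , drop = FALSE], 2, scl, `*`),
                         2, loc, `+`)
    }
  }
  colnames(x) <- feature_names()
  scan_id <- sprintf("S%03d", seq_len(n))
  rownames(x) <- scan_id
  list(features = x, batch = batch, cluster = cluster, scan_id = scan_id)
}
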