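#' Pipeline configuration
#'
#' A single configuration object driving the full phenotyping analysis:
#' simulate (or load) -> segment -> lattice extraction per window size and
#' kernel -> ComBat harmonization (batch = kernel) -> per-kernel clustering
#' with consensus K -> cross-kernel entanglement -> optional centroid
#' mapping of an independent cohort -> association reports.
#'
#' @param mode `"synthetic"` (generate phantoms) or `"nifti"` (read volumes
#'   from `paths$volumes_dir` named `<scan_id>_<kernel>.nii.gz`, with a
#'   covariate CSV at `paths$covariates`).
#' @param cohort A [cohort_config()] for synthetic mode; its seed is
#'   overridden by `seed`.
#' @param map_cohort Optional [cohort_config()] for an independent
#'   validation cohort mapped onto the learned phenotype centroids, or
#'   `NULL`.
#' @param lattice A [lattice_spec()]; `window_mm` lists every window size
#'   analyzed.
#' @param segmentation A [segmentation_params()].
#' @param harmonization A [harmonization_config()].
#' @param cluster_k `"auto"` (consensus selection over `k_range`) or a fixed
#'   integer K.
#' @param k_range,n_resamples,subsample_frac Consensus-clustering settings.
#' @param entanglement_l,untangle Entanglement norm exponent and untangling
#'   method.
#' @param paths Named list of input paths for nifti mode.
#' @param seed Integer master seed recorded in all outputs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("synthetic", "nifti"),
                            cohort = cohort_config(),
                            map_cohort = NULL,
                            lattice = lattice_spec(),
                            segmentation = segmentation_params(),
                            harmonization = harmonization_config(),
                            cluster_k = "auto",
                            k_range = 2:6, n_resamples = 250,
                            subsample_frac = 0.8,
                            entanglement_l = 1.5, untangle = "step2side",
                            paths = list(), seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "nifti") {
    for (p in unlist(paths))
      if (!file.exists(p)) stopf("configured path does not exist: %s", p)
  }
  structure(list(mode = mode, cohort = cohort, map_cohort = map_cohort,
                 lattice = lattice, segmentation = segmentation,
                 harmonization = harmonization, cluster_k = cluster_k,
                 k_range = k_range, n_resamples = n_resamples,
                 subsample_frac = subsample_frac,
                 entanglement_l = entanglement_l, untangle = untangle,
                 paths = paths, seed = as.integer(seed)),
            class = "pipeline_config")
}

feature_csv_cols <- function() c("scan_id", "kernel", "window_mm",
                                 "n_windows_used", feature_names())

write_feature_rows <- function(vectors, path) {
  rows <- lapply(vectors, function(fv)
    data.frame(scan_id = attr(fv, "scan_id"),
               kernel = attr(fv, "kernel_label"),
               window_mm = attr(fv, "window_mm"),
               n_windows_used = attr(fv, "n_windows_used"),
               t(unclass(fv)), stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  names(df) <- feature_csv_cols()
  write.csv(df, path, row.names = FALSE)
  df
}

read_feature_csv <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Run the full phenotyping pipeline
#'
#' Executes every stage into `out_dir`, caching by file: a stage whose
#' output files already exist is skipped, so deleting downstream artifacts
#' and re-running reproduces them bit-identically from the cached upstream
#' stages. A JSON provenance manifest (seed, config hash, per-file MD5
#' checksums, per-stage key results) is rewritten at the end of every run.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output run directory (created if missing).
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("volumes", "masks", "features", "harmonized", "clusters",
              "reports"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)

  kernels <- c("medium", "sharp")
  windows <- config$lattice$window_mm
  cov_csv <- file.path(out_dir, "covariates.csv")

  ## stage: simulate (or ingest)
  if (config$mode == "synthetic") {
    cohort_cfg <- config$cohort
    cohort_cfg$seed <- config$seed
    vol_paths <- function(cov)
      file.path(out_dir, "volumes",
                paste0(cov$scan_id, "_", cov$kernel, ".nii.gz"))
    if (!file.exists(cov_csv)) {
      cohort <- tryCatch(generate_cohort(cohort_cfg), error = function(e)
        stage_error("simulate", "generation_failed", conditionMessage(e)))
      write.csv(cohort$covariates, cov_csv, row.names = FALSE)
      for (sc in cohort$scans)
        write_nifti_volume(sc$volume,
                           file.path(out_dir, "volumes",
                                     paste0(sc$scan_id, "_",
                                            sc$kernel_label, ".nii.gz")))
    }
    covariates <- read.csv(cov_csv, stringsAsFactors = FALSE)
    volume_files <- vol_paths(covariates)
  } else {
    covariates <- read.csv(config$paths$covariates, stringsAsFactors = FALSE)
    write.csv(covariates, cov_csv, row.names = FALSE)
    volume_files <- file.path(config$paths$volumes_dir,
                              paste0(covariates$scan_id, "_",
                                     covariates$kernel, ".nii.gz"))
    missing <- volume_files[!file.exists(volume_files)]
    if (length(missing) > 0)
      stage_error("ingest", "missing_volume",
                  paste("missing volumes:",
                        paste(basename(missing), collapse = ", ")))
  }

  ## stage: segment
  mask_files <- file.path(out_dir, "masks",
                          paste0(covariates$scan_id, "_", covariates$kernel,
                                 "_mask.nii.gz"))
  for (i in seq_along(volume_files)) {
    if (file.exists(mask_files[i])) next
    vol <- read_ct_nifti(volume_files[i], scan_id = covariates$scan_id[i])
    mask <- tryCatch(segment_lung(vol, config$segmentation),
                     error = function(e)
                       stage_error("segment", "no_lung_field",
                                   conditionMessage(e),
                                   scan_id = covariates$scan_id[i]))
    write_nifti_volume(mask, mask_files[i])
  }

  ## stage: extract
  for (k in kernels) {
    rows_k <- which(covariates$kernel == k)
    fpaths <- file.path(out_dir, "features",
                        sprintf("features_%s_W%g.csv", k, windows))
    if (all(file.exists(fpaths))) next
    per_scan <- lapply(rows_k, function(i) {
      vol <- read_ct_nifti(volume_files[i], scan_id = covariates$scan_id[i])
      mask <- read_mask_nifti(mask_files[i])
      tryCatch(extract_scan(vol, mask, config$lattice, kernel_label = k),
               error = function(e)
                 stage_error("extract", "no_valid_windows",
                             conditionMessage(e),
                             scan_id = covariates$scan_id[i]))
    })
    for (wi in seq_along(windows)) {
      vecs <- lapply(per_scan, `[[`, wi)
      write_feature_rows(vecs, fpaths[wi])
    }
  }

  ## stage: harmonize (batch = kernel), per window size
  harmonize_info <- list()
  for (w in windows) {
    hpath <- file.path(out_dir, "harmonized",
                       sprintf("harmonized_W%g.csv", w))
    kpath <- file.path(out_dir, "harmonized",
                       sprintf("ks_report_W%g.csv", w))
    stacked <- do.call(rbind, lapply(kernels, function(k)
      read_feature_csv(file.path(out_dir, "features",
                                 sprintf("features_%s_W%g.csv", k, w)))))
    cov_rows <- covariates[match(paste(stacked$scan_id, stacked$kernel),
                                 paste(covariates$scan_id,
                                       covariates$kernel)), ]
    fx <- as.matrix(stacked[, feature_names()])
    rownames(fx) <- paste(stacked$scan_id, stacked$kernel, sep = "_")

    flags <- flag_outliers(fx, cov_rows, config$harmonization)
    keep <- rep(TRUE, nrow(fx))
    if (config$harmonization$drop_outliers && any(flags$flagged)) {
      # drop the whole acquisition so kernel leaf sets stay comparable
      bad_scans <- unique(stacked$scan_id[flags$flagged])
      keep <- !(stacked$scan_id %in% bad_scans)
    }
    ks_before <- ks_batch_assessment(fx[keep, , drop = FALSE],
                                     stacked$kernel[keep],
                                     config$harmonization)
    model <- tryCatch(
      combat_fit(fx[keep, , drop = FALSE], stacked$kernel[keep],
                 cov_rows[keep, , drop = FALSE], config$harmonization),
      error = function(e)
        stage_error("harmonize", "combat_fit_failed", conditionMessage(e)))
    hx <- combat_apply(model, fx[keep, , drop = FALSE],
                       stacked$kernel[keep], cov_rows[keep, , drop = FALSE])
    ks_after <- ks_batch_assessment(hx, stacked$kernel[keep],
                                    config$harmonization)

    if (!file.exists(hpath)) {
      hdf <- cbind(stacked[keep, c("scan_id", "kernel", "window_mm",
                                   "n_windows_used")], as.data.frame(hx))
      write.csv(hdf, hpath, row.names = FALSE)
      ks_df <- data.frame(feature = ks_before$table$feature,
                          D_before = ks_before$table$D,
                          p_before = ks_before$table$p,
                          D_after = ks_after$table$D,
                          p_after = ks_after$table$p)
      write.csv(ks_df, kpath, row.names = FALSE)
    }
    harmonize_info[[paste0("W", w)]] <- list(
      n_outlier_scans = sum(flags$flagged),
      ks_significant_before = ks_before$n_significant,
      ks_significant_after = ks_after$n_significant)
  }

  ## stage: cluster per kernel and window size
  cluster_info <- list()
  dendrograms <- list()
  assignments_all <- list()
  for (w in windows) {
    hdf <- read.csv(file.path(out_dir, "harmonized",
                              sprintf("harmonized_W%g.csv", w)),
                    stringsAsFactors = FALSE)
    for (k in kernels) {
      sub <- hdf[hdf$kernel == k, ]
      fx <- as.matrix(sub[, feature_names()])
      rownames(fx) <- sub$scan_id
      dend <- hierarchical_cluster(fx)
      key <- sprintf("%s_W%g", k, w)
      dendrograms[[key]] <- dend
      if (identical(config$cluster_k, "auto")) {
        cons <- consensus_select_k(fx, k_range = config$k_range,
                                   n_resamples = config$n_resamples,
                                   subsample_frac = config$subsample_frac,
                                   seed = config$seed)
        sel_k <- cons$selected_k
        cons_path <- file.path(out_dir, "clusters",
                               sprintf("consensus_%s.json", key))
        if (!file.exists(cons_path))
          jsonlite::write_json(list(k_range = cons$k_range,
                                    cdf_area = cons$cdf_area,
                                    delta_area = cons$delta_area,
                                    selected_k = cons$selected_k,
                                    settings = cons$settings),
                               cons_path, auto_unbox = TRUE, digits = NA,
                               pretty = TRUE)
      } else {
        sel_k <- as.integer(config$cluster_k)
      }
      asg <- cut_clusters(dend, sel_k)
      assignments_all[[key]] <- asg
      apath <- file.path(out_dir, "clusters",
                         sprintf("assignments_%s.csv", key))
      if (!file.exists(apath))
        write.csv(data.frame(scan_id = names(asg), cluster = asg),
                  apath, row.names = FALSE)
      cluster_info[[key]] <- list(k = sel_k,
                                  sizes = as.integer(tabulate(asg, sel_k)))
    }
  }

  ## stage: entanglement across kernels, per window size
  entanglement_per_w <- list()
  for (w in windows) {
    ent <- entanglement(dendrograms[[sprintf("medium_W%g", w)]],
                        dendrograms[[sprintf("sharp_W%g", w)]],
                        L = config$entanglement_l,
                        untangle = config$untangle)
    entanglement_per_w[[paste0("W", w)]] <- ent$coefficient
  }
  ent_path <- file.path(out_dir, "reports", "entanglement.json")
  if (!file.exists(ent_path))
    jsonlite::write_json(list(coefficients = entanglement_per_w,
                              L = config$entanglement_l,
                              untangle = config$untangle),
                         ent_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)

  ## stage: association reports per kernel and window size
  for (w in windows) for (k in kernels) {
    key <- sprintf("%s_W%g", k, w)
    rpath <- file.path(out_dir, "reports",
                       sprintf("association_%s.csv", key))
    if (file.exists(rpath)) next
    cov_k <- covariates[covariates$kernel == k, ]
    rep_tab <- build_association_table(assignments_all[[key]], cov_k)
    write.csv(rep_tab, rpath, row.names = FALSE)
  }

  ## stage: map an independent cohort (optional)
  mapping_info <- NULL
  if (!is.null(config$map_cohort)) {
    mapping_info <- run_mapping_stage(config, out_dir, assignments_all,
                                      windows)
  }

  ## provenance manifest
  cfg_json <- jsonlite::toJSON(unclass_recursive(config), auto_unbox = TRUE,
                               digits = NA)
  files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  checksums <- as.list(setNames(unname(tools::md5sum(files)),
                                sub(paste0("^", out_dir, "/?"), "", files)))
  manifest <- list(
    package = "lungpheno",
    version = as.character(utils::packageVersion("lungpheno")),
    seed = config$seed,
    config_hash = md5_of_string(as.character(cfg_json)),
    windows_mm = windows,
    harmonization = harmonize_info,
    clusters = cluster_info,
    entanglement = entanglement_per_w,
    mapping = mapping_info,
    checksums = checksums)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

unclass_recursive <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_recursive))
  x
}

# Independent-cohort stage: simulate, segment and extract the validation
# cohort (single "medium" rendering), learn centroids from the training
# medium-kernel harmonized features, map, and report associations.
run_mapping_stage <- function(config, out_dir, assignments_all, windows) {
  map_dir <- file.path(out_dir, "mapped")
  dir.create(map_dir, showWarnings = FALSE)
  map_cfg <- config$map_cohort
  map_cfg$seed <- config$seed + 1L

  mcov_csv <- file.path(map_dir, "covariates.csv")
  fpaths <- file.path(map_dir, sprintf("features_W%g.csv", windows))
  if (!file.exists(mcov_csv) || !all(file.exists(fpaths))) {
    cohort <- generate_cohort(map_cfg)
    med <- cohort$scans[vapply(cohort$scans, function(s)
      s$kernel_label == "medium", logical(1))]
    cov <- cohort$covariates[cohort$covariates$kernel == "medium", ]
    write.csv(cov, mcov_csv, row.names = FALSE)
    per_scan <- lapply(med, function(sc) {
      mask <- segment_lung(sc$volume, config$segmentation)
      extract_scan(sc$volume, mask, config$lattice, kernel_label = "medium")
    })
    for (wi in seq_along(windows))
      write_feature_rows(lapply(per_scan, `[[`, wi), fpaths[wi])
  }
  mcov <- read.csv(mcov_csv, stringsAsFactors = FALSE)

  info <- list()
  for (wi in seq_along(windows)) {
    w <- windows[wi]
    hdf <- read.csv(file.path(out_dir, "harmonized",
                              sprintf("harmonized_W%g.csv", w)),
                    stringsAsFactors = FALSE)
    train <- hdf[hdf$kernel == "medium", ]
    fx <- as.matrix(train[, feature_names()])
    rownames(fx) <- train$scan_id
    key <- sprintf("medium_W%g", w)
    model <- fit_centroids(fx, assignments_all[[key]][train$scan_id])

    new_df <- read_feature_csv(fpaths[wi])
    nx <- as.matrix(new_df[, feature_names()])
    rownames(nx) <- new_df$scan_id
    mapped <- map_clusters(model, nx)
    mpath <- file.path(map_dir, sprintf("mapped_W%g.csv", w))
    if (!file.exists(mpath))
      write.csv(data.frame(scan_id = names(mapped), cluster = mapped),
                mpath, row.names = FALSE)
    rpath <- file.path(out_dir, "reports",
                       sprintf("mapped_association_W%g.csv", w))
    if (!file.exists(rpath) && length(unique(mapped)) > 1)
      write.csv(build_association_table(mapped, mcov), rpath,
                row.names = FALSE)
    info[[paste0("W", w)]] <- list(
      sizes = as.integer(tabulate(mapped, nrow(model$centroids))))
  }
  info
}
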