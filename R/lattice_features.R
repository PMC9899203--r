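#' Lattice extraction specification
#'
#' @param window_mm Lattice window edge length(s) in mm; the defaults 4, 8
#'   and 20 mm probe texture at increasing spatial scale.
#' @param min_occupancy Minimum fraction of in-mask voxels for a window to be
#'   evaluated, in (0, 1\].
#' @param n_gray_levels Number of gray levels for quantization (>= 2).
#' @param hu_clip HU interval for fixed-range quantization; fixed (rather
#'   than per-window) so gray levels are comparable across windows and scans.
#' @param glcm_distance Co-occurrence offset in voxels.
#' @return A `lattice_spec` list.
#' @export
lattice_spec <- function(window_mm = c(4, 8, 20), min_occupancy = 0.5,
                         n_gray_levels = 32L, hu_clip = c(-1024, 200),
                         glcm_distance = 1L) {
  if (any(window_mm <= 0)) stopf("`window_mm` must be > 0")
  if (!(min_occupancy > 0 && min_occupancy <= 1))
    stopf("`min_occupancy` must lie in (0, 1]")
  if (!is_count(n_gray_levels) || n_gray_levels < 2)
    stopf("`n_gray_levels` must be >= 2")
  if (length(hu_clip) != 2L || hu_clip[1] >= hu_clip[2])
    stopf("`hu_clip` lower bound must be below the upper bound")
  structure(list(window_mm = window_mm, min_occupancy = min_occupancy,
                 n_gray_levels = as.integer(n_gray_levels),
                 hu_clip = hu_clip, glcm_distance = as.integer(glcm_distance)),
            class = "lattice_spec")
}

#' Quantize HU values to gray levels
#'
#' Values are clamped to `spec$hu_clip` and linearly binned into
#' `spec$n_gray_levels` equal-width levels 1..n over the fixed clip range;
#' the upper clip bound maps to level n. NA values stay NA.
#'
#' @param values Numeric vector (or array) of HU values.
#' @param spec A [lattice_spec()].
#' @return Integer gray levels with the same shape as `values`.
#' @export
quantize <- function(values, spec = lattice_spec()) {
  if (length(values) == 0) stopf("`values` must be non-empty")
  lo <- spec$hu_clip[1]
  hi <- spec$hu_clip[2]
  n <- spec$n_gray_levels
  v <- pmin(pmax(values, lo), hi)
  lev <- pmin(n, as.integer(floor((v - lo) / (hi - lo) * n)) + 1L)
  if (!is.null(dim(values))) dim(lev) <- dim(values)
  lev
}

#' First-order gray-level histogram features
#'
#' Returns mean, variance, skewness and excess kurtosis of the raw HU values
#' (population moments), plus Shannon entropy (natural log) and uniformity
#' (energy; sum of squared level probabilities) of the quantized gray-level
#' distribution. Zero-variance windows return skewness 0 and kurtosis 0 by
#' convention.
#'
#' @param window_values Numeric vector of in-mask HU values (>= 1 value).
#' @param spec A [lattice_spec()] supplying the quantization rule.
#' @return Named numeric vector of 6 features.
#' @export
histogram_features <- function(window_values, spec = lattice_spec()) {
  if (length(window_values) == 0) stopf("`window_values` must be non-empty")
  x <- as.numeric(window_values)
  n <- length(x)
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v > 0) {
    skew <- mean((x - m)^3) / v^1.5
    kurt <- mean((x - m)^4) / v^2 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  p <- tabulate(quantize(x, spec), nbins = spec$n_gray_levels) / n
  p <- p[p > 0]
  c(hist_mean = m, hist_variance = v, hist_skewness = skew,
    hist_kurtosis = kurt, hist_entropy = -sum(p * log(p)),
    hist_uniformity = sum(p^2))
}

#' Gray-level co-occurrence (GLCM) features
#'
#' Accumulates one symmetric, normalized co-occurrence matrix over all 13
#' unique 3D directions at `spec$glcm_distance`, counting only voxel pairs
#' where both ends are in-window and in-mask (out-of-mask voxels are NA in
#' `window_levels`). Zero-variance matrices return correlation 0 by
#' convention.
#'
#' @param window_levels 3D integer array of gray levels (1..n), NA outside
#'   the mask.
#' @param spec A [lattice_spec()].
#' @return Named numeric vector of 9 features, or `NULL` if the window
#'   admits no valid voxel pair.
#' @export
glcm_features <- function(window_levels, spec = lattice_spec()) {
  stopifnot(length(dim(window_levels)) == 3L)
  counts <- cpp_glcm_counts(window_levels, spec$n_gray_levels,
                            spec$glcm_distance)
  total <- sum(counts)
  if (total == 0) return(NULL)
  p <- counts / total
  ng <- spec$n_gray_levels
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  pi_m <- rowSums(p)  # marginals (symmetric matrix: row = col marginal)
  mu_i <- sum(seq_len(ng) * pi_m)
  sd_i <- sqrt(sum((seq_len(ng) - mu_i)^2 * pi_m))
  corr <- if (sd_i > 0)
    sum(p * (i - mu_i) * (j - mu_i)) / (sd_i * sd_i) else 0
  pnz <- p[p > 0]
  c(glcm_contrast = sum(p * (i - j)^2),
    glcm_correlation = corr,
    glcm_energy = sum(p^2),
    glcm_homogeneity = sum(p / (1 + (i - j)^2)),
    glcm_entropy = -sum(pnz * log(pnz)),
    glcm_dissimilarity = sum(p * abs(i - j)),
    glcm_cluster_shade = sum(p * (i + j - 2 * mu_i)^3),
    glcm_cluster_prominence = sum(p * (i + j - 2 * mu_i)^4),
    glcm_max_probability = max(p))
}

#' Gray-level run-length (GLRLM) features
#'
#' Accumulates one run-length matrix over the same 13 unique 3D directions
#' (runs broken by mask and window boundaries) and returns the canonical
#' Galloway/Chu statistics: SRE, LRE, GLN, RLN, RP, LGRE, HGRE, SRLGE,
#' SRHGE, LRLGE, LRHGE. Run percentage uses the in-window voxel count per
#' direction summed over directions as its denominator.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 11 features, or `NULL` if the window
#'   contains no in-mask voxel.
#' @export
glrlm_features <- function(window_levels, spec = lattice_spec()) {
  stopifnot(length(dim(window_levels)) == 3L)
  res <- cpp_glrlm_counts(window_levels, spec$n_gray_levels)
  R <- res$counts
  nr <- sum(R)
  if (nr == 0) return(NULL)
  ng <- nrow(R)
  nl <- ncol(R)
  g2 <- matrix(seq_len(ng)^2, ng, nl)
  l2 <- matrix(rep(seq_len(nl)^2, each = ng), ng, nl)
  c(glrlm_sre = sum(R / l2) / nr,
    glrlm_lre = sum(R * l2) / nr,
    glrlm_gln = sum(rowSums(R)^2) / nr,
    glrlm_rln = sum(colSums(R)^2) / nr,
    glrlm_rp = nr / res$n_voxels,
    glrlm_lgre = sum(R / g2) / nr,
    glrlm_hgre = sum(R * g2) / nr,
    glrlm_srlge = sum(R / (g2 * l2)) / nr,
    glrlm_srhge = sum(R * g2 / l2) / nr,
    glrlm_lrlge = sum(R * l2 / g2) / nr,
    glrlm_lrhge = sum(R * g2 * l2) / nr)
}

#' Extract per-window feature vectors over a lattice
#'
#' Tiles the bounding box of the lung mask with non-overlapping windows of
#' edge `window_mm` (converted to voxels per axis by rounding, minimum 1
#' voxel). A window is evaluated when its in-mask voxel fraction is at least
#' `spec$min_occupancy`; each evaluated window yields all 26 features
#' computed on in-mask voxels only. Windows admitting no valid co-occurrence
#' pair are skipped.
#'
#' @param volume A [ct_volume()].
#' @param mask A [lung_mask()] of the same shape.
#' @param spec A [lattice_spec()].
#' @param window_mm Single window size in mm (defaults to the first entry of
#'   `spec$window_mm`).
#' @return data.frame with window center coordinates (mm), occupancy and the
#'   26 feature columns; attribute `window_mm` records the window size.
#' @export
lattice_extract <- function(volume, mask, spec = lattice_spec(),
                            window_mm = spec$window_mm[[1]]) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "lung_mask"))
  if (!identical(dim(volume$voxels), dim(mask$mask)))
    stopf("volume and mask shapes differ")
  if (mask$voxel_count == 0)
    stopf("mask is empty for scan %s", volume$scan_id)
  d <- dim(volume$voxels)
  win <- pmax(1L, as.integer(round(window_mm / volume$spacing)))
  levels_all <- quantize(volume$voxels, spec)
  levels_all[!mask$mask] <- NA_integer_

  idx <- which(mask$mask, arr.ind = TRUE)
  bb_lo <- apply(idx, 2, min)
  bb_hi <- apply(idx, 2, max)
  starts <- lapply(1:3, function(a) seq(bb_lo[a], bb_hi[a], by = win[a]))

  rows <- list()
  for (sx in starts[[1]]) for (sy in starts[[2]]) for (sz in starts[[3]]) {
    ex <- min(sx + win[1] - 1L, d[1])
    ey <- min(sy + win[2] - 1L, d[2])
    ez <- min(sz + win[3] - 1L, d[3])
    wl <- levels_all[sx:ex, sy:ey, sz:ez, drop = FALSE]
    n_in <- sum(!is.na(wl))
    occupancy <- n_in / prod(win)
    if (occupancy < spec$min_occupancy) next
    wv <- volume$voxels[sx:ex, sy:ey, sz:ez, drop = FALSE][!is.na(wl)]
    g <- glcm_features(wl, spec)
    r <- glrlm_features(wl, spec)
    if (is.null(g) || is.null(r)) next  # no valid neighbor pair: skip window
    rows[[length(rows) + 1L]] <- c(
      center_x = (sx + ex) / 2 * volume$spacing[1],
      center_y = (sy + ey) / 2 * volume$spacing[2],
      center_z = (sz + ez) / 2 * volume$spacing[3],
      occupancy = occupancy,
      histogram_features(wv, spec), g, r)
  }
  if (length(rows) == 0)
    stopf("no valid lattice windows for scan %s at W = %g mm",
          volume$scan_id, window_mm,
          class = "lungpheno_no_windows_error")
  out <- as.data.frame(do.call(rbind, rows))
  attr(out, "window_mm") <- window_mm
  attr(out, "scan_id") <- volume$scan_id
  out
}

#' Average lattice windows to a per-scan feature vector
#'
#' Unweighted mean of each of the 26 features over all evaluated windows.
#'
#' @param window_vectors data.frame from [lattice_extract()].
#' @param scan_id,kernel_label Metadata recorded on the result.
#' @return A `feature_vector`: named numeric vector of 26 features with
#'   attributes `window_mm`, `scan_id`, `kernel_label`, `n_windows_used`.
#' @export
aggregate_scan <- function(window_vectors, scan_id = NULL,
                           kernel_label = NA_character_) {
  if (is.null(window_vectors) || nrow(window_vectors) == 0)
    stopf("no window vectors to aggregate")
  fv <- colMeans(window_vectors[, feature_names(), drop = FALSE])
  structure(fv, class = "feature_vector",
            window_mm = attr(window_vectors, "window_mm"),
            scan_id = scan_id %||% attr(window_vectors, "scan_id"),
            kernel_label = kernel_label,
            n_windows_used = nrow(window_vectors))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the per-scan feature vector for each window size
#'
#' Convenience wrapper running [lattice_extract()] and [aggregate_scan()]
#' for every window size in `spec$window_mm`.
#'
#' @inheritParams lattice_extract
#' @param kernel_label Batch label recorded on each feature vector.
#' @return Named list of `feature_vector`s, one per window size
#'   (names `"W4"`, `"W8"`, ...).
#' @export
extract_scan <- function(volume, mask, spec = lattice_spec(),
                         kernel_label = NA_character_) {
  out <- lapply(spec$window_mm, function(w)
    aggregate_scan(lattice_extract(volume, mask, spec, window_mm = w),
                   kernel_label = kernel_label))
  names(out) <- paste0("W", spec$window_mm)
  out
}
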