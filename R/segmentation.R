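#' Lung segmentation parameters
#'
#' @param kmeans_k Number of intensity clusters for the K-means step
#'   (>= 2); the lowest-center cluster is the air/lung candidate set.
#' @param vessel_hu_threshold HU above which voxels are excluded from the
#'   final mask (vessel exclusion).
#' @param min_component_fraction Connected components smaller than this
#'   fraction of the candidate set are dropped.
#' @param closing_radius Radius (mm) of the spherical structuring element
#'   used for morphological closing.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(kmeans_k = 2L, vessel_hu_threshold = -300,
                                min_component_fraction = 0.01,
                                closing_radius = 2) {
  if (!is_count(kmeans_k) || kmeans_k < 2) stopf("`kmeans_k` must be >= 2")
  if (!is.finite(vessel_hu_threshold)) stopf("vessel threshold must be finite")
  structure(list(kmeans_k = as.integer(kmeans_k),
                 vessel_hu_threshold = vessel_hu_threshold,
                 min_component_fraction = min_component_fraction,
                 closing_radius = closing_radius),
            class = "segmentation_params")
}

# Deterministic 1D K-means on HU values: centers initialized at evenly
# spaced percentiles (10th and 90th for k = 2), Lloyd iterations to a
# center-shift tolerance of 1e-3 HU. No random initialization, so the
# segmentation stage is a pure function of its input.
kmeans_1d <- function(values, k, tol = 1e-3, max_iter = 100L) {
  centers <- as.numeric(quantile(values, probs = seq(0.1, 0.9,
                                                     length.out = k)))
  for (it in seq_len(max_iter)) {
    # assignment to nearest (sorted) center via midpoint cut-points
    ord <- order(centers)
    centers <- centers[ord]
    cuts <- (centers[-1] + centers[-k]) / 2
    assign <- findInterval(values, cuts) + 1L
    new_centers <- centers
    for (j in seq_len(k)) {
      sel <- assign == j
      if (any(sel)) new_centers[j] <- mean(values[sel])
    }
    if (max(abs(new_centers - centers)) < tol) {
      centers <- new_centers
      break
    }
    centers <- new_centers
  }
  cuts <- (centers[-1] + centers[-k]) / 2
  list(centers = centers, assignment = findInterval(values, cuts) + 1L)
}

border_component_ids <- function(labels) {
  d <- dim(labels)
  faces <- c(labels[1, , ], labels[d[1], , ],
             labels[, 1, ], labels[, d[2], ],
             labels[, , 1], labels[, , d[3]])
  setdiff(unique(faces), 0L)
}

#' Segment the lung field from a CT volume
#'
#' Intensity-based 3D segmentation: (1) deterministic 1D K-means on HU
#' separates air/lung from soft-tissue attenuation; voxels in the
#' lowest-center cluster form the candidate set; (2) 26-connected components
#' touching the volume border are removed (exterior air); (3) components
#' smaller than `min_component_fraction` of the candidate set are dropped;
#' (4) morphological closing with a spherical element of `closing_radius` mm;
#' (5) voxels brighter than `vessel_hu_threshold` are excluded (vessels).
#' Mask voxels on the outer face of the grid are always cleared.
#'
#' @param volume A [ct_volume()].
#' @param params A [segmentation_params()].
#' @return A [lung_mask()].
#' @export
segment_lung <- function(volume, params = segmentation_params()) {
  stopifnot(inherits(volume, "ct_volume"))
  v <- volume$voxels
  km <- kmeans_1d(as.numeric(v), params$kmeans_k)
  candidate <- array(km$assignment == which.min(km$centers), dim(v))
  n_candidate <- sum(candidate)
  if (n_candidate == 0)
    stopf("no lung field found in scan %s", volume$scan_id,
          class = "lungpheno_no_lung_error")

  labels <- cpp_label_components(candidate)
  drop <- border_component_ids(labels)
  keep_tab <- tabulate(labels[!(labels %in% c(0L, drop))])
  keep_ids <- which(keep_tab >= params$min_component_fraction * n_candidate)
  mask <- array(labels %in% keep_ids, dim(v))

  if (any(mask) && params$closing_radius > 0) {
    off <- ball_offsets(params$closing_radius, volume$spacing)
    mask <- cpp_binary_morph(cpp_binary_morph(mask, off, TRUE), off, FALSE)
  }

  mask[v > params$vessel_hu_threshold] <- FALSE

  # never allow mask voxels on the outer face
  d <- dim(mask)
  mask[c(1, d[1]), , ] <- FALSE
  mask[, c(1, d[2]), ] <- FALSE
  mask[, , c(1, d[3])] <- FALSE

  if (!any(mask))
    stopf("no lung field found in scan %s", volume$scan_id,
          class = "lungpheno_no_lung_error")
  lung_mask(mask)
}
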