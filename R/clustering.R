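#' Hierarchical clustering of radiomic feature vectors
#'
#' Features are z-scored per column (the dataset's own mean/SD, stored for
#' later centroid work), distances are Euclidean and linkage is Ward
#' (`ward.D2`). Zero-variance features are excluded from the distance with a
#' warning. Output is deterministic for fixed input.
#'
#' @param features n x p numeric matrix (>= 3 rows), rownames used as scan
#'   ids.
#' @return An `lp_dendrogram`: list with the `hclust` tree, `labels`,
#'   `standardization` (center/scale) and the standardized matrix.
#' @export
hierarchical_cluster <- function(features) {
  x <- as.matrix(features)
  if (nrow(x) < 3) stopf("need >= 3 scans to cluster")
  if (any(!is.finite(x))) stopf("non-finite feature values")
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  zero <- scl == 0
  if (any(zero)) {
    warning(sprintf("excluding %d zero-variance feature(s) from clustering",
                    sum(zero)))
    scl[zero] <- 1
  }
  z <- sweep(sweep(x, 2, ctr, `-`), 2, scl, `/`)
  z_used <- z[, !zero, drop = FALSE]
  hc <- hclust(dist(z_used), method = "ward.D2")
  structure(list(hclust = hc, labels = rownames(x),
                 standardization = list(center = ctr, scale = scl,
                                        excluded = which(zero)),
                 data_std = z), class = "lp_dendrogram")
}

#' @export
print.lp_dendrogram <- function(x, ...) {
  cat(sprintf("<lp_dendrogram> %d leaves, Ward (ward.D2) linkage\n",
              length(x$labels)))
  invisible(x)
}

# Displayed leaf order of an hclust tree under per-node flip flags.
# Node m concatenates the orders of its two children (merge convention:
# negative entries are leaves); flip[m] swaps the concatenation.
leaf_order_with_flips <- function(hc, flips) {
  merge <- hc$merge
  n <- nrow(merge) + 1L
  orders <- vector("list", nrow(merge))
  child_order <- function(v) if (v < 0) -v else orders[[v]]
  for (m in seq_len(nrow(merge))) {
    left <- child_order(merge[m, 1])
    right <- child_order(merge[m, 2])
    orders[[m]] <- if (flips[m]) c(right, left) else c(left, right)
  }
  orders[[nrow(merge)]]
}

entanglement_from_orders <- function(ord_a, ord_b, L) {
  n <- length(ord_a)
  x <- seq_len(n)
  y <- match(ord_a, ord_b)
  denom <- sum(abs(seq_len(n) - rev(seq_len(n)))^L)
  if (denom == 0) return(0)
  sum(abs(x - y)^L) / denom
}

#' Entanglement between two dendrograms
#'
#' Measures misalignment of the displayed leaf orderings of two dendrograms
#' over the same scans: with x_i and y_i the rank of leaf i in each tree's
#' displayed order, the coefficient is sum(|x_i - y_i|^L) normalized by its
#' maximum over worst-case orderings (attained by the reversed order), so it
#' lies in \[0, 1\]: 0 means perfectly aligned, 1 fully entangled. The
#' `"step2side"` untangling heuristic greedily flips subtrees of either tree
#' to minimize the coefficient before measuring; `"none"` measures the trees
#' as built.
#'
#' @param dend_a,dend_b `lp_dendrogram`s over identical leaf-label sets.
#' @param L Norm exponent (default 1.5).
#' @param untangle `"step2side"` or `"none"`.
#' @return An `entanglement_result`: list with `coefficient`, `L`,
#'   `untangle`.
#' @export
entanglement <- function(dend_a, dend_b, L = 1.5,
                         untangle = c("step2side", "none")) {
  untangle <- match.arg(untangle)
  stopifnot(inherits(dend_a, "lp_dendrogram"),
            inherits(dend_b, "lp_dendrogram"))
  only_a <- setdiff(dend_a$labels, dend_b$labels)
  only_b <- setdiff(dend_b$labels, dend_a$labels)
  if (length(only_a) > 0 || length(only_b) > 0)
    stopf("leaf labels differ (only in a: %s; only in b: %s)",
          paste(only_a, collapse = ","), paste(only_b, collapse = ","))

  ha <- dend_a$hclust
  hb <- dend_b$hclust
  fa <- rep(FALSE, nrow(ha$merge))
  fb <- rep(FALSE, nrow(hb$merge))
  coef_for <- function(fa, fb) {
    oa <- ha$labels[leaf_order_with_flips(ha, fa)]
    ob <- hb$labels[leaf_order_with_flips(hb, fb)]
    entanglement_from_orders(oa, ob, L)
  }
  best <- coef_for(fa, fb)
  if (untangle == "step2side") {
    repeat {
      improved <- FALSE
      for (side in 1:2) {
        flips <- if (side == 1) fa else fb
        for (m in seq_along(flips)) {
          flips[m] <- !flips[m]
          cand <- if (side == 1) coef_for(flips, fb) else coef_for(fa, flips)
          if (cand < best - 1e-12) {
            best <- cand
            if (side == 1) fa <- flips else fb <- flips
            improved <- TRUE
          } else {
            flips[m] <- !flips[m]
          }
        }
      }
      if (!improved) break
    }
  }
  structure(list(coefficient = best, L = L, untangle = untangle),
            class = "entanglement_result")
}

#' @export
print.entanglement_result <- function(x, ...) {
  cat(sprintf("Entanglement coefficient %.4f (L = %g, untangle = %s)\n",
              x$coefficient, x$L, x$untangle))
  invisible(x)
}

#' Consensus clustering for the number of phenotypes
#'
#' Monti-style consensus clustering with hierarchical (Ward) inner
#' clustering: over `n_resamples` random subsamples of `subsample_frac` of
#' the scans, the co-clustering proportion of every scan pair is accumulated
#' per candidate K; K is selected by the delta-area criterion on the
#' consensus CDFs (K = 2 uses its raw area; larger K the relative area
#' increase), the maximizer being chosen.
#'
#' @param features n x p matrix.
#' @param k_range Candidate cluster counts (within \[2, n-1\]).
#' @param n_resamples Number of resamples (>= 50).
#' @param subsample_frac Fraction of scans per resample.
#' @param seed Integer seed.
#' @return A `consensus_result`: per-K consensus matrices, per-K CDF areas
#'   and delta-areas, `selected_k`, and the resampling settings.
#' @export
consensus_select_k <- function(features, k_range = 2:6, n_resamples = 250,
                               subsample_frac = 0.8, seed = 1L) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (any(k_range < 2) || any(k_range > n - 1))
    stopf("`k_range` must lie within [2, n-1]")
  if (n_resamples < 50) stopf("`n_resamples` must be >= 50")
  z <- scale(x)
  z[, attr(z, "scaled:scale") == 0] <- 0
  m_sub <- max(2L, round(subsample_frac * n))

  co_sampled <- matrix(0, n, n)
  co_clustered <- lapply(k_range, function(k) matrix(0, n, n))
  names(co_clustered) <- as.character(k_range)
  with_rng_seed(seed, {
    for (r in seq_len(n_resamples)) {
      idx <- sort(sample.int(n, m_sub))
      co_sampled[idx, idx] <- co_sampled[idx, idx] + 1
      hc <- hclust(dist(z[idx, , drop = FALSE]), method = "ward.D2")
      for (k in k_range) {
        ct <- cutree(hc, k)
        ind <- outer(ct, ct, `==`)
        key <- as.character(k)
        co_clustered[[key]][idx, idx] <- co_clustered[[key]][idx, idx] + ind
      }
    }
  })

  undefined_pairs <- sum(co_sampled[upper.tri(co_sampled)] == 0)
  if (undefined_pairs > 0)
    warning(sprintf(paste0("%d scan pair(s) never co-sampled; their ",
                           "consensus is treated as 0 (raise ",
                           "`subsample_frac` or `n_resamples`)"),
                    undefined_pairs))

  consensus <- lapply(co_clustered, function(M) {
    C <- ifelse(co_sampled > 0, M / pmax(co_sampled, 1), 0)
    diag(C) <- 1
    C
  })

  areas <- vapply(consensus, function(C) {
    v <- sort(C[upper.tri(C)])
    m <- length(v)
    # area under the empirical CDF of consensus values
    sum(diff(v) * (seq_len(m - 1) / m))
  }, numeric(1))
  delta <- numeric(length(k_range))
  delta[1] <- areas[1]
  if (length(k_range) > 1)
    delta[-1] <- diff(areas) / areas[-length(areas)]
  selected <- k_range[which.max(delta)]

  structure(list(consensus = consensus, k_range = k_range,
                 cdf_area = setNames(areas, k_range),
                 delta_area = setNames(delta, k_range),
                 selected_k = selected,
                 settings = list(n_resamples = n_resamples,
                                 subsample_frac = subsample_frac,
                                 seed = seed)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> K scanned %s; selected K = %d\n",
              paste(range(x$k_range), collapse = "-"), x$selected_k))
  print(round(rbind(cdf_area = x$cdf_area, delta_area = x$delta_area), 4))
  invisible(x)
}

#' Cut a dendrogram into K phenotype clusters
#'
#' Cluster labels are ordered by descending cluster size; ties are broken by
#' ascending centroid norm in the standardized feature space.
#'
#' @param dendrogram An `lp_dendrogram`.
#' @param k Number of clusters (2 <= k <= n).
#' @return Integer assignments in 1..k, named by scan id.
#' @export
cut_clusters <- function(dendrogram, k) {
  stopifnot(inherits(dendrogram, "lp_dendrogram"))
  n <- length(dendrogram$labels)
  if (k > n) stopf("k = %d exceeds the number of scans (%d)", k, n)
  raw <- cutree(dendrogram$hclust, k)
  sizes <- tabulate(raw, k)
  norms <- vapply(seq_len(k), function(g)
    sqrt(sum(colMeans(dendrogram$data_std[raw == g, , drop = FALSE])^2)),
    numeric(1))
  new_order <- order(-sizes, norms)
  relabel <- integer(k)
  relabel[new_order] <- seq_len(k)
  setNames(relabel[raw], dendrogram$labels)
}

#' Fit cluster centroids for phenotype mapping
#'
#' Stores per-cluster means in the standardized space of the training
#' matrix, together with the standardization parameters, so an independent
#' cohort can be standardized identically and assigned by nearest centroid.
#'
#' @param features n x p training matrix.
#' @param assignments Integer cluster labels per row (all clusters
#'   nonempty).
#' @return A `cluster_model`: `centroids` (K x p, standardized space),
#'   `center`, `scale`, `sizes`.
#' @export
fit_centroids <- function(features, assignments) {
  x <- as.matrix(features)
  stopifnot(length(assignments) == nrow(x))
  k <- max(assignments)
  if (any(tabulate(assignments, k) == 0))
    stopf("empty cluster in `assignments`")
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  z <- sweep(sweep(x, 2, ctr, `-`), 2, scl, `/`)
  centroids <- do.call(rbind, lapply(seq_len(k), function(g)
    colMeans(z[assignments == g, , drop = FALSE])))
  rownames(centroids) <- paste0("cluster", seq_len(k))
  structure(list(centroids = centroids, center = ctr, scale = scl,
                 sizes = tabulate(assignments, k)),
            class = "cluster_model")
}

#' Map scans to the nearest phenotype centroid
#'
#' Standardizes `new_features` with the training model's parameters and
#' assigns each scan to the Euclidean-nearest centroid (ties to the lower
#' cluster label).
#'
#' @param model A `cluster_model` from [fit_centroids()].
#' @param new_features m x p matrix with the training feature columns.
#' @return Integer assignments in 1..K, named by scan id.
#' @export
map_clusters <- function(model, new_features) {
  stopifnot(inherits(model, "cluster_model"))
  x <- as.matrix(new_features)
  stopifnot(ncol(x) == length(model$center))
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    sid <- rownames(x)[bad[1, 1]] %||% paste0("row ", bad[1, 1])
    fn <- colnames(x)[bad[1, 2]] %||% paste0("feature ", bad[1, 2])
    stopf("non-finite feature value (scan %s, %s)", sid, fn)
  }
  z <- sweep(sweep(x, 2, model$center, `-`), 2, model$scale, `/`)
  d2 <- outer(rowSums(z^2), rowSums(model$centroids^2), `+`) -
    2 * z %*% t(model$centroids)
  assign <- apply(d2, 1, which.min)  # which.min takes the lowest index tie
  setNames(as.integer(assign),
           rownames(x) %||% as.character(seq_len(nrow(x))))
}

#' Permutation test for phenotype cluster separation
#'
#' An interpretation of "statistically significant clusters": the observed
#' between/within sum-of-squares ratio of the clustering (on z-scored
#' features) is compared with the same statistic recomputed on Gaussian null
#' data (independent features with the observed per-feature mean/SD),
#' re-clustered and cut at the same K each time.
#'
#' @param features n x p matrix.
#' @param assignments Cluster labels from [cut_clusters()].
#' @param n_perm Number of null simulations.
#' @param seed Integer seed.
#' @return List with `statistic`, `p_value`, `n_perm`.
#' @export
cluster_separation_test <- function(features, assignments, n_perm = 999,
                                    seed = 1L) {
  x <- scale(as.matrix(features))
  x[, attr(x, "scaled:scale") == 0] <- 0
  k <- max(assignments)
  bw_ratio <- function(z, cl) {
    tot <- sum(sweep(z, 2, colMeans(z), `-`)^2)
    within <- sum(vapply(seq_len(max(cl)), function(g) {
      zg <- z[cl == g, , drop = FALSE]
      sum(sweep(zg, 2, colMeans(zg), `-`)^2)
    }, numeric(1)))
    (tot - within) / within
  }
  obs <- bw_ratio(x, assignments)
  null <- with_rng_seed(seed, vapply(seq_len(n_perm), function(i) {
    z0 <- matrix(rnorm(length(x)), nrow(x), ncol(x))
    hc <- hclust(dist(z0), method = "ward.D2")
    bw_ratio(z0, cutree(hc, k))
  }, numeric(1)))
  list(statistic = obs, p_value = (1 + sum(null >= obs)) / (n_perm + 1),
       n_perm = n_perm)
}
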