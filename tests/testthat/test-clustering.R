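test_that("Ward tree matches the exhaustive Lance-Williams oracle", {
  set.seed(10)
  for (rep in 1:10) {
    n <- sample(4:7, 1)
    x <- matrix(rnorm(n * 5), n, 5)
    colnames(x) <- paste0("f", 1:5)
    d <- hierarchical_cluster(x)
    # the oracle works on the same standardized matrix
    expect_equal(sort(d$hclust$height),
                 sort(oracle_ward_heights(d$data_std)), tolerance = 1e-10)
  }

  # coincident points merge first at height zero
  y <- rbind(c(0, 0), c(0, 0), c(5, 5))
  rownames(y) <- c("a", "b", "c")
  colnames(y) <- c("f1", "f2")
  dy <- hierarchical_cluster(y)
  expect_equal(dy$hclust$height[1], 0)
  expect_setequal(abs(dy$hclust$merge[1, ]), c(1, 2))
})

test_that("cluster cuts are size-ordered and recover planted blobs", {
  ft <- generate_feature_table(60, cluster_shift = c(rep(4, 8), rep(0, 18)),
                               seed = 14, cluster_fraction = 0.4)
  d <- hierarchical_cluster(ft$features)
  asg <- cut_clusters(d, 2)
  expect_equal(rand_index(asg, ft$cluster), 1.0)
  # label 1 is the larger cluster by convention
  expect_gte(sum(asg == 1), sum(asg == 2))

  # K = n puts every scan in its own cluster
  small <- ft$features[1:5, ]
  d5 <- hierarchical_cluster(small)
  expect_equal(sort(unname(cut_clusters(d5, 5))), 1:5)
  expect_error(cut_clusters(d5, 6), "exceeds")

  # permuting the input rows leaves the partition unchanged
  perm <- sample(nrow(ft$features))
  dp <- hierarchical_cluster(ft$features[perm, ])
  asg_p <- cut_clusters(dp, 2)
  expect_equal(rand_index(asg_p[ft$scan_id], asg), 1.0)
})

test_that("consensus clustering is reproducible and sees duplicate pairs", {
  ft <- generate_feature_table(40, cluster_shift = c(rep(4, 8), rep(0, 18)),
                               seed = 3)
  c1 <- consensus_select_k(ft$features, k_range = 2:4, n_resamples = 60,
                           seed = 5)
  c2 <- consensus_select_k(ft$features, k_range = 2:4, n_resamples = 60,
                           seed = 5)
  expect_identical(c1$consensus, c2$consensus)
  expect_identical(c1$selected_k, c2$selected_k)
  expect_true(all(vapply(c1$consensus, function(C)
    all(C >= 0 & C <= 1) && isTRUE(all.equal(C, t(C))) &&
      all(diag(C) == 1), logical(1))))

  # exact duplicate rows always co-cluster at any K
  base <- matrix(rnorm(20 * 26), 20, 26,
                 dimnames = list(NULL, feature_names()))
  dup <- rbind(base, base)
  rownames(dup) <- sprintf("S%03d", 1:40)
  cd <- consensus_select_k(dup, k_range = 2:3, n_resamples = 60, seed = 7)
  for (C in cd$consensus)
    for (i in 1:20) {
      pair <- C[i, i + 20]
      if (!is.na(pair) && pair > 0)  # co-sampled at least once
        expect_equal(pair, 1)
    }
})

test_that("entanglement has its defined extremes, bounds and symmetry", {
  lad <- ladder_dendrogram(letters[1:6])
  self <- entanglement(lad, lad, untangle = "none")
  expect_equal(self$coefficient, 0)

  rev_lad <- ladder_dendrogram(rev(letters[1:6]))
  flipped <- entanglement(lad, rev_lad, untangle = "none")
  expect_equal(flipped$coefficient, 1)  # reversal attains the maximum

  set.seed(20)
  for (rep in 1:25) {
    n <- sample(5:12, 1)
    ids <- sprintf("S%02d", 1:n)
    xa <- matrix(rnorm(n * 4), n, dimnames = list(ids, paste0("f", 1:4)))
    xb <- matrix(rnorm(n * 4), n, dimnames = list(ids, paste0("f", 1:4)))
    da <- hierarchical_cluster(xa)
    db <- hierarchical_cluster(xb)
    e_ab <- entanglement(da, db, untangle = "none")$coefficient
    e_ba <- entanglement(db, da, untangle = "none")$coefficient
    expect_gte(e_ab, 0)
    expect_lte(e_ab, 1)
    expect_equal(e_ab, e_ba)
    # untangling can only improve the alignment
    e_un <- entanglement(da, db, untangle = "step2side")$coefficient
    expect_lte(e_un, e_ab)
  }

  other <- ladder_dendrogram(letters[2:7])
  expect_error(entanglement(lad, other), "labels differ")
})

test_that("centroid models store standardization and map consistently", {
  x <- rbind(c(0, 0), c(2, 2), c(10, 10), c(12, 12))
  rownames(x) <- paste0("s", 1:4)
  colnames(x) <- c("f1", "f2")
  asg <- c(1L, 1L, 2L, 2L)
  model <- fit_centroids(x, asg)
  # de-standardized centroids equal raw-space cluster means
  raw <- sweep(sweep(model$centroids, 2, model$scale, `*`), 2,
               model$center, `+`)
  expect_equal(unname(raw), rbind(c(1, 1), c(11, 11)), tolerance = 1e-10)

  one <- fit_centroids(x, c(1L, 2L, 2L, 2L))
  raw1 <- sweep(sweep(one$centroids, 2, one$scale, `*`), 2, one$center, `+`)
  expect_equal(unname(raw1[1, ]), c(0, 0), tolerance = 1e-10)

  expect_error(fit_centroids(x, c(1L, 1L, 1L, 3L)), "empty cluster")

  # a scan equal to centroid 2 maps to cluster 2; equidistant ties go low
  z2 <- sweep(sweep(model$centroids, 2, model$scale, `*`), 2,
              model$center, `+`)
  expect_equal(unname(map_clusters(model, z2[2, , drop = FALSE])), 2L)
  mid <- (z2[1, ] + z2[2, ]) / 2
  expect_equal(unname(map_clusters(model, rbind(mid))), 1L)

  bad <- rbind(c(1, NA))
  colnames(bad) <- c("f1", "f2")
  rownames(bad) <- "s9"
  expect_error(map_clusters(model, bad), "non-finite")

  # training-set round trip on separated blobs
  ft <- generate_feature_table(100, cluster_shift = c(rep(4, 8), rep(0, 18)),
                               seed = 8)
  d <- hierarchical_cluster(ft$features)
  asg2 <- cut_clusters(d, 2)
  cm <- fit_centroids(ft$features, asg2)
  mapped <- map_clusters(cm, ft$features)
  expect_gte(mean(mapped == asg2), 0.95)
})

test_that("planted two-cluster structure is deemed significant", {
  ft <- generate_feature_table(40, cluster_shift = c(rep(4, 8), rep(0, 18)),
                               seed = 21)
  d <- hierarchical_cluster(ft$features)
  asg <- cut_clusters(d, 2)
  st <- cluster_separation_test(ft$features, asg, n_perm = 99, seed = 2)
  expect_lt(st$p_value, 0.05)
})
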