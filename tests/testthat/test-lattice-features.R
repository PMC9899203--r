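spec32 <- lattice_spec()

test_that("quantization is fixed-range, exact and endpoint-correct", {
  expect_equal(quantize(c(-1024, 200), spec32), c(1L, 32L))
  expect_true(all(quantize(rep(-500, 10), spec32) ==
                  quantize(-500, spec32)))
  # exact uniform grid: 3200 bin-centred values -> 100 per level
  grid <- -1024 + (200 - -1024) * ((0:3199) + 0.5) / 3200
  counts <- tabulate(quantize(grid, spec32), 32)
  expect_true(all(counts == 100))
  expect_error(quantize(numeric(0), spec32), "non-empty")
})

test_that("histogram features match hand computations and bounds", {
  f <- histogram_features(rep(-700, 20), spec32)
  expect_equal(unname(f[c("hist_variance", "hist_entropy",
                          "hist_uniformity", "hist_skewness",
                          "hist_kurtosis")]), c(0, 0, 1, 0, 0))

  g <- histogram_features(c(0, 0, 10, 10), spec32)
  expect_equal(unname(g["hist_mean"]), 5)
  expect_equal(unname(g["hist_variance"]), 25)   # population variance
  expect_equal(unname(g["hist_entropy"]), log(2))
  expect_equal(unname(g["hist_uniformity"]), 0.5)

  set.seed(1)
  h <- histogram_features(rnorm(200, -800, 80), spec32)
  expect_gt(h["hist_uniformity"], 0)
  expect_lte(h["hist_uniformity"], 1)
  expect_gte(h["hist_entropy"], 0)
  expect_lte(h["hist_entropy"], log(32))
})

test_that("GLCM features match single-cell and strip enumerations", {
  const <- array(5L, c(3, 3, 3))
  f <- glcm_features(const, spec32)
  expect_equal(unname(f[c("glcm_contrast", "glcm_energy", "glcm_entropy",
                          "glcm_max_probability", "glcm_homogeneity",
                          "glcm_correlation")]), c(0, 1, 0, 1, 1, 0))

  # 1x1x4 strip (1,2,1,2): symmetric mass all on (1,2)/(2,1)
  strip <- array(c(1L, 2L, 1L, 2L), c(1, 1, 4))
  g <- glcm_features(strip, spec32)
  expect_equal(unname(g["glcm_contrast"]), 1)
  expect_equal(unname(g["glcm_dissimilarity"]), 1)
  expect_equal(unname(g["glcm_max_probability"]), 0.5)
  expect_equal(unname(g["glcm_energy"]), 0.5)
})

test_that("GLRLM features match run enumerations", {
  # 1x1x5 strip (1,1,2,2,2). Along the strip axis the runs are (1, len 2)
  # and (2, len 3); each of the other 12 accumulated directions sees every
  # voxel as its own length-1 ray, contributing R(1,1) += 2 and R(2,1) += 3.
  # Hand totals: R(1,1) = 24, R(2,1) = 36, R(1,2) = 1, R(2,3) = 1, n_r = 62.
  strip <- array(c(1L, 1L, 2L, 2L, 2L), c(1, 1, 5))
  f <- glrlm_features(strip, spec32)
  expect_equal(unname(f["glrlm_rp"]), 62 / (13 * 5))
  expect_equal(unname(f["glrlm_gln"]), (25^2 + 37^2) / 62)
  expect_equal(unname(f["glrlm_rln"]), (60^2 + 1 + 1) / 62)
  expect_equal(unname(f["glrlm_sre"]), (60 + 1 / 4 + 1 / 9) / 62)
  expect_equal(unname(f["glrlm_lre"]), (60 + 4 + 9) / 62)

  # constant 1x1xn strip: one axial run of length n plus 12 x n unit runs
  n <- 7
  g <- glrlm_features(array(3L, c(1, 1, n)), spec32)
  expect_equal(unname(g["glrlm_rp"]), (12 * n + 1) / (13 * n))
  expect_equal(unname(g["glrlm_sre"]), (12 * n + 1 / n^2) / (12 * n + 1))
  expect_equal(unname(g["glrlm_lre"]), (12 * n + n^2) / (12 * n + 1))

  # the spec's single-direction arithmetic (RP 2/5, SRE (1/4+1/9)/2, ...)
  # is recovered by restricting the oracle to one direction
  one_dir <- oracle_glrlm_1d(strip)
  expect_equal(one_dir$rp, 2 / 5)
  expect_equal(one_dir$sre, (1 / 4 + 1 / 9) / 2)
  expect_equal(one_dir$lre, (4 + 9) / 2)
  expect_equal(one_dir$gln, 1)
  expect_equal(one_dir$rln, 1)
})

test_that("GLCM/GLRLM agree with brute-force enumeration oracles", {
  set.seed(42)
  for (rep in 1:20) {
    lv <- random_level_window(c(6, 6, 6), ngray = 6,
                              na_frac = ifelse(rep %% 2 == 0, 0.2, 0))
    spec6 <- lattice_spec(n_gray_levels = 6)
    g <- glcm_features(lv, spec6)
    og <- oracle_glcm(lv, 6)
    expect_equal(g, og[names(g)], tolerance = 1e-12)
    r <- glrlm_features(lv, spec6)
    orc <- oracle_glrlm(lv, 6)
    expect_equal(r, orc[names(r)], tolerance = 1e-12)
  }
})

test_that("lattice tiling, occupancy rule and aggregation behave exactly", {
  # 40 mm all-lung cube at 1 mm spacing: W = 8 tiles to 5x5x5 windows
  set.seed(5)
  v <- array(-850 + rnorm(40^3, sd = 30), c(40, 40, 40))
  vol <- ct_volume(v, scan_id = "cube")
  # interior mask (the tiling covers the mask bounding box exactly)
  mk <- lung_mask(array(TRUE, c(40, 40, 40)))
  lw <- lattice_extract(vol, mk, spec32, window_mm = 8)
  expect_equal(nrow(lw), 125)
  expect_true(all(is.finite(as.matrix(lw[, feature_names()]))))

  # occupancy rule: a mask filling 40% of each window is excluded
  mk40 <- array(FALSE, c(40, 40, 40))
  mk40[, , seq(1, 40, by = 5)] <- TRUE  # 20% fill
  mk40[, , seq(2, 40, by = 5)] <- TRUE  # 40% fill total
  expect_error(lattice_extract(vol, lung_mask(mk40), spec32, window_mm = 5),
               "no valid lattice windows")

  fv <- aggregate_scan(lw)
  expect_length(unclass(fv), 26)
  expect_identical(attr(fv, "n_windows_used"), 125L)
  expect_equal(as.numeric(fv),
               unname(colMeans(as.matrix(lw[, feature_names()]))))
  # mean of two windows is their midpoint, a single window is returned as is
  two <- lw[1:2, ]
  attr(two, "window_mm") <- 8
  expect_equal(as.numeric(aggregate_scan(two)),
               unname((unlist(lw[1, feature_names()]) +
                       unlist(lw[2, feature_names()])) / 2))
  one <- lw[1, ]
  attr(one, "window_mm") <- 8
  expect_equal(as.numeric(aggregate_scan(one)),
               unname(unlist(lw[1, feature_names()])))
})

test_that("constant HU offsets shift the mean and spare quantized features", {
  # values placed at bin centres so a sub-half-bin offset cannot re-bin
  bin_w <- (200 - -1024) / 32
  set.seed(8)
  centres <- -1024 + (sample.int(32, 4^3, replace = TRUE) - 0.5) * bin_w
  lv0 <- array(quantize(centres, spec32), c(4, 4, 4))
  off <- bin_w / 2 - 1e-6
  lv1 <- array(quantize(centres + off, spec32), c(4, 4, 4))
  expect_identical(lv0, lv1)
  f0 <- histogram_features(centres, spec32)
  f1 <- histogram_features(centres + off, spec32)
  expect_equal(unname(f1["hist_mean"] - f0["hist_mean"]), off)
  expect_equal(f0["hist_entropy"], f1["hist_entropy"])
})
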