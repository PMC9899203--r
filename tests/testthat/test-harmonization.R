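make_cov <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(scan_id = sprintf("S%03d", seq_len(n)),
             age = rnorm(n, 65, 6), bmi = rnorm(n, 27, 5),
             pack_years = pmax(0, rnorm(n, 50, 22)),
             sex = sample(c("female", "male"), n, TRUE),
             smoking_status = sample(c("current", "former"), n, TRUE),
             lungrads_group = sample(c("A", "B"), n, TRUE, prob = c(.85, .15)),
             stringsAsFactors = FALSE)
}

test_that("residual outlier rule flags exactly the displaced scan", {
  n <- 20
  cov <- make_cov(n, seed = 2)
  # a small panel: with 26 features x 3 covariates the 2.5 x IQR rule is
  # expected to flag ~1 clean scan by chance, which would mask the check
  x <- matrix(rnorm(n * 3, sd = 0.3), n, 3,
              dimnames = list(cov$scan_id, paste0("f", 1:3)))
  x[, 1] <- 2 + 0.5 * cov$age + rnorm(n, sd = 0.1)
  base <- flag_outliers(x, cov)
  expect_false(any(base$flagged))  # no contamination yet

  res <- stats::resid(stats::lm(x[, 1] ~ cov$age))
  x2 <- x
  x2[7, 1] <- x2[7, 1] + 10 * stats::IQR(res)
  fl <- flag_outliers(x2, cov)
  expect_true(fl$flagged[7])
  expect_equal(sum(fl$flagged), 1)
  expect_true(all(fl$triggers$scan_id == cov$scan_id[7]))

  # identical feature values: every residual equals the median
  same <- matrix(3, n, 3, dimnames = list(cov$scan_id, paste0("f", 1:3)))
  expect_false(any(flag_outliers(same, cov)$flagged))

  # infinite multiplier covers all residuals
  huge <- harmonization_config(iqr_multiplier = 1e9)
  expect_false(any(flag_outliers(x2, cov, huge)$flagged))
})

test_that("ComBat matches the reference implementation and its contracts", {
  ft <- generate_feature_table(
    80, cluster_shift = c(rep(2, 8), rep(0, 18)),
    batch_effects = list(medium = list(location = 1, scale = 1.4),
                         sharp = list(location = -0.5, scale = 0.8)),
    seed = 11)
  cov <- make_cov(80, seed = 11)
  model <- combat_fit(ft$features, ft$batch, cov)
  mine <- combat_apply(model, ft$features, ft$batch, cov)

  # independent oracle: the original empirical-Bayes ComBat implementation
  mod <- stats::model.matrix(~ sex + lungrads_group + smoking_status +
                               age + bmi + pack_years, cov)
  ref <- t(suppressMessages(
    sva::ComBat(dat = t(ft$features), batch = ft$batch, mod = mod)))
  expect_lt(max(abs(mine - ref)), 1e-4)

  # harmonization shrinks the between-batch mean separation
  gap_before <- abs(colMeans(ft$features[ft$batch == "medium", ]) -
                    colMeans(ft$features[ft$batch == "sharp", ]))
  gap_after <- abs(colMeans(mine[ft$batch == "medium", ]) -
                   colMeans(mine[ft$batch == "sharp", ]))
  expect_lt(mean(gap_after), mean(gap_before))

  expect_error(combat_fit(ft$features[1:3, ], c("a", "a", "b"), cov[1:3, ]),
               "single scan")
  cov_dup <- cov
  cov_dup$bmi2 <- cov_dup$bmi
  cfg_dup <- harmonization_config(protected_variables = c("bmi", "bmi2"))
  expect_error(combat_fit(ft$features, ft$batch, cov_dup, cfg_dup),
               "rank deficient")
  expect_error(combat_apply(model, ft$features,
                            rep("unknown", 80), cov), "unseen batch")
})

test_that("location shifts are removed and protected slopes survive", {
  # feature-specific location shifts: the empirical-Bayes prior is diffuse,
  # so each batch mean is removed essentially exactly
  set.seed(13)
  shifts <- rnorm(26, 5, 2)
  ft <- generate_feature_table(
    400, cluster_shift = 0,
    batch_effects = list(a = list(location = shifts, scale = 1),
                         b = list(location = 0, scale = 1)),
    seed = 13)
  model <- combat_fit(ft$features, ft$batch)
  h <- combat_apply(model, ft$features, ft$batch)
  std_gap <- abs(colMeans(h[ft$batch == "a", ]) -
                 colMeans(h[ft$batch == "b", ])) / apply(h, 2, sd)
  expect_lt(max(std_gap), 0.05)

  # a shift common to all features is shrunk toward the shared prior; the
  # per-feature residual then carries an O(1/3 * sqrt(2/n)) shrinkage floor,
  # so the mean gap is the sharp check here
  ft2 <- generate_feature_table(
    400, cluster_shift = 0,
    batch_effects = list(a = list(location = 5, scale = 1),
                         b = list(location = 0, scale = 1)),
    seed = 14)
  h2 <- combat_apply(combat_fit(ft2$features, ft2$batch),
                     ft2$features, ft2$batch)
  gap2 <- abs(colMeans(h2[ft2$batch == "a", ]) -
              colMeans(h2[ft2$batch == "b", ])) / apply(h2, 2, sd)
  expect_lt(mean(gap2), 0.1)
  expect_gt(mean(abs(colMeans(ft2$features[ft2$batch == "a", ]) -
                     colMeans(ft2$features[ft2$batch == "b", ]))) /
            mean(gap2), 20)  # shift shrunk by well over an order of magnitude

  # protected-covariate effect recovered within 10% (noise-only batch model)
  set.seed(3)
  n <- 500
  cov <- data.frame(scan_id = sprintf("S%03d", 1:n), age = rnorm(n, 65, 6))
  batch <- rep(c("a", "b"), length.out = n)
  x <- matrix(rnorm(n * 26), n, 26, dimnames = list(NULL, feature_names()))
  x[batch == "b", ] <- x[batch == "b", ] * 1.5 + 2
  beta <- 0.8
  x[, 1] <- x[, 1] + beta * (cov$age - 65)
  cfg <- harmonization_config(protected_variables = "age")
  h2 <- combat_apply(combat_fit(x, batch, cov, cfg), x, batch, cov)
  slope <- unname(stats::coef(stats::lm(h2[, 1] ~ cov$age))[2])
  expect_lt(abs(slope - beta) / beta, 0.10)
})

test_that("ComBat is nearly idempotent and near-identity on one batch", {
  set.seed(5)
  n <- 400
  batch <- rep(c("a", "b"), length.out = n)
  gam <- rnorm(26)
  del <- exp(rnorm(26, 0, 0.3))
  x <- matrix(rnorm(n * 26), n, 26, dimnames = list(NULL, feature_names()))
  x[batch == "b", ] <- sweep(sweep(x[batch == "b", ], 2, del, `*`),
                             2, gam, `+`)
  h <- combat_apply(combat_fit(x, batch), x, batch)
  second <- combat_fit(h, batch)
  expect_lt(max(abs(second$gamma_star)), 1e-3)

  # single batch: gamma* is exactly 0 and delta* ~ n/(n-1), so the transform
  # is the identity up to that variance-convention factor
  xa <- x[batch == "a", ]
  m1 <- combat_fit(xa, rep("a", nrow(xa)))
  expect_equal(max(abs(m1$gamma_star)), 0, tolerance = 1e-12)
  expect_equal(unname(m1$delta_star[1, ]),
               rep(nrow(xa) / (nrow(xa) - 1), 26), tolerance = 1e-2)
  h1 <- combat_apply(m1, xa, rep("a", nrow(xa)))
  expect_lt(max(abs(h1 - xa)) / sd(xa), 0.01)
})

test_that("KS assessment has exact extremes and detects batch separation", {
  x <- matrix(rnorm(60 * 26), 60, 26, dimnames = list(NULL, feature_names()))
  dup <- rbind(x, x)
  ks <- ks_batch_assessment(dup, rep(c("a", "b"), each = 60))
  expect_true(all(ks$table$D == 0))
  expect_true(all(ks$table$p == 1))

  y <- x
  y[, 1] <- y[, 1] + 100  # disjoint supports on feature 1
  ks2 <- ks_batch_assessment(rbind(x, y)[, 1, drop = FALSE],
                             rep(c("a", "b"), each = 60))
  expect_equal(ks2$table$D[1], 1)

  expect_error(ks_batch_assessment(x, rep(c("a", "b", "c"), each = 20)),
               "exactly 2")
})
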