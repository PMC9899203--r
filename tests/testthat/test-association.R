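test_that("Kruskal-Wallis matches hand and permutation computations", {
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kw$statistic, 3.857142857, tolerance = 1e-6)
  expect_equal(kw$p_value, 0.04953, tolerance = 1e-3)

  same <- kruskal_wallis(rep(2, 8), rep(c("a", "b"), each = 4))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # exhaustive permutation oracle at n = 8: the permutation null is lumpy
  # at this size, so the chi-square approximation tracks it on average and
  # within a coarse worst-case band at single draws
  set.seed(6)
  diffs <- vapply(1:10, function(rep) {
    v <- sample(100, 7)
    vals <- c(v, v[1])  # one tied pair
    kw2 <- kruskal_wallis(vals, rep(c("a", "b"), each = 4))
    combs <- utils::combn(8, 4)
    stats <- apply(combs, 2, function(ix) {
      g <- rep("b", 8)
      g[ix] <- "a"
      kruskal_wallis(vals, g)$statistic
    })
    abs(kw2$p_value - mean(stats >= kw2$statistic - 1e-12))
  }, numeric(1))
  expect_lt(mean(diffs), 0.1)
  expect_lt(max(diffs), 0.15)
})

test_that("2x2 chi-square matches the textbook continuity formula", {
  yates <- function(tab) {
    n <- sum(tab)
    e <- outer(rowSums(tab), colSums(tab)) / n
    sum(pmax(abs(tab - e) - 0.5, 0)^2 / e)
  }
  set.seed(9)
  for (rep in 1:1000) {
    tab <- matrix(rpois(4, 40) + 1, 2, 2)
    mine <- chi_square_2x2(tab)
    expect_equal(mine$statistic, yates(tab), tolerance = 1e-12)
    expect_equal(mine$p_value, stats::pchisq(yates(tab), 1,
                                             lower.tail = FALSE),
                 tolerance = 1e-12)
  }

  flat <- chi_square_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(chi_square_2x2(matrix(c(5, 0, 7, 0), 2)), "zero margin")
  expect_error(chi_square_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integers")
})

make_assoc_cohort <- function(n_per, bmi_shift, seed) {
  set.seed(seed)
  n <- 2 * n_per
  cl <- rep(1:2, each = n_per)
  cov <- data.frame(
    scan_id = sprintf("S%04d", 1:n),
    age = pmax(40, rnorm(n, 64.8, 5.84)),
    bmi = pmax(15, rnorm(n, 27.08, 6.04) + bmi_shift * (cl == 2)),
    pack_years = pmax(0, rnorm(n, 52.47, 24.85)),
    sex = sample(c("female", "male"), n, TRUE),
    smoking_status = sample(c("current", "former"), n, TRUE),
    lungrads_group = sample(c("A", "B"), n, TRUE, prob = c(262, 46) / 308),
    cancer = sample(c("no", "yes"), n, TRUE, prob = c(293, 15) / 308),
    stringsAsFactors = FALSE)
  list(cov = cov, assignments = stats::setNames(cl, cov$scan_id))
}

test_that("association tables detect the planted BMI effect and stay null
           elsewhere", {
  co <- make_assoc_cohort(150, bmi_shift = 4, seed = 31)
  tab <- build_association_table(co$assignments, co$cov)
  expect_s3_class(tab, "association_report")
  expect_equal(tab$covariate,
               c("age", "bmi", "sex", "smoking_status", "pack_years",
                 "lungrads_group", "cancer"))
  bmi_p <- tab$p_value[tab$covariate == "bmi"]
  expect_lt(bmi_p, 0.05)
  # cluster-independent covariate should be unremarkable on this seed
  expect_gt(tab$p_value[tab$covariate == "pack_years"], 0.001)

  # p-values invariant to swapping the cluster labels
  swapped <- stats::setNames(3L - co$assignments, names(co$assignments))
  tab2 <- build_association_table(swapped, co$cov)
  expect_equal(tab$p_value, tab2$p_value, tolerance = 1e-12)

  # lossless CSV round trip
  f <- tempfile(fileext = ".csv")
  utils::write.csv(tab, f, row.names = FALSE)
  back <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$p_value, tab$p_value, tolerance = 1e-12)
  expect_equal(back$cluster1, tab$cluster1)

  # a covariate that is entirely NA is dropped with a warning
  co$cov$pack_years <- NA_real_
  expect_warning(t3 <- build_association_table(co$assignments, co$cov),
                 "omitted")
  expect_false("pack_years" %in% t3$covariate)
})
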