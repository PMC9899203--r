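#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with the chi-square asymptotic p-value on
#' (groups - 1) degrees of freedom. When every value is identical the tie
#' correction is degenerate; by convention H = 0, p = 1.
#'
#' @param values Numeric vector.
#' @param groups Group label per value (>= 2 nonempty groups).
#' @return List with `statistic` (H) and `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(groups[keep])
  if (nlevels(groups) < 2) stopf("need >= 2 nonempty groups")
  if (length(unique(values)) == 1)
    return(list(statistic = 0, p_value = 1))
  kt <- kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Chi-square test on a 2x2 contingency table
#'
#' Pearson chi-square with Yates continuity correction by default (the R
#' default for 2x2 tables, and the convention behind the reported screening
#' association p-values); 1 df asymptotic p-value.
#'
#' @param table 2x2 matrix of nonnegative integer counts with all margins
#'   positive.
#' @param continuity Apply the Yates correction?
#' @return List with `statistic` (chi-square) and `p_value`.
#' @export
chi_square_2x2 <- function(table, continuity = TRUE) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2))) stopf("`table` must be 2x2")
  if (any(tab < 0) || any(tab != floor(tab)))
    stopf("counts must be nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("chi-square test undefined: zero margin")
  ct <- suppressWarnings(chisq.test(tab, correct = continuity))
  list(statistic = unname(ct$statistic), p_value = ct$p.value)
}

#' Per-phenotype covariate association table
#'
#' Builds the per-cluster covariate summary: continuous covariates are
#' reported as mean (SD) per cluster and tested with Kruskal-Wallis;
#' categorical covariates as per-cluster counts tested with chi-square
#' (Yates-corrected for 2x2). Rows follow the conventional screening-table
#' order (age, BMI, sex, smoking status, pack-years, Lung-RADS, cancer,
#' obstruction when present); covariates entirely missing are omitted with a
#' warning. Summaries use complete cases per covariate.
#'
#' @param assignments Named integer cluster labels (names = scan ids).
#' @param covariates data.frame with a `scan_id` column and the covariates.
#' @param continuous_set,categorical_set Covariate names to treat as
#'   continuous / categorical.
#' @return An `association_report` data.frame: covariate, one summary column
#'   per cluster, test, statistic, p_value.
#' @export
build_association_table <- function(assignments, covariates,
                                    continuous_set = c("age", "bmi",
                                                       "pack_years"),
                                    categorical_set = c("sex",
                                                        "smoking_status",
                                                        "lungrads_group",
                                                        "cancer",
                                                        "obstruction")) {
  stopifnot(!is.null(names(assignments)), "scan_id" %in% names(covariates))
  cov <- covariates[match(names(assignments), covariates$scan_id), ,
                    drop = FALSE]
  if (any(is.na(cov$scan_id)))
    stopf("assignments contain scans missing from the covariate table")
  cl <- factor(assignments)
  k <- nlevels(cl)

  row_order <- c("age", "bmi", "sex", "smoking_status", "pack_years",
                 "lungrads_group", "cancer", "obstruction")
  wanted <- intersect(row_order, c(continuous_set, categorical_set))
  rows <- list()
  for (v in wanted) {
    if (!v %in% names(cov) || all(is.na(cov[[v]]))) {
      if (v %in% names(cov) || v != "obstruction")
        warning(sprintf("covariate `%s` missing or empty; row omitted", v))
      next
    }
    x <- cov[[v]]
    if (v %in% continuous_set) {
      summaries <- vapply(levels(cl), function(g) {
        xi <- x[cl == g & !is.na(x)]
        sprintf("%.2f (%.2f)", mean(xi), sd(xi))
      }, character(1))
      tst <- kruskal_wallis(x, cl)
      test_name <- "kruskal_wallis"
    } else {
      f <- factor(x)
      tab <- table(f, cl)
      summaries <- vapply(levels(cl), function(g)
        paste(tab[, g], collapse = "/"), character(1))
      tst <- tryCatch({
        if (all(dim(tab) == c(2, 2))) chi_square_2x2(tab) else {
          ct <- suppressWarnings(chisq.test(tab))
          list(statistic = unname(ct$statistic), p_value = ct$p.value)
        }
      }, error = function(e) {
        warning(sprintf("chi-square undefined for `%s`: %s", v,
                        conditionMessage(e)))
        list(statistic = NA_real_, p_value = NA_real_)
      })
      test_name <- "chi_square"
    }
    rows[[v]] <- data.frame(
      covariate = v, t(setNames(summaries, paste0("cluster", levels(cl)))),
      test = test_name, statistic = tst$statistic, p_value = tst$p_value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("association_report", "data.frame")
  out
}
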