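#' Harmonization configuration
#'
#' @param iqr_multiplier Residual-outlier rule half-width: a scan is flagged
#'   when any residual falls outside median +/- `iqr_multiplier` * IQR.
#' @param residual_covariates Continuous covariates used (one at a time) as
#'   predictors in the univariable outlier-screening regressions.
#' @param protected_variables Covariates whose associations with features
#'   ComBat must preserve.
#' @param drop_outliers Drop flagged scans before fitting ComBat?
#' @param eb_tolerance Convergence tolerance of the empirical-Bayes
#'   iterations.
#' @param ks_alpha Significance level for the KS residual-batch assessment.
#' @return A `harmonization_config` list.
#' @export
harmonization_config <- function(iqr_multiplier = 2.5,
                                 residual_covariates = c("age", "bmi",
                                                         "pack_years"),
                                 protected_variables = c("sex",
                                                         "lungrads_group",
                                                         "smoking_status",
                                                         "age", "bmi",
                                                         "pack_years"),
                                 drop_outliers = TRUE,
                                 eb_tolerance = 1e-4,
                                 ks_alpha = 0.05) {
  if (iqr_multiplier <= 0) stopf("`iqr_multiplier` must be > 0")
  if (!(ks_alpha > 0 && ks_alpha < 1)) stopf("`ks_alpha` must be in (0, 1)")
  structure(list(iqr_multiplier = iqr_multiplier,
                 residual_covariates = residual_covariates,
                 protected_variables = protected_variables,
                 drop_outliers = drop_outliers,
                 eb_tolerance = eb_tolerance, ks_alpha = ks_alpha),
            class = "harmonization_config")
}

#' Flag residual outlier scans
#'
#' For each feature and each covariate in `config$residual_covariates`, fits
#' the univariable OLS regression feature ~ intercept + covariate over all
#' scans and flags scan i when its residual falls outside
#' median +/- m * IQR of that residual vector. A constant covariate
#' degenerates to the intercept-only model (residuals = centered values).
#'
#' @param features n x p numeric feature matrix (rownames = scan ids).
#' @param covariates data.frame with the residual covariates, rows aligned
#'   with `features`.
#' @param config A [harmonization_config()].
#' @return List with `flagged` (logical per scan, named) and `triggers`
#'   (data.frame of scan, feature, covariate for each violation).
#' @export
flag_outliers <- function(features, covariates,
                          config = harmonization_config()) {
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(nrow(covariates) == n)
  miss <- setdiff(config$residual_covariates, names(covariates))
  if (length(miss) > 0)
    stopf("missing residual covariates: %s", paste(miss, collapse = ", "))
  scan_ids <- rownames(features) %||% as.character(seq_len(n))
  flagged <- setNames(rep(FALSE, n), scan_ids)
  trig <- list()
  m <- config$iqr_multiplier
  for (cv in config$residual_covariates) {
    x <- as.numeric(covariates[[cv]])
    X <- if (var(x) > 0) cbind(1, x) else matrix(1, n, 1)
    res <- features - X %*% qr.solve(X, features)
    for (f in seq_len(ncol(features))) {
      r <- res[, f]
      med <- median(r)
      iqr <- stats::IQR(r)
      # guard against flagging numerically identical residuals (iqr == 0)
      eps <- 1e-8 * (max(abs(r)) + 1)
      out <- r < med - m * iqr - eps | r > med + m * iqr + eps
      if (any(out)) {
        flagged[out] <- TRUE
        trig[[length(trig) + 1L]] <- data.frame(
          scan_id = scan_ids[out],
          feature = colnames(features)[f] %||% paste0("f", f),
          covariate = cv, stringsAsFactors = FALSE)
      }
    }
  }
  triggers <- if (length(trig) > 0) do.call(rbind, trig) else
    data.frame(scan_id = character(), feature = character(),
               covariate = character(), stringsAsFactors = FALSE)
  list(flagged = flagged, triggers = triggers)
}

# Build the reference-coded design matrix of protected covariates (no
# intercept column; the batch cell-means columns carry the intercept).
protected_design <- function(covariates, protected_variables) {
  cols <- list()
  for (v in protected_variables) {
    if (!v %in% names(covariates))
      stopf("protected variable `%s` missing from covariates", v)
    x <- covariates[[v]]
    if (is.numeric(x)) {
      cols[[v]] <- as.numeric(x)
    } else {
      f <- factor(x)
      if (nlevels(f) > 1)
        for (lv in levels(f)[-1])
          cols[[paste0(v, lv)]] <- as.numeric(f == lv)
    }
  }
  if (length(cols) == 0) return(NULL)
  do.call(cbind, cols)
}

#' Fit parametric empirical-Bayes ComBat
#'
#' Standard parametric ComBat assuming per-batch location and scale
#' variation of each feature: per feature, grand and protected-covariate
#' effects are estimated by least squares; data are standardized; per-batch
#' location (gamma) and scale (delta) estimates are shrunk toward parametric
#' empirical-Bayes priors (normal on location, inverse-gamma on scale),
#' iterated to `config$eb_tolerance`.
#'
#' @param features n x p numeric matrix (scans x features).
#' @param batch Batch label per scan (kernel or manufacturer); factor or
#'   character. Every batch must contain >= 2 scans.
#' @param covariates Optional data.frame of protected covariates aligned
#'   with `features`; the protected design is built from
#'   `config$protected_variables` (reference-coded indicators for
#'   categorical variables). `NULL` for no protected variables.
#' @param config A [harmonization_config()].
#' @return A `combat_model` with standardization parameters (grand mean,
#'   covariate coefficients, pooled variance) and per-(feature, batch)
#'   empirical-Bayes location/scale estimates (gamma_star, delta_star).
#' @export
combat_fit <- function(features, batch, covariates = NULL,
                       config = harmonization_config()) {
  x <- as.matrix(features)
  n <- nrow(x)
  p <- ncol(x)
  batch <- factor(batch)
  stopifnot(length(batch) == n)
  n_b <- table(batch)
  if (any(n_b < 2))
    stopf("batch `%s` has a single scan; ComBat needs >= 2 per batch",
          names(n_b)[which(n_b < 2)[1]])

  B <- vapply(levels(batch), function(b) as.numeric(batch == b),
              numeric(n))
  colnames(B) <- levels(batch)
  mod <- if (is.null(covariates)) NULL else
    protected_design(covariates,
                     intersect(config$protected_variables, names(covariates)))
  design <- cbind(B, mod)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    aliased <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stopf("design matrix is rank deficient; aliased columns: %s",
          paste(aliased, collapse = ", "))
  }

  beta <- qr.coef(qrd, x)                      # (nbatch + q) x p
  nbatch <- nlevels(batch)
  grand_mean <- crossprod(n_b / n, beta[seq_len(nbatch), , drop = FALSE])[1, ]
  var_pooled <- colMeans((x - design %*% beta)^2)
  if (any(var_pooled <= 0))
    stopf("feature with zero pooled variance cannot be harmonized")

  stand_mean <- matrix(grand_mean, n, p, byrow = TRUE)
  if (!is.null(mod))
    stand_mean <- stand_mean +
      mod %*% beta[-(seq_len(nbatch)), , drop = FALSE]
  s <- sweep(x - stand_mean, 2, sqrt(var_pooled), `/`)

  gamma_hat <- delta_hat <- matrix(NA_real_, nbatch, p,
                                   dimnames = list(levels(batch), NULL))
  gamma_star <- delta_star <- gamma_hat
  for (b in seq_len(nbatch)) {
    sb <- s[batch == levels(batch)[b], , drop = FALSE]
    gamma_hat[b, ] <- colMeans(sb)
    delta_hat[b, ] <- apply(sb, 2, var)
    eb <- eb_shrink(sb, gamma_hat[b, ], delta_hat[b, ], config$eb_tolerance)
    gamma_star[b, ] <- eb$gamma
    delta_star[b, ] <- eb$delta
  }

  structure(list(
    grand_mean = grand_mean,
    beta_covariates = if (is.null(mod)) NULL else
      beta[-(seq_len(nbatch)), , drop = FALSE],
    var_pooled = var_pooled,
    gamma_star = gamma_star, delta_star = delta_star,
    gamma_hat = gamma_hat, delta_hat = delta_hat,
    batch_levels = levels(batch),
    protected_variables = config$protected_variables,
    feature_names = colnames(x)), class = "combat_model")
}

# Parametric empirical-Bayes shrinkage of one batch's location/scale
# estimates across features (normal prior on gamma, inverse-gamma on delta),
# iterated to `tol`.
eb_shrink <- function(sb, g_hat, d_hat, tol) {
  n <- nrow(sb)
  g_bar <- mean(g_hat)
  t2 <- var(g_hat)
  # inverse-gamma prior moments
  m <- mean(d_hat)
  s2 <- var(d_hat)
  a_prior <- (2 * s2 + m^2) / s2
  b_prior <- (m * s2 + m^3) / s2
  g_old <- g_hat
  d_old <- d_hat
  change <- 1
  while (change > tol) {
    g_new <- (t2 * n * g_hat + d_old * g_bar) / (t2 * n + d_old)
    sum2 <- colSums(sweep(sb, 2, g_new, `-`)^2)
    d_new <- (0.5 * sum2 + b_prior) / (n / 2 + a_prior - 1)
    change <- max(abs(g_new - g_old) / abs(g_old),
                  abs(d_new - d_old) / abs(d_old))
    g_old <- g_new
    d_old <- d_new
  }
  list(gamma = g_old, delta = d_old)
}

#' Apply a fitted ComBat model
#'
#' Standardizes features with the model's grand/covariate effects and pooled
#' variance, removes the per-batch empirical-Bayes location/scale
#' (subtract gamma*, divide by sqrt(delta*)), and back-transforms, so the
#' protected-covariate structure is re-added unchanged.
#'
#' @param model A `combat_model` from [combat_fit()].
#' @param features n x p matrix with the model's feature columns.
#' @param batch Batch label per scan; every label must be known to the model.
#' @param covariates Protected covariates aligned with `features` (required
#'   when the model was fitted with covariates).
#' @return Harmonized matrix, same shape as `features`.
#' @export
combat_apply <- function(model, features, batch, covariates = NULL) {
  stopifnot(inherits(model, "combat_model"))
  x <- as.matrix(features)
  n <- nrow(x)
  p <- length(model$grand_mean)
  stopifnot(ncol(x) == p)
  batch <- as.character(batch)
  unseen <- setdiff(unique(batch), model$batch_levels)
  if (length(unseen) > 0)
    stopf("unseen batch label(s): %s", paste(unseen, collapse = ", "))

  stand_mean <- matrix(model$grand_mean, n, p, byrow = TRUE)
  if (!is.null(model$beta_covariates)) {
    if (is.null(covariates))
      stopf("model was fitted with protected covariates; supply `covariates`")
    mod <- protected_design(covariates,
                            intersect(model$protected_variables,
                                      names(covariates)))
    stand_mean <- stand_mean + mod %*% model$beta_covariates
  }
  s <- sweep(x - stand_mean, 2, sqrt(model$var_pooled), `/`)
  for (b in model$batch_levels) {
    rows <- which(batch == b)
    if (length(rows) == 0) next
    s[rows, ] <- sweep(sweep(s[rows, , drop = FALSE], 2,
                             model$gamma_star[b, ], `-`),
                       2, sqrt(model$delta_star[b, ]), `/`)
  }
  out <- sweep(s, 2, sqrt(model$var_pooled), `*`) + stand_mean
  dimnames(out) <- dimnames(x)
  out
}

#' Kolmogorov-Smirnov assessment of residual batch differences
#'
#' Two-sample KS test per feature between exactly two batches; p-values use
#' the asymptotic two-sample formula, switching to the exact small-sample
#' computation when either batch has fewer than 25 scans.
#'
#' @param features n x p matrix.
#' @param batch Batch label per scan (exactly 2 distinct labels).
#' @param config A [harmonization_config()] (supplies `ks_alpha`).
#' @return List with `table` (data.frame: feature, D, p) and
#'   `n_significant` (count of features with p < `ks_alpha`).
#' @export
ks_batch_assessment <- function(features, batch,
                                config = harmonization_config()) {
  x <- as.matrix(features)
  batch <- factor(batch)
  if (nlevels(batch) != 2)
    stopf("KS assessment requires exactly 2 batches, got %d", nlevels(batch))
  a <- x[batch == levels(batch)[1], , drop = FALSE]
  b <- x[batch == levels(batch)[2], , drop = FALSE]
  exact <- min(nrow(a), nrow(b)) < 25
  res <- t(vapply(seq_len(ncol(x)), function(f) {
    kt <- suppressWarnings(ks.test(a[, f], b[, f], exact = exact))
    c(D = unname(kt$statistic), p = kt$p.value)
  }, numeric(2)))
  tab <- data.frame(feature = colnames(x) %||% paste0("f", seq_len(ncol(x))),
                    D = res[, 1], p = res[, 2], stringsAsFactors = FALSE)
  list(table = tab, n_significant = sum(tab$p < config$ks_alpha))
}
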