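# Fixtures built once per test session and shared across files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

# One segmented phantom pair (both phenotypes, medium kernel).
phantom_fixture <- function() fixture("phantoms", {
  p1 <- make_phantom_volume(1, "medium", seed = 7)
  p2 <- make_phantom_volume(2, "medium", seed = 107)
  list(p1 = p1, p2 = p2, mask1 = segment_lung(p1$volume))
})

# A small end-to-end pipeline run (synthetic mode, fixed K = 2), reused by
# the pipeline, determinism and structural tests.
pipeline_fixture <- function() fixture("pipeline_run", {
  cfg <- pipeline_config(
    mode = "synthetic",
    cohort = cohort_config(n_scans = 10),
    map_cohort = cohort_config(n_scans = 4, emit_obstruction = TRUE),
    cluster_k = 2,
    seed = 11L)
  dir <- file.path(tempdir(), "lungpheno-run-a")
  manifest <- run_pipeline(cfg, dir)
  list(cfg = cfg, dir = dir, manifest = manifest)
})

# A lung-shaped dendrogram pair built on fabricated merges: a "ladder" tree
# whose displayed leaf order is exactly `labels`.
ladder_dendrogram <- function(labels) {
  n <- length(labels)
  merge <- matrix(0L, n - 1, 2)
  merge[1, ] <- c(-1L, -2L)
  if (n > 2)
    for (m in 2:(n - 1)) merge[m, ] <- c(m - 1L, -(m + 1L))
  hc <- structure(list(merge = merge, height = seq_len(n - 1),
                       order = seq_len(n), labels = labels,
                       method = "ward.D2"), class = "hclust")
  structure(list(hclust = hc, labels = labels,
                 standardization = NULL,
                 data_std = matrix(0, n, 1, dimnames = list(labels, NULL))),
            class = "lp_dendrogram")
}

random_level_window <- function(dim3, ngray, na_frac = 0) {
  lv <- array(sample.int(ngray, prod(dim3), replace = TRUE), dim3)
  if (na_frac > 0)
    lv[sample.int(length(lv), round(na_frac * length(lv)))] <- NA_integer_
  lv
}
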