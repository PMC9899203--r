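# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded generators compose without side effects.
with_rng_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

stopf <- function(fmt, ..., class = "lungpheno_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

# Structured pipeline-stage failure with a machine-readable code.
stage_error <- function(stage, code, message, scan_id = NULL) {
  stop(structure(
    class = c("lungpheno_stage_error", "lungpheno_error", "error", "condition"),
    list(message = sprintf("[stage %s] %s%s", stage, message,
                           if (is.null(scan_id)) "" else
                             sprintf(" (scan %s)", scan_id)),
         stage = stage, code = code, scan_id = scan_id, call = NULL)))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x) && x >= 0
}

# Separable 3D Gaussian smoothing with physical sigma (mm) under possibly
# anisotropic voxel spacing; edges handled by index clamping (replication).
gaussian_blur3d <- function(x, sigma_mm, spacing) {
  stopifnot(length(dim(x)) == 3L, sigma_mm > 0)
  out <- x
  for (axis in 1:3) {
    sig_vox <- sigma_mm / spacing[axis]
    half <- max(1L, as.integer(ceiling(3 * sig_vox)))
    w <- dnorm(seq(-half, half), sd = sig_vox)
    w <- w / sum(w)
    n <- dim(out)[axis]
    acc <- array(0, dim(out))
    for (k in seq_along(w)) {
      off <- k - half - 1L
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)
      shifted <- switch(axis,
                        out[idx, , , drop = FALSE],
                        out[, idx, , drop = FALSE],
                        out[, , idx, drop = FALSE])
      acc <- acc + w[k] * shifted
    }
    out <- acc
  }
  out
}

# Integer voxel offsets of a physically spherical structuring element.
ball_offsets <- function(radius_mm, spacing) {
  r_vox <- pmax(0L, as.integer(floor(radius_mm / spacing)))
  grid <- expand.grid(dx = -r_vox[1]:r_vox[1],
                      dy = -r_vox[2]:r_vox[2],
                      dz = -r_vox[3]:r_vox[3])
  d2 <- (grid$dx * spacing[1])^2 + (grid$dy * spacing[2])^2 +
    (grid$dz * spacing[3])^2
  as.matrix(grid[d2 <= radius_mm^2 + 1e-9, , drop = FALSE])
}

md5_of_string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeChar(x, tf, eos = NULL)
  unname(tools::md5sum(tf))
}
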