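# Independent oracles: brute-force recomputations used to validate the
# package's texture and clustering code paths.

oracle_dirs <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1), c(0, 1, 1), c(0, 1, -1),
  c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

in_bounds <- function(p, d) all(p >= 1) && all(p <= d)

# Enumerates every voxel pair per direction; features computed with explicit
# double loops over the normalized matrix.
oracle_glcm <- function(lv, ngray, distance = 1) {
  d <- dim(lv)
  counts <- matrix(0, ngray, ngray)
  for (k in seq_len(nrow(oracle_dirs))) {
    off <- oracle_dirs[k, ] * distance
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      q <- c(x, y, z) + off
      if (!in_bounds(q, d)) next
      a <- lv[x, y, z]
      b <- lv[q[1], q[2], q[3]]
      if (is.na(a) || is.na(b)) next
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  if (sum(counts) == 0) return(NULL)
  p <- counts / sum(counts)
  mu <- 0
  for (i in 1:ngray) mu <- mu + i * sum(p[i, ])
  sig2 <- 0
  for (i in 1:ngray) sig2 <- sig2 + (i - mu)^2 * sum(p[i, ])
  feats <- c(glcm_contrast = 0, glcm_correlation = 0, glcm_energy = 0,
             glcm_homogeneity = 0, glcm_entropy = 0, glcm_dissimilarity = 0,
             glcm_cluster_shade = 0, glcm_cluster_prominence = 0,
             glcm_max_probability = 0)
  for (i in 1:ngray) for (j in 1:ngray) {
    pij <- p[i, j]
    feats["glcm_contrast"] <- feats["glcm_contrast"] + pij * (i - j)^2
    feats["glcm_energy"] <- feats["glcm_energy"] + pij^2
    feats["glcm_homogeneity"] <- feats["glcm_homogeneity"] +
      pij / (1 + (i - j)^2)
    if (pij > 0)
      feats["glcm_entropy"] <- feats["glcm_entropy"] - pij * log(pij)
    feats["glcm_dissimilarity"] <- feats["glcm_dissimilarity"] +
      pij * abs(i - j)
    feats["glcm_cluster_shade"] <- feats["glcm_cluster_shade"] +
      pij * (i + j - 2 * mu)^3
    feats["glcm_cluster_prominence"] <- feats["glcm_cluster_prominence"] +
      pij * (i + j - 2 * mu)^4
    if (sig2 > 0)
      feats["glcm_correlation"] <- feats["glcm_correlation"] +
        pij * (i - mu) * (j - mu) / sig2
  }
  feats["glcm_max_probability"] <- max(p)
  feats
}

# Scans every ray per direction and splits runs by hand.
oracle_glrlm <- function(lv, ngray) {
  d <- dim(lv)
  maxlen <- max(d)
  counts <- matrix(0, ngray, maxlen)
  n_in <- sum(!is.na(lv))
  for (k in seq_len(nrow(oracle_dirs))) {
    off <- oracle_dirs[k, ]
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      if (in_bounds(c(x, y, z) - off, d)) next  # not a ray start
      ray <- integer(0)
      p <- c(x, y, z)
      while (in_bounds(p, d)) {
        ray <- c(ray, lv[p[1], p[2], p[3]])
        p <- p + off
      }
      cur <- NA_integer_
      len <- 0L
      for (v in c(ray, NA_integer_)) {
        if (!is.na(v) && !is.na(cur) && v == cur) {
          len <- len + 1L
        } else {
          if (len > 0) counts[cur, len] <- counts[cur, len] + 1
          cur <- v
          len <- if (is.na(v)) 0L else 1L
        }
      }
    }
  }
  nr <- sum(counts)
  if (nr == 0) return(NULL)
  feats <- c(glrlm_sre = 0, glrlm_lre = 0, glrlm_gln = 0, glrlm_rln = 0,
             glrlm_rp = nr / (13 * n_in), glrlm_lgre = 0, glrlm_hgre = 0,
             glrlm_srlge = 0, glrlm_srhge = 0, glrlm_lrlge = 0,
             glrlm_lrhge = 0)
  for (g in 1:ngray) for (l in 1:maxlen) {
    r <- counts[g, l]
    if (r == 0) next
    feats["glrlm_sre"] <- feats["glrlm_sre"] + r / l^2
    feats["glrlm_lre"] <- feats["glrlm_lre"] + r * l^2
    feats["glrlm_lgre"] <- feats["glrlm_lgre"] + r / g^2
    feats["glrlm_hgre"] <- feats["glrlm_hgre"] + r * g^2
    feats["glrlm_srlge"] <- feats["glrlm_srlge"] + r / (g^2 * l^2)
    feats["glrlm_srhge"] <- feats["glrlm_srhge"] + r * g^2 / l^2
    feats["glrlm_lrlge"] <- feats["glrlm_lrlge"] + r * l^2 / g^2
    feats["glrlm_lrhge"] <- feats["glrlm_lrhge"] + r * g^2 * l^2
  }
  for (g in 1:ngray) feats["glrlm_gln"] <- feats["glrlm_gln"] +
    sum(counts[g, ])^2
  for (l in 1:maxlen) feats["glrlm_rln"] <- feats["glrlm_rln"] +
    sum(counts[, l])^2
  feats[c("glrlm_sre", "glrlm_lre", "glrlm_gln", "glrlm_rln", "glrlm_lgre",
          "glrlm_hgre", "glrlm_srlge", "glrlm_srhge", "glrlm_lrlge",
          "glrlm_lrhge")] <-
    feats[c("glrlm_sre", "glrlm_lre", "glrlm_gln", "glrlm_rln",
            "glrlm_lgre", "glrlm_hgre", "glrlm_srlge", "glrlm_srhge",
            "glrlm_lrlge", "glrlm_lrhge")] / nr
  feats
}

# Run-length statistics of a 1x1xn strip along its axis only (the spec's
# single-direction hand examples).
oracle_glrlm_1d <- function(strip) {
  vals <- as.integer(strip)
  r <- rle(vals)
  nr <- length(r$lengths)
  list(rp = nr / length(vals),
       sre = sum(1 / r$lengths^2) / nr,
       lre = sum(r$lengths^2) / nr,
       gln = sum(table(r$values)^2) / nr,
       rln = sum(table(r$lengths)^2) / nr)
}

# Exhaustive Ward agglomeration via the Lance-Williams update on squared
# distances (the ward.D2 convention).
oracle_ward_heights <- function(x) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  sizes <- rep(1, n)
  active <- 1:n
  heights <- numeric(0)
  for (step in 1:(n - 1)) {
    best <- c(NA, NA, Inf)
    for (i in seq_along(active)) for (j in seq_len(i - 1)) {
      a <- active[i]
      b <- active[j]
      if (d[a, b] < best[3]) best <- c(a, b, d[a, b])
    }
    a <- best[1]; b <- best[2]; h <- best[3]
    heights <- c(heights, h)
    for (k in active) {
      if (k %in% c(a, b)) next
      d2 <- sqrt(((sizes[a] + sizes[k]) * d[a, k]^2 +
                  (sizes[b] + sizes[k]) * d[b, k]^2 -
                  sizes[k] * h^2) / (sizes[a] + sizes[b] + sizes[k]))
      d[a, k] <- d[k, a] <- d2
    }
    sizes[a] <- sizes[a] + sizes[b]
    active <- setdiff(active, b)
  }
  heights
}

rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, `==`)[upper.tri(diag(n))]
  same_b <- outer(b, b, `==`)[upper.tri(diag(n))]
  mean(same_a == same_b)
}
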