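# Independent brute-force oracles used to verify the vectorized feature and
# geometry code. These are deliberately naive (explicit loops over voxels,
# pairs, runs and zones) and share no code with the package internals.

oracle_dirs13 <- matrix(c(
  1, 0, 0,  0, 1, 0,  0, 0, 1,
  1, 1, 0,  1, -1, 0, 1, 0, 1,
  1, 0, -1, 0, 1, 1,  0, 1, -1,
  1, 1, 1,  1, 1, -1, 1, -1, 1, 1, -1, -1), ncol = 3, byrow = TRUE)

# same documented binning rule as the package default (fixed bin number over
# VOI min-max), restated independently
oracle_discretize <- function(vals, mask, n_bins) {
  v <- vals[mask]
  lo <- min(v); hi <- max(v)
  g <- array(0L, dim(mask))
  if (hi <= lo) {
    g[mask] <- 1L
  } else {
    g[mask] <- pmin(pmax(floor((vals[mask] - lo) / (hi - lo) * n_bins) + 1L,
                         1L), n_bins)
  }
  g
}

in_grid <- function(p, d) all(p >= 1) && all(p <= d)

# GLCM: direction-averaged features from exhaustively enumerated pairs
oracle_glcm <- function(vals, mask, n_bins) {
  d <- dim(mask)
  g <- oracle_discretize(vals, mask, n_bins)
  L <- n_bins
  idx <- which(mask, arr.ind = TRUE)
  per_dir <- list()
  for (k in seq_len(nrow(oracle_dirs13))) {
    dv <- oracle_dirs13[k, ]
    M <- matrix(0, L, L)
    for (r in seq_len(nrow(idx))) {
      p <- idx[r, ]; q <- p + dv
      if (in_grid(q, d) && mask[q[1], q[2], q[3]]) {
        i <- g[p[1], p[2], p[3]]; j <- g[q[1], q[2], q[3]]
        M[i, j] <- M[i, j] + 1
      }
    }
    if (sum(M) == 0) next
    P <- (M + t(M)); P <- P / sum(P)
    ii <- matrix(seq_len(L), L, L); jj <- t(ii)
    mu <- sum(ii * P); s2 <- sum((ii - mu)^2 * P)
    pp <- P[P > 0]
    per_dir[[length(per_dir) + 1]] <- c(
      homogeneity = sum(P / (1 + abs(ii - jj))),
      energy = sum(P^2),
      contrast = sum((ii - jj)^2 * P),
      correlation = if (s2 > 0) sum((ii - mu) * (jj - mu) * P) / s2 else NA_real_,
      entropy = -sum(pp * log2(pp)),
      dissimilarity = sum(abs(ii - jj) * P))
  }
  rowMeans(do.call(cbind, per_dir))
}

# maximal in-mask constant-level runs along one direction, by walking
oracle_runs <- function(g, mask, dv) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  runs <- NULL
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    lev <- g[p[1], p[2], p[3]]
    prev <- p - dv
    if (in_grid(prev, d) && mask[prev[1], prev[2], prev[3]] &&
        g[prev[1], prev[2], prev[3]] == lev) next  # not a run start
    len <- 1L
    q <- p + dv
    while (in_grid(q, d) && mask[q[1], q[2], q[3]] &&
           g[q[1], q[2], q[3]] == lev) {
      len <- len + 1L
      q <- q + dv
    }
    runs <- rbind(runs, c(lev, len))
  }
  runs
}

oracle_rlm_indices <- function(runs, np) {
  lev <- runs[, 1]; len <- runs[, 2]
  nr <- nrow(runs)
  c(SRE = sum(1 / len^2) / nr, LRE = sum(len^2) / nr,
    LGRE = sum(1 / lev^2) / nr, HGRE = sum(lev^2) / nr,
    SRLGE = sum(1 / (lev^2 * len^2)) / nr,
    SRHGE = sum(lev^2 / len^2) / nr,
    LRLGE = sum(len^2 / lev^2) / nr,
    LRHGE = sum(lev^2 * len^2) / nr,
    GLNU = sum(table(lev)^2) / nr,
    RLNU = sum(table(len)^2) / nr,
    RP = nr / np)
}

oracle_glrlm <- function(vals, mask, n_bins) {
  g <- oracle_discretize(vals, mask, n_bins)
  np <- sum(mask)
  f <- sapply(seq_len(nrow(oracle_dirs13)), function(k)
    oracle_rlm_indices(oracle_runs(g, mask, oracle_dirs13[k, ]), np))
  rowMeans(f)
}

# NGLDM: per-voxel 26-neighborhood mean differences, plain loops
oracle_ngldm <- function(vals, mask, n_bins) {
  d <- dim(mask)
  g <- oracle_discretize(vals, mask, n_bins)
  L <- n_bins
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  idx <- which(mask, arr.ind = TRUE)
  nvox <- nrow(idx)
  s <- numeric(L); ni <- numeric(L)
  for (r in seq_len(nvox)) {
    p <- idx[r, ]
    lev <- g[p[1], p[2], p[3]]
    ni[lev] <- ni[lev] + 1
    nb <- c()
    for (o in seq_len(nrow(offs))) {
      q <- p + offs[o, ]
      if (in_grid(q, d) && mask[q[1], q[2], q[3]])
        nb <- c(nb, g[q[1], q[2], q[3]])
    }
    if (length(nb) > 0) s[lev] <- s[lev] + abs(lev - mean(nb))
  }
  p_i <- ni / nvox
  occ <- which(p_i > 0); ng <- length(occ)
  contrast <- 0
  if (ng > 1) {
    num <- 0
    for (i in occ) for (j in occ) num <- num + p_i[i] * p_i[j] * (i - j)^2
    contrast <- num / (ng * (ng - 1)) * sum(s) / nvox
  }
  psum <- sum(p_i * s)
  bden <- 0
  if (ng > 1)
    for (i in occ) for (j in occ)
      if (i != j) bden <- bden + abs(i * p_i[i] - j * p_i[j])
  c(Coarseness = if (psum > 0) 1 / psum else NA_real_,
    Contrast = contrast,
    Busyness = if (bden > 0) psum / bden else NA_real_)
}

# GLZLM: zones by explicit BFS flood fill over 26-connectivity
oracle_zones <- function(g, mask) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  seen <- array(FALSE, d)
  zones <- NULL
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p0 <- idx[r, ]
    if (seen[p0[1], p0[2], p0[3]]) next
    lev <- g[p0[1], p0[2], p0[3]]
    stack <- list(p0)
    seen[p0[1], p0[2], p0[3]] <- TRUE
    size <- 0L
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (o in seq_len(nrow(offs))) {
        q <- p + offs[o, ]
        if (in_grid(q, d) && mask[q[1], q[2], q[3]] &&
            !seen[q[1], q[2], q[3]] && g[q[1], q[2], q[3]] == lev) {
          seen[q[1], q[2], q[3]] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
    zones <- rbind(zones, c(lev, size))
  }
  zones
}

oracle_glzlm <- function(vals, mask, n_bins) {
  g <- oracle_discretize(vals, mask, n_bins)
  z <- oracle_zones(g, mask)
  lev <- z[, 1]; sz <- z[, 2]
  nz <- nrow(z); np <- sum(mask)
  c(SZE = sum(1 / sz^2) / nz, LZE = sum(sz^2) / nz,
    LGZE = sum(1 / lev^2) / nz, HGZE = sum(lev^2) / nz,
    SZLGE = sum(1 / (lev^2 * sz^2)) / nz, SZHGE = sum(lev^2 / sz^2) / nz,
    LZLGE = sum(sz^2 / lev^2) / nz, LZHGE = sum(lev^2 * sz^2) / nz,
    GLNUz = sum(table(lev)^2) / nz, ZLNU = sum(table(sz)^2) / nz,
    ZP = nz / np)
}

# physical-distance dilation by direct pairwise check (small grids only)
oracle_dilate <- function(mask, radius_mm, sp) {
  d <- dim(mask)
  src <- which(mask, arr.ind = TRUE)
  out <- array(FALSE, d)
  all_idx <- which(array(TRUE, d), arr.ind = TRUE)
  for (r in seq_len(nrow(all_idx))) {
    v <- all_idx[r, ]
    for (s in seq_len(nrow(src))) {
      dist2 <- sum(((v - src[s, ]) * sp)^2)
      if (dist2 <= radius_mm^2 + 1e-9) { out[v[1], v[2], v[3]] <- TRUE; break }
    }
  }
  out
}

# ROC AUC by exhaustive concordant-pair counting
oracle_auc <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

# random small VOI fixture: values + connected-ish random mask
random_voi <- function(seed, dmax = 6, n_levels_vals = 40) {
  set.seed(seed)
  d <- sample(3:dmax, 3, replace = TRUE)
  vals <- array(stats::rnorm(prod(d), 60, 25), d)
  mask <- array(stats::runif(prod(d)) < 0.65, d)
  if (sum(mask) < 3) mask[sample(prod(d), 3)] <- TRUE
  list(vals = vals, mask = mask, dim = d)
}
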