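# Texture matrix features (GLCM, GLRLM, NGLDM, GLZLM) on discretized VOIs.
# All matrices are built in 3D over the 26-neighborhood / 13 unique
# directions, restricted to in-mask voxels; undefined indices follow the
# package sentinel policy (NA + warning, keys never dropped).

# ---- GLCM ------------------------------------------------------------------

#' Grey-level co-occurrence matrix features
#'
#' Symmetric co-occurrence counts of discretized grey levels at distance 1,
#' over the 13 unique 3D directions, restricted to voxel pairs that are both
#' inside the mask. By default a feature value is computed per direction and
#' averaged over directions with at least one pair
#' (\code{aggregate = "average"}); \code{"merge"} pools counts across
#' directions into one matrix first.
#'
#' Features (normalized matrix P over levels i, j; marginal mean mu and
#' variance sigma^2): homogeneity sum P/(1+|i-j|); energy sum P^2; contrast
#' sum (i-j)^2 P; correlation sum (i-mu)(j-mu) P / sigma^2; entropy
#' -sum P log2 P; dissimilarity sum |i-j| P. A zero grey-level variance
#' leaves correlation undefined (NA, warning).
#'
#' @inheritParams histogram_features
#' @param aggregate \code{"average"} (per-direction features averaged) or
#'   \code{"merge"} (single pooled matrix).
#' @return Named numeric of 6 GLCM features.
#' @export
glcm_features <- function(volume, mask, scheme = discretization_scheme(),
                          aggregate = c("average", "merge")) {
  aggregate <- match.arg(aggregate)
  vals <- if (inherits(volume, "image_volume")) volume$values else volume
  m <- as_mask_array(mask)
  if (sum(m) < 2L) stop("GLCM needs at least 2 masked voxels")
  dd <- discretize_voi(vals, m, scheme)
  g <- dd$levels; L <- dd$n_levels
  dirs <- directions_13()
  mats <- vector("list", nrow(dirs))
  for (k in seq_len(nrow(dirs))) {
    d <- dirs[k, ]
    nm <- shift_array(m, -d, FALSE)      # nm[v] = m[v + d]
    valid <- m & nm
    if (!any(valid)) { mats[[k]] <- NULL; next }
    gn <- shift_array(g, -d, 0L)
    i <- g[valid]; j <- gn[valid]
    M <- matrix(tabulate((j - 1L) * L + i, nbins = L * L), L, L)
    mats[[k]] <- M + t(M)                # symmetric counts
  }
  mats <- Filter(Negate(is.null), mats)
  if (length(mats) == 0L)
    stop("GLCM needs at least one in-mask neighbor pair")
  if (aggregate == "merge") mats <- list(Reduce(`+`, mats))
  feats <- vapply(mats, glcm_from_matrix, numeric(6))
  res <- rowMeans(feats, na.rm = FALSE)
  if (anyNA(res))
    warning("GLCM correlation undefined (zero grey-level variance); NA sentinel")
  names(res) <- paste0("GLCM_", c("Homogeneity", "Energy", "Contrast",
                                  "Correlation", "Entropy", "Dissimilarity"))
  res
}

glcm_from_matrix <- function(M) {
  P <- M / sum(M)
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  pr <- rowSums(P)
  mu <- sum(seq_len(L) * pr)
  s2 <- sum((seq_len(L) - mu)^2 * pr)
  corr <- if (s2 > 0) sum((i - mu) * (j - mu) * P) / s2 else NA_real_
  pp <- P[P > 0]
  c(sum(P / (1 + abs(i - j))),
    sum(P^2),
    sum((i - j)^2 * P),
    corr,
    -sum(pp * log2(pp)),
    sum(abs(i - j) * P))
}

# ---- GLRLM -----------------------------------------------------------------

#' Grey-level run-length matrix features
#'
#' Maximal runs of constant discretized grey level along each of the 13
#' unique 3D directions, restricted to in-mask voxels (a gap in the mask
#' breaks a run). Features are computed per direction and averaged.
#'
#' With runs of level i and length l (Nr runs, Np masked voxels): SRE
#' sum 1/l^2 / Nr, LRE sum l^2 / Nr, LGRE sum 1/i^2 / Nr, HGRE sum i^2 / Nr,
#' SRLGE, SRHGE, LRLGE, LRHGE the four cross terms, GLNU and RLNU the
#' squared marginal-count sums / Nr, RP = Nr / Np.
#'
#' @inheritParams histogram_features
#' @return Named numeric of 11 GLRLM features.
#' @export
glrlm_features <- function(volume, mask, scheme = discretization_scheme()) {
  vals <- if (inherits(volume, "image_volume")) volume$values else volume
  m <- as_mask_array(mask)
  if (!any(m)) stop("mask is empty")
  dd <- discretize_voi(vals, m, scheme)
  g <- dd$levels
  np <- sum(m)
  dirs <- directions_13()
  feats <- vapply(seq_len(nrow(dirs)), function(k) {
    r <- runs_along(g, dirs[k, ], dd$n_levels)
    rlm_indices(r$level, r$length, np)
  }, numeric(11))
  res <- rowMeans(feats)
  names(res) <- paste0("GLRLM_", c("SRE", "LRE", "LGRE", "HGRE", "SRLGE",
                                   "SRHGE", "LRLGE", "LRHGE", "GLNU",
                                   "RLNU", "RP"))
  res
}

# Enumerate maximal constant-level runs along direction d over the whole
# grid (level 0 = outside mask, dropped). Lines are grouped by the lattice
# key p - s*d where s is the coordinate along the first +1 axis of d.
runs_along <- function(g, d, L) {
  dm <- dim(g)
  n <- length(g)
  idx <- arrayInd(seq_len(n), dm)
  ax <- which(d != 0)[1]                     # canonical: d[ax] == +1
  s <- idx[, ax]
  k1 <- idx[, 1] - s * d[1]
  k2 <- idx[, 2] - s * d[2]
  k3 <- idx[, 3] - s * d[3]
  M <- 2L * max(dm) + 3L
  id <- (k1 * M + k2) * M + k3
  ord <- order(id, s, method = "radix")
  v <- as.vector(g)[ord]
  lid <- id[ord]
  newline <- c(TRUE, lid[-1] != lid[-n])
  line <- cumsum(newline)
  r <- rle(v + line * (L + 1L))              # level + line offset: runs never span lines
  ends <- cumsum(r$lengths)
  lev <- v[ends]
  keep <- lev > 0L
  list(level = lev[keep], length = r$lengths[keep])
}

rlm_indices <- function(lev, len, np) {
  nr <- length(lev)
  if (nr == 0L) return(rep(NA_real_, 11))
  il2 <- 1 / len^2; l2 <- as.numeric(len)^2
  ig2 <- 1 / as.numeric(lev)^2; g2 <- as.numeric(lev)^2
  cl <- tabulate(lev)
  cr <- tabulate(len)
  c(SRE = sum(il2) / nr, LRE = sum(l2) / nr,
    LGRE = sum(ig2) / nr, HGRE = sum(g2) / nr,
    SRLGE = sum(ig2 * il2) / nr, SRHGE = sum(g2 * il2) / nr,
    LRLGE = sum(ig2 * l2) / nr, LRHGE = sum(g2 * l2) / nr,
    GLNU = sum(cl^2) / nr, RLNU = sum(cr^2) / nr,
    RP = nr / np)
}

# ---- NGLDM -----------------------------------------------------------------

#' Neighboring grey-level difference matrix features
#'
#' For each masked voxel, the mean discretized grey level of its in-mask
#' 26-neighbors is computed; s_i is the summed absolute difference between
#' voxels of level i and their neighborhood mean, p_i the level's voxel
#' fraction. Voxels with no in-mask neighbor contribute 0 to s.
#' Coarseness = 1 / sum(p_i s_i); Contrast =
#' (sum_{i != j} p_i p_j (i-j)^2 / (Ng (Ng-1))) * (sum s_i / N); Busyness =
#' sum(p_i s_i) / sum_{i != j} |i p_i - j p_j| (over occupied levels).
#' A single-level VOI gives Contrast 0 and leaves Coarseness and Busyness
#' degenerate (NA sentinel, warning).
#'
#' @inheritParams histogram_features
#' @return Named numeric: NGLDM_Coarseness, NGLDM_Contrast, NGLDM_Busyness.
#' @export
ngldm_features <- function(volume, mask, scheme = discretization_scheme()) {
  vals <- if (inherits(volume, "image_volume")) volume$values else volume
  m <- as_mask_array(mask)
  if (!any(m)) stop("mask is empty")
  dd <- discretize_voi(vals, m, scheme)
  g <- dd$levels; L <- dd$n_levels
  nsum <- array(0, dim(m)); ncnt <- array(0L, dim(m))
  dirs <- directions_13()
  for (k in seq_len(nrow(dirs))) {
    for (sgn in c(1L, -1L)) {
      o <- sgn * dirs[k, ]
      sm <- shift_array(m, o, FALSE)
      sg <- shift_array(g, o, 0L)
      nsum <- nsum + sg * sm
      ncnt <- ncnt + sm
    }
  }
  lev <- g[m]
  cnt <- ncnt[m]
  dev <- numeric(length(lev))
  has <- cnt > 0L
  dev[has] <- abs(lev[has] - (nsum[m][has] / cnt[has]))
  nvox <- length(lev)
  ni <- tabulate(lev, nbins = L)
  p <- ni / nvox
  s <- vapply(split(dev, factor(lev, levels = seq_len(L))), sum, numeric(1))
  occ <- which(p > 0)
  ng <- length(occ)
  contrast <- if (ng > 1) {
    ii <- rep(occ, each = ng); jj <- rep(occ, times = ng)
    num <- sum(p[ii] * p[jj] * (ii - jj)^2)
    (num / (ng * (ng - 1))) * (sum(s) / nvox)
  } else 0
  psum <- sum(p * s)
  coarse <- if (psum > 0) 1 / psum else NA_real_
  bden <- if (ng > 1) {
    ii <- rep(occ, each = ng); jj <- rep(occ, times = ng)
    keep <- ii != jj
    sum(abs(ii[keep] * p[ii[keep]] - jj[keep] * p[jj[keep]]))
  } else 0
  busy <- if (bden > 0) psum / bden else NA_real_
  if (is.na(coarse) || is.na(busy))
    warning("degenerate NGLDM (single level or flat neighborhood); NA sentinel")
  c(NGLDM_Coarseness = coarse, NGLDM_Contrast = contrast,
    NGLDM_Busyness = busy)
}

# ---- GLZLM -----------------------------------------------------------------

#' Grey-level zone-length (size-zone) matrix features
#'
#' Zones are maximal 26-connected components of constant discretized grey
#' level inside the mask; the matrix counts zones by (level, size). Indices
#' mirror the run-length family with run length replaced by zone size S:
#' SZE, LZE, LGZE, HGZE, SZLGE, SZHGE, LZLGE, LZHGE, GLNUz, ZLNU,
#' ZP = Nz / Np.
#'
#' @inheritParams histogram_features
#' @return Named numeric of 11 GLZLM features.
#' @export
glzlm_features <- function(volume, mask, scheme = discretization_scheme()) {
  vals <- if (inherits(volume, "image_volume")) volume$values else volume
  m <- as_mask_array(mask)
  if (!any(m)) stop("mask is empty")
  dd <- discretize_voi(vals, m, scheme)
  z <- zones_26(dd$levels, m)
  np <- sum(m)
  nz <- length(z$size)
  sz <- as.numeric(z$size); lv <- as.numeric(z$level)
  is2 <- 1 / sz^2; s2 <- sz^2
  ig2 <- 1 / lv^2; g2 <- lv^2
  cl <- tabulate(z$level)
  cs <- tabulate(z$size)
  res <- c(SZE = sum(is2) / nz, LZE = sum(s2) / nz,
           LGZE = sum(ig2) / nz, HGZE = sum(g2) / nz,
           SZLGE = sum(ig2 * is2) / nz, SZHGE = sum(g2 * is2) / nz,
           LZLGE = sum(ig2 * s2) / nz, LZHGE = sum(g2 * s2) / nz,
           GLNUz = sum(cl^2) / nz, ZLNU = sum(cs^2) / nz,
           ZP = nz / np)
  names(res) <- paste0("GLZLM_", names(res))
  res
}

# 26-connected constant-level zones by iterative minimum-label propagation.
# Returns list(level, size) per zone.
zones_26 <- function(g, m) {
  lab <- array(0, dim(m))
  lab[m] <- which(m)
  dirs <- directions_13()
  offs <- rbind(dirs, -dirs)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(offs))) {
      o <- offs[k, ]
      sl <- shift_array(lab, o, 0)
      sg <- shift_array(g, o, 0L)
      sel <- m & sl > 0 & sg == g & sl < lab
      if (any(sel)) {
        lab[sel] <- sl[sel]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  zl <- lab[m]
  zg <- g[m]
  f <- factor(zl)
  list(level = as.integer(tapply(zg, f, `[`, 1L)),
       size = as.integer(tabulate(as.integer(f))))
}
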