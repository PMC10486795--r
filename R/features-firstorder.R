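#' Grey-level descriptors of a VOI
#'
#' The seven standard HU descriptors over the masked voxels only: minimum,
#' mean, standard deviation, maximum, and the three quartile-style tertile
#' cut points HUQ1/HUQ2/HUQ3 (25th/50th/75th percentiles under the inclusive
#' linear-interpolation quantile rule, \code{\link[stats]{quantile}} type 7).
#' The standard deviation is the population SD (a single voxel gives 0).
#'
#' @param volume an \code{image_volume} (or bare 3D numeric array).
#' @param mask logical/0-1 3D mask, nonempty.
#' @return Named numeric: HUmin, HUmean, HUstd, HUmax, HUQ1, HUQ2, HUQ3.
#' @export
grey_level_descriptors <- function(volume, mask) {
  vals <- if (inherits(volume, "image_volume")) volume$values else volume
  m <- as_mask_array(mask)
  if (!any(m)) stop("mask is empty")
  v <- vals[m]
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(HUmin = min(v), HUmean = mean(v), HUstd = pop_sd(v), HUmax = max(v),
    HUQ1 = q[1], HUQ2 = q[2], HUQ3 = q[3])
}

#' First-order histogram features of a VOI
#'
#' Skewness and kurtosis are standardized central moments of the raw masked
#' intensities (population moments; kurtosis is the plain fourth standardized
#' moment, 3 for a normal distribution). Histogram energy and entropy are
#' computed on the discretized grey-level probabilities p:
#' energy = sum(p^2), entropy = -sum(p log2 p). A zero-variance VOI leaves
#' skewness and kurtosis undefined: they are reported as \code{NA} with a
#' warning (the package-wide sentinel policy; keys are never dropped).
#'
#' @inheritParams grey_level_descriptors
#' @param scheme a \code{\link{discretization_scheme}}.
#' @return Named numeric: Skewness, Kurtosis, Histogram_Energy,
#'   Histogram_Entropy.
#' @export
histogram_features <- function(volume, mask, scheme = discretization_scheme()) {
  vals <- if (inherits(volume, "image_volume")) volume$values else volume
  m <- as_mask_array(mask)
  if (!any(m)) stop("mask is empty")
  v <- vals[m]
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  if (m2 <= 0) {
    warning("zero-variance VOI: skewness/kurtosis undefined, reported as NA")
    sk <- NA_real_; ku <- NA_real_
  } else {
    sk <- mean((v - mu)^3) / m2^1.5
    ku <- mean((v - mu)^4) / m2^2
  }
  dd <- discretize_voi(vals, m, scheme)
  p <- tabulate(dd$levels[m], nbins = dd$n_levels)
  p <- p / sum(p)
  p <- p[p > 0]
  c(Skewness = sk, Kurtosis = ku,
    Histogram_Energy = sum(p^2),
    Histogram_Entropy = -sum(p * log2(p)))
}

#' Shape features of a binary VOI
#'
#' Volume is voxel count times voxel volume, reported in millilitres.
#' Surface area A is measured on a triangulated iso-surface of the binary
#' mask (marching-tetrahedra mesh at the 0.5 level; \code{method = "faces"}
#' gives the cruder voxel-face-count area used as an oracle bound in tests).
#' Sphericity = pi^(1/3) (6V)^(2/3) / A with V in mm^3 (1 for a perfect
#' sphere, smaller for irregular shapes). Compacity = A^(3/2) / V
#' (dimensionless; larger for irregular shapes).
#'
#' @param mask logical/0-1 3D mask, nonempty.
#' @param spacing_mm per-axis voxel size in mm.
#' @param method surface-area estimator: \code{"mesh"} (default) or
#'   \code{"faces"}.
#' @return Named numeric: Shape_Volume_mL, Shape_Sphericity, Shape_Compacity.
#' @export
shape_features <- function(mask, spacing_mm, method = c("mesh", "faces")) {
  method <- match.arg(method)
  m <- as_mask_array(mask)
  if (!any(m)) stop("mask is empty")
  spacing_mm <- as.numeric(spacing_mm)
  vol_mm3 <- sum(m) * prod(spacing_mm)
  A <- surface_area(m, spacing_mm, method)
  c(Shape_Volume_mL = vol_mm3 / 1000,
    Shape_Sphericity = pi^(1 / 3) * (6 * vol_mm3)^(2 / 3) / A,
    Shape_Compacity = A^1.5 / vol_mm3)
}

#' Surface area of a binary mask
#'
#' @inheritParams shape_features
#' @return Surface area in mm^2.
#' @export
surface_area <- function(mask, spacing_mm, method = c("mesh", "faces")) {
  method <- match.arg(method)
  m <- as_mask_array(mask)
  spacing_mm <- as.numeric(spacing_mm)
  if (method == "faces") return(face_count_area(m, spacing_mm))
  mesh_area(m, spacing_mm)
}

# Exposed-face area: count 6-neighbor in/out transitions per axis.
face_count_area <- function(m, sp) {
  d <- dim(m)
  p <- array(FALSE, d + 2L)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  face <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  total <- 0
  for (ax in 1:3) {
    o <- c(0L, 0L, 0L); o[ax] <- 1L
    s <- shift_array(p, o, FALSE)
    total <- total + sum(xor(p, s)) * face[ax]
  }
  total
}

# Triangulated iso-surface area. The binary mask is mildly smoothed (Gaussian,
# sigma = 0.9 * min spacing) so the 0.5 level set is a subvoxel-interpolated
# surface rather than the voxel staircase (whose area would not converge to
# the true area under grid refinement); triangles come from a Kuhn
# 6-tetrahedra decomposition of each grid cell with linear edge
# interpolation (marching tetrahedra).
mesh_area <- function(m, sp) {
  sigma_mm <- 0.9 * min(sp)
  sigma_vox <- sigma_mm / sp
  pad <- as.integer(ceiling(3 * max(sigma_vox)) + 2L)
  d <- dim(m)
  dp <- d + 2L * pad
  f <- array(0, dp)
  f[pad + (1:d[1]), pad + (1:d[2]), pad + (1:d[3])] <- as.numeric(m)
  f <- smooth_gaussian(f, sigma_vox)

  nc <- dp - 1L
  n_cells <- prod(nc)
  # corner k (1..8) offset bits along x/y/z
  off <- cbind(bitwAnd(0:7, 1L), bitwAnd(bitwShiftR(0:7, 1L), 1L),
               bitwAnd(bitwShiftR(0:7, 2L), 1L))
  # collect corner values of mixed cells only
  Vmin <- array(Inf, nc); Vmax <- array(-Inf, nc)
  for (k in 1:8) {
    sub <- f[(1:nc[1]) + off[k, 1], (1:nc[2]) + off[k, 2], (1:nc[3]) + off[k, 3]]
    Vmin <- pmin(Vmin, sub); Vmax <- pmax(Vmax, sub)
  }
  mixed <- which(Vmin < 0.5 & Vmax >= 0.5)
  if (length(mixed) == 0L) return(0)
  base <- arrayInd(mixed, nc)
  V <- matrix(0, length(mixed), 8L)
  for (k in 1:8) {
    lin <- (base[, 1] + off[k, 1]) +
      dp[1] * ((base[, 2] + off[k, 2] - 1L) +
                 dp[2] * (base[, 3] + off[k, 3] - 1L))
    V[, k] <- f[lin]
  }
  corners <- off * rep(sp, each = 8L)   # physical corner coords (mm)

  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  tets <- lapply(perms, function(pm) {
    a <- integer(3); a[pm[1]] <- 1L
    b <- a; b[pm[2]] <- 1L
    1L + c(0L, a[1] + 2L * a[2] + 4L * a[3], b[1] + 2L * b[2] + 4L * b[3], 7L)
  })
  tri_area_rows <- function(P1, P2, P3) {
    u <- P2 - P1; v <- P3 - P1
    cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
    cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
    cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
    0.5 * sqrt(cx^2 + cy^2 + cz^2)
  }
  total <- 0
  for (tet in tets) {
    Vq <- V[, tet, drop = FALSE]
    s <- Vq >= 0.5
    code <- s %*% c(1L, 2L, 4L, 8L)
    interp <- function(rows, i, j) {
      vi <- Vq[rows, i]; vj <- Vq[rows, j]
      t <- (0.5 - vi) / (vj - vi)
      ci <- corners[tet[i], ]; cj <- corners[tet[j], ]
      cbind(ci[1] + t * (cj[1] - ci[1]),
            ci[2] + t * (cj[2] - ci[2]),
            ci[3] + t * (cj[3] - ci[3]))
    }
    for (cd in 1:14) {
      rows <- which(code == cd)
      if (length(rows) == 0L) next
      ins <- which(bitwAnd(cd, c(1L, 2L, 4L, 8L)) > 0L)
      outs <- setdiff(1:4, ins)
      if (length(ins) == 1L || length(ins) == 3L) {
        apex <- if (length(ins) == 1L) ins else outs
        oth <- if (length(ins) == 1L) outs else ins
        total <- total + sum(tri_area_rows(interp(rows, apex, oth[1]),
                                           interp(rows, apex, oth[2]),
                                           interp(rows, apex, oth[3])))
      } else {
        P1 <- interp(rows, ins[1], outs[1])
        P2 <- interp(rows, ins[1], outs[2])
        P3 <- interp(rows, ins[2], outs[2])
        P4 <- interp(rows, ins[2], outs[1])
        total <- total + sum(tri_area_rows(P1, P2, P3)) +
          sum(tri_area_rows(P1, P3, P4))
      }
    }
  }
  total
}
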