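#' Configuration for the synthetic lesion phantom
#'
#' The phantom emulates a portal-phase CT sub-volume containing one
#' ellipsoidal lesion: a parenchyma background plus a spatially correlated
#' texture field (Gaussian white noise smoothed by a Gaussian kernel of
#' width \code{texture_corr_len_mm}, rescaled to unit SD) scaled by
#' \code{heterogeneity} (HU), plus independent voxel noise. The lesion
#' region is shifted to \code{tumor_hu}. The grid must be large enough that
#' the lesion plus a 5 mm rim fits strictly inside.
#'
#' @param grid_shape voxels per axis (length 3).
#' @param spacing_mm per-axis voxel size in mm, > 0.
#' @param background_hu parenchyma mean HU.
#' @param tumor_hu lesion mean HU.
#' @param noise_sd_hu SD of additive white voxel noise (HU), >= 0.
#' @param texture_corr_len_mm correlation length (Gaussian sigma, mm) of the
#'   texture field; 0 gives unsmoothed white texture.
#' @param heterogeneity texture amplitude in HU (SD of the correlated
#'   component), >= 0.
#' @param lesion_radii_mm ellipsoid semi-axes in mm (length 3).
#' @param seed integer RNG seed.
#' @return An object of class \code{phantom_config}.
#' @export
phantom_config <- function(grid_shape = c(48L, 48L, 48L),
                           spacing_mm = c(1, 1, 1),
                           background_hu = 70,
                           tumor_hu = 90,
                           noise_sd_hu = 8,
                           texture_corr_len_mm = 2,
                           heterogeneity = 10,
                           lesion_radii_mm = c(12, 10, 9),
                           seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              spacing_mm = as.numeric(spacing_mm),
              background_hu = background_hu, tumor_hu = tumor_hu,
              noise_sd_hu = noise_sd_hu,
              texture_corr_len_mm = texture_corr_len_mm,
              heterogeneity = heterogeneity,
              lesion_radii_mm = as.numeric(lesion_radii_mm),
              seed = as.integer(seed))
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 4L))
    stop("`grid_shape` must be 3 integers >= 4")
  if (length(cfg$spacing_mm) != 3L || any(cfg$spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive numbers")
  if (cfg$noise_sd_hu < 0) stop("`noise_sd_hu` must be >= 0")
  if (cfg$heterogeneity < 0) stop("`heterogeneity` must be >= 0")
  if (cfg$texture_corr_len_mm < 0) stop("`texture_corr_len_mm` must be >= 0")
  if (length(cfg$lesion_radii_mm) != 3L || any(cfg$lesion_radii_mm <= 0))
    stop("`lesion_radii_mm` must be 3 positive numbers")
  # lesion + 5 mm rim must fit strictly inside the grid
  half_extent <- (cfg$grid_shape - 1) / 2 * cfg$spacing_mm
  if (any(cfg$lesion_radii_mm + 5 >= half_extent))
    stop(sprintf(
      "lesion (radii %s mm) plus a 5 mm rim does not fit strictly inside the %s grid",
      paste(cfg$lesion_radii_mm, collapse = "/"),
      paste(cfg$grid_shape, collapse = "x")))
  structure(cfg, class = "phantom_config")
}

#' Generate a synthetic lesion-bearing volume and tumor mask
#'
#' @param config a \code{\link{phantom_config}}.
#' @return List with \code{volume} (an \code{image_volume}) and
#'   \code{tumor_mask} (logical array marking exactly the lesion voxels).
#'   Identical configs (including seed) give identical voxel arrays.
#' @export
make_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  d <- config$grid_shape
  sp <- config$spacing_mm
  # voxel-center coordinates relative to grid center, in mm
  ax <- lapply(1:3, function(a) ((seq_len(d[a]) - 1) - (d[a] - 1) / 2) * sp[a])
  r <- config$lesion_radii_mm
  q1 <- (ax[[1]] / r[1])^2
  q2 <- (ax[[2]] / r[2])^2
  q3 <- (ax[[3]] / r[3])^2
  quad <- outer(outer(q1, q2, `+`), q3, `+`)
  tumor <- quad <= 1
  if (!any(tumor)) stop("lesion radii smaller than voxel spacing: empty lesion")

  with_seed(config$seed, {
    tex <- if (config$heterogeneity > 0) {
      f <- array(stats::rnorm(prod(d)), d)
      f <- smooth_gaussian(f, config$texture_corr_len_mm / sp)
      s <- stats::sd(as.vector(f))
      if (s > 0) f <- f / s
      f * config$heterogeneity
    } else array(0, d)
    noise <- if (config$noise_sd_hu > 0)
      array(stats::rnorm(prod(d), sd = config$noise_sd_hu), d)
    else array(0, d)
    vals <- config$background_hu + tex + noise
    vals[tumor] <- config$tumor_hu + tex[tumor] + noise[tumor]
  })
  vol <- image_volume(vals, sp)
  # reject lesions whose 5 mm rim would leave the grid (dilate_mask errors)
  invisible(dilate_mask(tumor, 5, sp))
  list(volume = vol, tumor_mask = tumor)
}

# Separable Gaussian smoothing; sigma_vox per axis (0 = no smoothing).
smooth_gaussian <- function(a, sigma_vox) {
  d <- dim(a)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    half <- max(1L, min(ceiling(3 * s), d[axis] - 1L))
    k <- stats::dnorm(-half:half, sd = s)
    k <- k / sum(k)
    a <- apply_filter_axis(a, k, axis)
  }
  a
}

# Convolve along one axis with kernel k (reflected edge padding).
apply_filter_axis <- function(a, k, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  dm <- dim(ap)
  m <- matrix(ap, nrow = dm[1])
  half <- (length(k) - 1L) / 2L
  idx <- c(rev(seq_len(half) + 1L), seq_len(dm[1]), dm[1] - seq_len(half))
  mp <- m[idx, , drop = FALSE]
  out <- stats::filter(mp, k, sides = 2)
  out <- out[(half + 1L):(half + dm[1]), , drop = FALSE]
  res <- array(as.numeric(out), dm)
  aperm(res, order(perm))
}
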