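#' Dilate a binary mask by a physical radius
#'
#' Morphological dilation with a metric (anisotropy-aware) structuring
#' element: the output contains exactly the voxels whose center lies within
#' \code{radius_mm} (Euclidean distance in physical mm, using the per-axis
#' voxel spacing) of some voxel center in the input mask. The output is
#' always a superset of the input. Because the peritumoral rim must never be
#' silently truncated, dilation that would place voxels outside the image
#' grid is an error rather than a clipped result.
#'
#' @param mask logical (or 0/1) 3D array; must contain at least one voxel.
#' @param radius_mm dilation radius in millimetres, > 0.
#' @param spacing_mm per-axis voxel size in millimetres.
#' @return logical 3D array of the same shape.
#' @export
dilate_mask <- function(mask, radius_mm, spacing_mm) {
  m <- as_mask_array(mask)
  if (!any(m)) stop("mask is empty")
  if (!is.numeric(radius_mm) || length(radius_mm) != 1L || radius_mm <= 0)
    stop("`radius_mm` must be a single positive number")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive numbers")

  offs <- ball_offsets(radius_mm, spacing_mm)
  nm <- sum(m)
  out <- array(FALSE, dim(m))
  for (i in seq_len(nrow(offs))) {
    s <- shift_array(m, offs[i, ], FALSE)
    if (sum(s) < nm)
      stop(sprintf(
        "dilation by %g mm exceeds the %s grid: the expanded mask would be truncated",
        radius_mm, paste(dim(m), collapse = "x")))
    out <- out | s
  }
  out
}

# Integer offsets whose physical length is <= radius_mm.
ball_offsets <- function(radius_mm, spacing_mm) {
  r <- floor(radius_mm / spacing_mm)
  g <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  d2 <- (g$dx * spacing_mm[1])^2 + (g$dy * spacing_mm[2])^2 + (g$dz * spacing_mm[3])^2
  as.matrix(g[d2 <= radius_mm^2 + 1e-9, , drop = FALSE])
}

#' Build the peritumoral margin VOI
#'
#' Expands the tumor mask by \code{width_mm} (default 5 mm, measured in
#' physical distance between voxel centers) and subtracts the tumor, giving
#' the disjoint peritumoral rim. The margin is clipped only by the image
#' grid, never by an organ mask; a rim that would leave the grid raises an
#' error.
#'
#' @param tumor logical/0-1 3D tumor mask, nonempty.
#' @param volume the \code{image_volume} the mask lives on.
#' @param width_mm rim width in millimetres (default 5).
#' @return An object of class \code{voi_pair}: list with logical arrays
#'   \code{tumor} and \code{margin} (disjoint, same grid), plus
#'   \code{spacing_mm} and grid \code{dim}.
#' @export
make_margin <- function(tumor, volume, width_mm = 5) {
  stopifnot(inherits(volume, "image_volume"))
  tm <- as_mask_array(tumor)
  check_same_grid(volume, tm)
  dil <- dilate_mask(tm, width_mm, volume$spacing_mm)
  margin <- dil & !tm
  if (!any(margin)) stop("margin is empty after dilation")
  structure(list(tumor = tm, margin = margin,
                 spacing_mm = volume$spacing_mm, dim = dim(tm),
                 width_mm = width_mm),
            class = "voi_pair")
}

#' @exportS3Method
print.voi_pair <- function(x, ...) {
  cat(sprintf("<voi_pair> tumor %d voxels, %g mm margin %d voxels on %s grid\n",
              sum(x$tumor), x$width_mm, sum(x$margin),
              paste(x$dim, collapse = "x")))
  invisible(x)
}
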