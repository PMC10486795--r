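#' Construct an image volume
#'
#' A 3D scalar grid of CT attenuation values in Hounsfield units (HU) with
#' per-axis voxel spacing in millimetres. Arrays use R's native index order
#' \code{[x, y, z]} (first index fastest); this convention is used by every
#' function in the package. Masks are voxel-aligned with the grid: a voxel's
#' physical position is \code{origin_mm + (index - 1) * spacing_mm}.
#'
#' @param values 3D numeric array of HU values; all values must be finite.
#' @param spacing_mm numeric length-3, strictly positive voxel size in mm.
#' @param origin_mm numeric length-3 physical offset of voxel \code{[1,1,1]}.
#' @return An object of class \code{image_volume}: a list with elements
#'   \code{values}, \code{spacing_mm}, \code{origin_mm}.
#' @export
image_volume <- function(values, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (anyNA(values) || any(!is.finite(values)))
    stop("image volume contains non-finite values (NA/NaN/Inf are rejected)")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 strictly positive finite numbers")
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("`origin_mm` must be 3 finite numbers")
  structure(list(values = values, spacing_mm = spacing_mm, origin_mm = origin_mm),
            class = "image_volume")
}

#' @exportS3Method
print.image_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  cat(sprintf("  HU range [%.1f, %.1f], origin (%g, %g, %g) mm\n",
              min(x$values), max(x$values),
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3]))
  invisible(x)
}

# Coerce/validate a mask given either a logical/0-1 array or image_volume-like
as_mask_array <- function(mask) {
  if (inherits(mask, "image_volume")) mask <- mask$values
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3D array")
  if (anyNA(mask)) stop("mask contains missing values")
  if (!is_binary01(mask))
    stop("mask values must be strictly 0/1 (other values rejected)")
  array(as.logical(mask), dim(mask))
}

check_same_grid <- function(volume, mask) {
  dv <- dim(volume$values); dm <- dim(mask)
  if (!identical(as.integer(dv), as.integer(dm)))
    stop(sprintf("volume grid %s and mask grid %s do not match",
                 paste(dv, collapse = "x"), paste(dm, collapse = "x")))
  invisible(TRUE)
}

#' Read and write volumes and masks as NIfTI
#'
#' Lossless round-trip of voxel values, spacing and origin through
#' \code{.nii}/\code{.nii.gz} files. Masks are additionally constrained to
#' hold only 0/1 values; any other value is rejected on read and write.
#'
#' @param path file path ending in \code{.nii} or \code{.nii.gz}.
#' @param volume,mask an \code{image_volume} (for masks: with 0/1 values, or
#'   a logical array plus \code{spacing_mm}).
#' @param spacing_mm,origin_mm grid geometry used when \code{mask} is a bare
#'   array.
#' @return \code{read_volume}/\code{read_mask} return an
#'   \code{image_volume} (mask values are 0/1); the writers return the path
#'   invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  img <- RNifti::asNifti(volume$values)
  aff <- diag(4)
  aff[1, 1] <- volume$spacing_mm[1]
  aff[2, 2] <- volume$spacing_mm[2]
  aff[3, 3] <- volume$spacing_mm[3]
  aff[1:3, 4] <- volume$origin_mm
  RNifti::`qform<-`(img, structure(aff, code = 2L)) -> img
  RNifti::`pixdim<-`(img, volume$spacing_mm) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  if (length(dim(vals)) != 3L)
    stop("expected a 3D NIfTI volume, got ", length(dim(vals)), " dimensions")
  xf <- RNifti::xform(img)
  image_volume(array(as.numeric(vals), dim(vals)),
               spacing_mm = RNifti::pixdim(img)[1:3],
               origin_mm = xf[1:3, 4])
}

#' @rdname write_volume
#' @export
write_mask <- function(mask, path, spacing_mm = NULL, origin_mm = c(0, 0, 0)) {
  if (inherits(mask, "image_volume")) {
    m <- as_mask_array(mask)  # validates 0/1
    vol <- image_volume(array(as.integer(m), dim(m)), mask$spacing_mm, mask$origin_mm)
  } else {
    m <- as_mask_array(mask)
    if (is.null(spacing_mm)) stop("`spacing_mm` required for a bare mask array")
    vol <- image_volume(array(as.integer(m), dim(m)), spacing_mm, origin_mm)
  }
  write_volume(vol, path)
}

#' @rdname write_volume
#' @export
read_mask <- function(path) {
  vol <- read_volume(path)
  m <- as_mask_array(vol$values)  # rejects values outside {0,1}
  image_volume(array(as.integer(m), dim(m)), vol$spacing_mm, vol$origin_mm)
}
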