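#' Grey-level discretization scheme
#'
#' Texture matrices are computed on intensities discretized to integer grey
#' levels. Two IBSI-style modes are supported: a fixed number of bins over
#' the VOI's own min-max range (default, 64 bins; invariant to affine HU
#' rescaling of the VOI), or a fixed bin width over an absolute HU window
#' (comparable bin meaning across patients).
#'
#' @param mode \code{"fixed-bin-number"} or \code{"fixed-bin-size"}.
#' @param n_bins number of grey levels for fixed-bin-number mode (>= 2).
#' @param bin_width_hu bin width in HU for fixed-bin-size mode (> 0).
#' @param bounds optional \code{c(lower, upper)} absolute HU window. Required
#'   for fixed-bin-size mode; if given in fixed-bin-number mode it replaces
#'   the VOI min-max.
#' @return An object of class \code{discretization_scheme}.
#' @export
discretization_scheme <- function(mode = c("fixed-bin-number", "fixed-bin-size"),
                                  n_bins = 64L, bin_width_hu = NULL,
                                  bounds = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed-bin-number") {
    n_bins <- as.integer(n_bins)
    if (is.na(n_bins) || n_bins < 2L) stop("`n_bins` must be >= 2")
  } else {
    if (is.null(bin_width_hu) || bin_width_hu <= 0)
      stop("`bin_width_hu` must be a positive number in fixed-bin-size mode")
    if (is.null(bounds))
      stop("fixed-bin-size mode requires an absolute HU window in `bounds`")
  }
  if (!is.null(bounds)) {
    bounds <- as.numeric(bounds)
    if (length(bounds) != 2L || !(bounds[1] < bounds[2]))
      stop("`bounds` must be c(lower, upper) with lower < upper")
  }
  structure(list(mode = mode, n_bins = n_bins, bin_width_hu = bin_width_hu,
                 bounds = bounds),
            class = "discretization_scheme")
}

#' @exportS3Method
print.discretization_scheme <- function(x, ...) {
  if (x$mode == "fixed-bin-number")
    cat(sprintf("<discretization> %d bins over %s\n", x$n_bins,
                if (is.null(x$bounds)) "VOI min-max"
                else sprintf("[%g, %g] HU", x$bounds[1], x$bounds[2])))
  else
    cat(sprintf("<discretization> %g HU bins over [%g, %g] HU\n",
                x$bin_width_hu, x$bounds[1], x$bounds[2]))
  invisible(x)
}

# Discretize masked voxels to integer levels 1..L; 0 outside the mask.
# Returns list(levels = integer array, n_levels).
discretize_voi <- function(values, mask, scheme = discretization_scheme()) {
  stopifnot(inherits(scheme, "discretization_scheme"))
  v <- values[mask]
  if (length(v) == 0L) stop("mask is empty")
  if (scheme$mode == "fixed-bin-number") {
    b <- scheme$bounds %||% range(v)
    L <- scheme$n_bins
    if (b[2] <= b[1]) {          # constant VOI: single occupied level
      lev <- rep.int(1L, length(v))
    } else {
      lev <- pmin(pmax(floor((v - b[1]) / (b[2] - b[1]) * L) + 1L, 1L), L)
    }
  } else {
    b <- scheme$bounds
    L <- as.integer(ceiling((b[2] - b[1]) / scheme$bin_width_hu))
    lev <- pmin(pmax(floor((v - b[1]) / scheme$bin_width_hu) + 1L, 1L), L)
  }
  g <- array(0L, dim(mask))
  g[mask] <- as.integer(lev)
  list(levels = g, n_levels = as.integer(L))
}
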