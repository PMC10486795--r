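#' Names of the 45 retained radiomic indices
#'
#' The index panel the pipeline works with: 7 grey-level descriptors, 4
#' first-order histogram parameters, 3 shape indices, 6 GLCM, 11 GLRLM, 3
#' NGLDM and 11 GLZLM features (GLCM entropy is reported once, in log2;
#' LifeX-style double reporting of the same entropy in a second log base is
#' not counted as a separate index).
#'
#' @return Character vector of 45 bare (un-namespaced) feature names.
#' @export
radiomic_feature_names <- function() {
  c("HUmin", "HUmean", "HUstd", "HUmax", "HUQ1", "HUQ2", "HUQ3",
    "Skewness", "Kurtosis", "Histogram_Energy", "Histogram_Entropy",
    "Shape_Volume_mL", "Shape_Sphericity", "Shape_Compacity",
    paste0("GLCM_", c("Homogeneity", "Energy", "Contrast", "Correlation",
                      "Entropy", "Dissimilarity")),
    paste0("GLRLM_", c("SRE", "LRE", "LGRE", "HGRE", "SRLGE", "SRHGE",
                       "LRLGE", "LRHGE", "GLNU", "RLNU", "RP")),
    paste0("NGLDM_", c("Coarseness", "Contrast", "Busyness")),
    paste0("GLZLM_", c("SZE", "LZE", "LGZE", "HGZE", "SZLGE", "SZHGE",
                       "LZLGE", "LZHGE", "GLNUz", "ZLNU", "ZP")))
}

#' Extract the 45 radiomic indices for one VOI
#'
#' @param volume an \code{image_volume}.
#' @param mask logical/0-1 3D mask on the same grid.
#' @param scheme a \code{\link{discretization_scheme}}.
#' @param prefix optional namespace prepended as \code{<prefix>_<name>}
#'   (e.g. \code{"Portal_Tumor"}).
#' @return Named numeric vector of exactly 45 values (NA sentinel for
#'   indices undefined on the VOI; keys are never dropped).
#' @export
extract_features <- function(volume, mask, scheme = discretization_scheme(),
                             prefix = NULL) {
  stopifnot(inherits(volume, "image_volume"))
  m <- as_mask_array(mask)
  check_same_grid(volume, m)
  out <- c(grey_level_descriptors(volume, m),
           histogram_features(volume, m, scheme),
           shape_features(m, volume$spacing_mm),
           glcm_features(volume, m, scheme),
           glrlm_features(volume, m, scheme),
           ngldm_features(volume, m, scheme),
           glzlm_features(volume, m, scheme))
  stopifnot(identical(names(out), radiomic_feature_names()))
  if (!is.null(prefix)) names(out) <- paste0(prefix, "_", names(out))
  out
}

#' Extract tumor and margin feature vectors from a VOI pair
#'
#' Runs \code{\link{extract_features}} on the Tumor-VOI and the Margin-VOI
#' of a \code{\link{make_margin}} pair, namespacing keys as
#' \code{<Phase>_<VOI>_<Name>} (e.g. \code{Portal_Margin_GLZLM_ZLNU}).
#' Extraction is deterministic given its inputs and either returns the full
#' 90-value vector or fails; a partial vector is never returned.
#'
#' @param volume an \code{image_volume}.
#' @param pair a \code{voi_pair}.
#' @param scheme a \code{\link{discretization_scheme}}.
#' @param phase phase label used in the namespace (default \code{"Portal"}).
#' @return Named numeric vector of 90 values (45 per VOI).
#' @export
extract_all <- function(volume, pair, scheme = discretization_scheme(),
                        phase = "Portal") {
  stopifnot(inherits(pair, "voi_pair"))
  c(extract_features(volume, pair$tumor, scheme,
                     prefix = paste0(phase, "_Tumor")),
    extract_features(volume, pair$margin, scheme,
                     prefix = paste0(phase, "_Margin")))
}
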