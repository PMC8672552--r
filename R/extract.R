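REGISTRY <- local({
  hist <- c("mean", "variance", "skewness", "kurtosis", "median", "minimum",
            "maximum", "p10", "p90", "entropy", "uniformity")
  glcm <- c("joint_maximum", "joint_average", "joint_variance",
            "joint_entropy", "difference_average", "difference_variance",
            "difference_entropy", "sum_average", "sum_variance",
            "sum_entropy", "angular_second_moment", "contrast",
            "dissimilarity", "inverse_difference",
            "inverse_difference_normalized", "inverse_difference_moment",
            "inverse_difference_moment_normalized", "inverse_variance",
            "correlation", "autocorrelation", "cluster_tendency",
            "cluster_shade", "cluster_prominence",
            "information_correlation_1", "information_correlation_2")
  glrlm <- c("short_run_emphasis", "long_run_emphasis",
             "low_grey_level_run_emphasis", "high_grey_level_run_emphasis",
             "short_run_low_grey_level_emphasis",
             "short_run_high_grey_level_emphasis",
             "long_run_low_grey_level_emphasis",
             "long_run_high_grey_level_emphasis",
             "grey_level_non_uniformity",
             "grey_level_non_uniformity_normalized",
             "run_length_non_uniformity",
             "run_length_non_uniformity_normalized", "run_percentage",
             "grey_level_variance", "run_length_variance", "run_entropy")
  glszm <- c("small_zone_emphasis", "large_zone_emphasis",
             "low_grey_level_zone_emphasis", "high_grey_level_zone_emphasis",
             "small_zone_low_grey_level_emphasis",
             "small_zone_high_grey_level_emphasis",
             "large_zone_low_grey_level_emphasis",
             "large_zone_high_grey_level_emphasis",
             "grey_level_non_uniformity",
             "grey_level_non_uniformity_normalized",
             "zone_size_non_uniformity",
             "zone_size_non_uniformity_normalized", "zone_percentage",
             "grey_level_variance", "zone_size_variance", "zone_entropy")
  ngtdm <- c("coarseness", "contrast", "busyness", "complexity", "strength")
  data.frame(
    name = c(paste0("hist_", hist), paste0("glcm_", glcm),
             paste0("glrlm_", glrlm), paste0("glszm_", glszm),
             paste0("ngtdm_", ngtdm)),
    family = c(rep("histogram", length(hist)), rep("GLCM", length(glcm)),
               rep("GLRLM", length(glrlm)), rep("GLSZM", length(glszm)),
               rep("NGTDM", length(ngtdm))),
    stringsAsFactors = FALSE
  )
})

registryNames <- function(family) {
  REGISTRY$name[REGISTRY$family == family]
}

#' The 73-feature registry
#'
#' Canonical ordered list of the features this package extracts: 11
#' intensity-histogram features plus 62 texture features (25 GLCM, 16
#' GLRLM, 16 GLSZM, 5 NGTDM), with their family tags. All feature tables
#' and vectors produced by the package follow this order. A
#' machine-readable copy ships as
#' \code{system.file("extdata", "feature_registry.json", package =
#' "DeltaRadiomics")}.
#'
#' @return data.frame with columns \code{name} and \code{family}
#'   (\code{histogram, GLCM, GLRLM, GLSZM, NGTDM}), 73 rows.
#' @examples
#' table(featureRegistry()$family)
#' @export
featureRegistry <- function() REGISTRY

#' Extract the full 73-feature vector from a masked volume
#'
#' Composes [discretizeRoi()] with the five family extractors
#' ([histogramFeatures()], [glcmFeatures()], [glrlmFeatures()],
#' [glszmFeatures()], [ngtdmFeatures()]) into one named vector in
#' registry order. The vector always has 73 slots; a family that cannot
#' be computed (e.g. no valid voxel pairs) contributes \code{NA} values
#' with a warning rather than failing the extraction.
#'
#' @param volume an [ImageVolume-class] (typically kidney-median
#'   normalized; discretization is min–max based, so features are
#'   unaffected by any global rescaling of this volume).
#' @param mask a non-empty [ROIMask-class] (typically the GTV).
#' @param nBins intensity bins for discretization (default 64).
#' @return Named numeric vector of length 73 with attribute
#'   \code{family}.
#' @examples
#' v <- ImageVolume(array(runif(1000), c(10, 10, 10)))
#' m <- ROIMask(array(TRUE, c(10, 10, 10)))
#' fv <- extractFeatures(v, m)
#' length(fv)
#' @export
extractFeatures <- function(volume, mask, nBins = 64) {
  d <- discretizeRoi(volume, mask, nBins = nBins)
  out <- c(
    histogramFeatures(d),
    glcmFeatures(buildGlcm(d)),
    glrlmFeatures(buildGlrlm(d)),
    glszmFeatures(buildGlszm(d)),
    ngtdmFeatures(buildNgtdm(d))
  )
  stopifnot(identical(names(out), REGISTRY$name))
  attr(out, "family") <- REGISTRY$family
  out
}
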