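#' Intensity-histogram features of a discretized ROI
#'
#' The 11 first-order features computed on the 64-level bin labels
#' (discretized intensities), following the standardized
#' intensity-histogram definitions: mean, variance, skewness, excess
#' kurtosis, median, minimum, maximum, 10th and 90th percentiles, entropy
#' and uniformity. Moments are population (1/n) moments; entropy is in
#' bits (log2) over occupied-bin probabilities; uniformity is the sum of
#' squared bin probabilities. Percentiles use the nearest-rank convention
#' (the \eqn{\lceil p n \rceil}-th order statistic). A zero-variance ROI
#' gets skewness 0, excess kurtosis 0 by convention.
#'
#' Skewness — the third standardized moment, the asymmetry of the ROI
#' intensity distribution — is the feature whose treatment-induced change
#' carries the outcome signal in this pipeline.
#'
#' @param d a \code{DiscretizedROI} from [discretizeRoi()].
#' @return Named numeric vector of 11 features (names prefixed
#'   \code{hist_}).
#' @examples
#' v <- ImageVolume(array(runif(512), c(8, 8, 8)))
#' m <- ROIMask(array(TRUE, c(8, 8, 8)))
#' histogramFeatures(discretizeRoi(v, m))["hist_skewness"]
#' @export
histogramFeatures <- function(d) {
  x <- as.numeric(d$labels[!is.na(d$labels)])
  n <- length(x)
  mu <- mean(x)
  m2 <- popMoment(x, 2)
  if (m2 > 0) {
    skew <- popMoment(x, 3) / m2^1.5
    kurt <- popMoment(x, 4) / m2^2 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  tab <- tabulate(as.integer(x), nbins = d$nBins)
  p <- tab[tab > 0] / n
  nearestRank <- function(q) sort(x, partial = ceiling(q * n))[ceiling(q * n)]
  c(hist_mean = mu,
    hist_variance = m2,
    hist_skewness = skew,
    hist_kurtosis = kurt,
    hist_median = median(x),
    hist_minimum = min(x),
    hist_maximum = max(x),
    hist_p10 = nearestRank(0.10),
    hist_p90 = nearestRank(0.90),
    hist_entropy = -sum(p * log2(p)),
    hist_uniformity = sum(p^2))
}
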