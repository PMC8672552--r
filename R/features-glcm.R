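#' Grey-level co-occurrence matrix and its 25 features
#'
#' \code{buildGlcm} counts label pairs over the 13 unique 3D direction
#' offsets at Chebyshev distance 1 (voxel units, no distance weighting),
#' symmetrizes, merges directions by summation, and normalizes to a joint
#' probability matrix. \code{glcmFeatures} computes the 25 standardized
#' co-occurrence features on that matrix. The maximal correlation
#' coefficient is deliberately excluded (numerically fragile), landing on
#' the canonical 25-feature co-occurrence list.
#'
#' Conventions for degenerate inputs: a single-label ROI gives a point
#' mass, for which contrast = 0, angular second moment = 1 and
#' correlation = 1; a ROI with no valid voxel pair (isolated voxel)
#' yields all-\code{NA} features with a warning.
#'
#' @param d a \code{DiscretizedROI} from [discretizeRoi()].
#' @param P a normalized symmetric co-occurrence matrix from
#'   \code{buildGlcm}.
#' @return \code{buildGlcm}: \code{nBins x nBins} matrix with entries
#'   summing to 1 (all zero if no pairs). \code{glcmFeatures}: named
#'   numeric vector of 25 features (prefix \code{glcm_}).
#' @examples
#' v <- ImageVolume(array(runif(64), c(4, 4, 4)))
#' m <- ROIMask(array(TRUE, c(4, 4, 4)))
#' P <- buildGlcm(discretizeRoi(v, m, nBins = 8))
#' glcmFeatures(P)["glcm_contrast"]
#' @export
buildGlcm <- function(d) {
  lab <- d$labels
  n <- d$nBins
  dims <- dim(lab)
  counts <- matrix(0, n, n)
  for (k in seq_len(nrow(DIRS13))) {
    pr <- shiftPairs(dims, DIRS13[k, ])
    if (is.null(pr)) next
    a <- lab[pr$src]; b <- lab[pr$dst]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    a <- a[ok]; b <- b[ok]
    # ordered pairs in both orders == symmetrization
    tab <- tabulate((a - 1L) * n + b, nbins = n * n) +
           tabulate((b - 1L) * n + a, nbins = n * n)
    counts <- counts + matrix(tab, n, n, byrow = TRUE)
  }
  tot <- sum(counts)
  if (tot > 0) counts / tot else counts
}

#' @rdname buildGlcm
#' @export
glcmFeatures <- function(P) {
  n <- nrow(P)
  nms <- registryNames("GLCM")
  if (sum(P) == 0) {
    warning("no valid voxel pairs; GLCM features set to NA")
    return(setNames(rep(NA_real_, length(nms)), nms))
  }
  I <- row(P); J <- col(P)
  nz <- P > 0
  p <- P[nz]; i <- I[nz]; j <- J[nz]

  px <- rowSums(P)                      # marginal (symmetric: px == py)
  mu <- sum(seq_len(n) * px)
  sig2 <- sum((seq_len(n) - mu)^2 * px)

  dk <- abs(i - j)
  pd <- vapply(0:(n - 1), function(k) sum(p[dk == k]), numeric(1))
  kd <- 0:(n - 1)
  da <- sum(kd * pd)

  sk <- i + j
  ps <- vapply(2:(2 * n), function(k) sum(p[sk == k]), numeric(1))
  ks <- 2:(2 * n)
  sa <- sum(ks * ps)

  hxy <- -sum(p * log2(p))
  pxnz <- px[px > 0]
  hx <- -sum(pxnz * log2(pxnz))
  hxy1 <- -sum(p * log2(px[i] * px[j]))
  ppij <- outer(px, px)
  occ <- ppij > 0
  hxy2 <- -sum(ppij[occ] * log2(ppij[occ]))

  corr <- if (sig2 > 0) sum((i - mu) * (j - mu) * p) / sig2 else 1
  ic1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  ic2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))

  offd <- dk > 0
  vals <- c(
    max(p),                                     # joint maximum
    mu,                                         # joint average
    sum((i - mu)^2 * p),                        # joint variance
    hxy,                                        # joint entropy
    da,                                         # difference average
    sum((kd - da)^2 * pd),                      # difference variance
    -sum(pd[pd > 0] * log2(pd[pd > 0])),        # difference entropy
    sa,                                         # sum average
    sum((ks - sa)^2 * ps),                      # sum variance
    -sum(ps[ps > 0] * log2(ps[ps > 0])),        # sum entropy
    sum(p^2),                                   # angular second moment
    sum((i - j)^2 * p),                         # contrast
    sum(dk * p),                                # dissimilarity
    sum(p / (1 + dk)),                          # inverse difference
    sum(p / (1 + dk / n)),                      # inverse difference normalized
    sum(p / (1 + (i - j)^2)),                   # inverse difference moment
    sum(p / (1 + ((i - j) / n)^2)),             # idm normalized
    sum(p[offd] / dk[offd]^2),                  # inverse variance
    corr,                                       # correlation
    sum(i * j * p),                             # autocorrelation
    sum((i + j - 2 * mu)^2 * p),                # cluster tendency
    sum((i + j - 2 * mu)^3 * p),                # cluster shade
    sum((i + j - 2 * mu)^4 * p),                # cluster prominence
    ic1,                                        # information correlation 1
    ic2                                         # information correlation 2
  )
  setNames(vals, nms)
}
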