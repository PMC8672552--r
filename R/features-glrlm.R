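#' Grey-level run-length matrix and its 16 features
#'
#' \code{buildGlrlm} finds runs of consecutive equal labels along each of
#' the 13 unique 3D grid directions and merges all runs into one
#' level-by-length count matrix (merged aggregation). Voxels outside the
#' ROI break runs. \code{glrlmFeatures} computes the 16 standardized
#' run-length features. Because runs are pooled over 13 directions, run
#' percentage uses \eqn{13 N_v} as its denominator, so an ROI in which
#' every run has length 1 yields run percentage exactly 1.
#'
#' @param d a \code{DiscretizedROI} from [discretizeRoi()].
#' @param R a run-length count matrix from \code{buildGlrlm} (attribute
#'   \code{nVoxels} carries the ROI size).
#' @return \code{buildGlrlm}: \code{nBins x maxRunLength} integer count
#'   matrix. \code{glrlmFeatures}: named numeric vector of 16 features
#'   (prefix \code{glrlm_}).
#' @examples
#' v <- ImageVolume(array(runif(64), c(4, 4, 4)))
#' m <- ROIMask(array(TRUE, c(4, 4, 4)))
#' R <- buildGlrlm(discretizeRoi(v, m, nBins = 4))
#' glrlmFeatures(R)["glrlm_run_percentage"]
#' @export
buildGlrlm <- function(d) {
  lab <- d$labels
  dims <- dim(lab)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  cells <- expand.grid(x = seq_len(nx), y = seq_len(ny), z = seq_len(nz))
  labv <- as.integer(lab)

  levels <- integer(0); lengths <- integer(0)
  for (k in seq_len(nrow(DIRS13))) {
    off <- DIRS13[k, ]
    # parametrize each lattice line in direction `off` by t, the (signed)
    # coordinate along the first axis the direction moves in
    a <- which(off != 0)[1]
    t <- cells[[a]] * sign(off[a])
    k1 <- cells$x - t * off[1]
    k2 <- cells$y - t * off[2]
    k3 <- cells$z - t * off[3]
    key <- (k1 + nx) + (k2 + ny) * (3 * nx + 1) +
           (k3 + nz) * (3 * nx + 1) * (3 * ny + 1)
    ord <- order(key, t)
    x <- labv[ord]
    g <- key[ord]
    N <- length(x)
    sameAsPrev <- c(FALSE,
                    g[-1] == g[-N] & !is.na(x[-1]) & !is.na(x[-N]) &
                    x[-1] == x[-N])
    runStart <- !is.na(x) & !sameAsPrev
    runId <- cumsum(runStart)
    inRoi <- !is.na(x)
    lengths <- c(lengths, tabulate(runId[inRoi], nbins = max(runId)))
    levels <- c(levels, x[runStart])
  }
  maxRun <- max(lengths)
  R <- matrix(0L, d$nBins, maxRun)
  tab <- tabulate((levels - 1L) * maxRun + lengths, nbins = d$nBins * maxRun)
  R <- matrix(tab, d$nBins, maxRun, byrow = TRUE)
  attr(R, "nVoxels") <- d$nVoxels
  R
}

#' @rdname buildGlrlm
#' @export
glrlmFeatures <- function(R) {
  nms <- registryNames("GLRLM")
  Nv <- attr(R, "nVoxels")
  Ns <- sum(R)
  i <- seq_len(nrow(R)); j <- seq_len(ncol(R))
  ri <- rowSums(R); rj <- colSums(R)
  p <- R / Ns
  mui <- sum(i * rowSums(p))
  muj <- sum(j * colSums(p))
  pij <- p
  II <- matrix(i, nrow(R), ncol(R))
  JJ <- matrix(j, nrow(R), ncol(R), byrow = TRUE)
  vals <- c(
    sum(rj / j^2) / Ns,                       # short run emphasis
    sum(rj * j^2) / Ns,                       # long run emphasis
    sum(ri / i^2) / Ns,                       # low grey level run emphasis
    sum(ri * i^2) / Ns,                       # high grey level run emphasis
    sum(pij / (II^2 * JJ^2)),                 # short run low grey level
    sum(pij * II^2 / JJ^2),                   # short run high grey level
    sum(pij * JJ^2 / II^2),                   # long run low grey level
    sum(pij * II^2 * JJ^2),                   # long run high grey level
    sum(ri^2) / Ns,                           # grey level non-uniformity
    sum(ri^2) / Ns^2,                         # gln normalized
    sum(rj^2) / Ns,                           # run length non-uniformity
    sum(rj^2) / Ns^2,                         # rln normalized
    Ns / (Nv * nrow(DIRS13)),                 # run percentage
    sum((II - mui)^2 * pij),                  # grey level variance
    sum((JJ - muj)^2 * pij),                  # run length variance
    -sum(pij[pij > 0] * log2(pij[pij > 0]))   # run entropy
  )
  setNames(vals, nms)
}
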