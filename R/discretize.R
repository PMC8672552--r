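#' Fixed-bin-number intensity discretization of a masked ROI
#'
#' Maps ROI voxel intensities onto \code{nBins} equal-width bins spanning
#' the ROI's own \eqn{[\min, \max]} range:
#' \deqn{label = \min(n, \lfloor n (x - \min)/(\max - \min) \rfloor + 1).}
#' Because the grid is re-anchored to the ROI range, every downstream
#' feature is invariant to monotone affine rescaling of the raw signal
#' (\eqn{x \to a x + b, a > 0}) — the property that makes texture features
#' comparable across scans with arbitrary MR signal scaling. A
#' constant-intensity ROI maps to label 1 everywhere by convention.
#'
#' @param volume an [ImageVolume-class].
#' @param mask an [ROIMask-class] on the same grid.
#' @param nBins number of intensity bins (>= 2); default 64, the bin count
#'   fixed for all histogram and texture quantification in this pipeline.
#' @return A \code{DiscretizedROI}: list with \code{labels} (integer 3D
#'   array cropped to the mask bounding box, \code{NA} outside the ROI),
#'   \code{nBins}, \code{binEdges} (length \code{nBins + 1}), and
#'   \code{nVoxels}.
#' @examples
#' v <- ImageVolume(array(runif(128), c(8, 4, 4)))
#' m <- ROIMask(array(TRUE, c(8, 4, 4)))
#' d <- discretizeRoi(v, m, nBins = 8)
#' range(d$labels, na.rm = TRUE)
#' @export
discretizeRoi <- function(volume, mask, nBins = 64) {
  stopifnot(is(volume, "ImageVolume"), is(mask, "ROIMask"))
  if (!identical(dim(volume@voxels), dim(mask@voxels)))
    stop("mask and volume grids differ")
  if (nBins < 2) stop("nBins must be >= 2")
  if (!any(mask@voxels)) stop("empty mask")
  nBins <- as.integer(nBins)

  bb <- maskBoundingBox(mask@voxels)
  vox <- volume@voxels[bb$x, bb$y, bb$z, drop = FALSE]
  msk <- mask@voxels[bb$x, bb$y, bb$z, drop = FALSE]

  xs <- vox[msk]
  lo <- min(xs); hi <- max(xs)
  labels <- array(NA_integer_, dim(vox))
  if (hi > lo) {
    lab <- floor(nBins * (xs - lo) / (hi - lo)) + 1L
    lab[lab > nBins] <- nBins
    labels[msk] <- as.integer(lab)
    edges <- seq(lo, hi, length.out = nBins + 1L)
  } else {
    labels[msk] <- 1L
    edges <- seq(lo, lo + 1, length.out = nBins + 1L)
  }
  structure(list(labels = labels, nBins = nBins, binEdges = edges,
                 nVoxels = length(xs)),
            class = "DiscretizedROI")
}

maskBoundingBox <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  list(x = min(idx[, 1]):max(idx[, 1]),
       y = min(idx[, 2]):max(idx[, 2]),
       z = min(idx[, 3]):max(idx[, 3]))
}

# The 13 unique 3D direction offsets at Chebyshev distance 1 (half of the
# 26-neighborhood; the other half are their negatives). Offsets are in
# voxel units with no distance weighting: images are used as acquired,
# without spatial interpolation.
thirteenDirections <- function() DIRS13

DIRS13 <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
DIRS13 <- local({
  d <- DIRS13[!(DIRS13[, 1] == 0 & DIRS13[, 2] == 0 & DIRS13[, 3] == 0), ,
              drop = FALSE]
  keep <- apply(d, 1, function(o) o[o != 0][1] > 0)
  unname(d[keep, , drop = FALSE])
})

# Aligned views of an integer label array under an offset: returns the
# linear indices of (source, neighbor) cell pairs fully inside the grid.
shiftPairs <- function(dims, off) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  rng <- function(n, o) {
    lo <- max(1, 1 - o); hi <- min(n, n - o)
    if (lo > hi) integer(0) else lo:hi
  }
  xr <- rng(nx, off[1]); yr <- rng(ny, off[2]); zr <- rng(nz, off[3])
  if (!length(xr) || !length(yr) || !length(zr))
    return(NULL)
  src <- as.vector(outer(outer(xr, (yr - 1) * nx, "+"),
                         (zr - 1) * nx * ny, "+"))
  dst <- src + off[1] + off[2] * nx + off[3] * nx * ny
  list(src = src, dst = dst)
}
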