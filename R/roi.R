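#' Select the three kidney slices used for normalization
#'
#' The kidney reference signal is read from three equally spaced axial
#' slices through the kidney: at 1/4, 1/2 and 3/4 of the kidney's slice
#' extent. With the kidney spanning slices \eqn{[first, last]}, the
#' selected slices are \eqn{first + round((last - first) q)} for
#' \eqn{q \in \{0.25, 0.5, 0.75\}}, rounding half away from zero. A
#' kidney confined to a single slice returns that slice three times.
#'
#' @param kidneyMask a non-empty kidney [ROIMask-class].
#' @return Integer vector of 3 slice indices (1-based, non-decreasing).
#' @examples
#' m <- array(FALSE, c(4, 4, 100))
#' m[2, 2, 63:97] <- TRUE   # kidney in 1-based slices 63..97
#' selectKidneySlices(ROIMask(m, "kidney"))
#' @export
selectKidneySlices <- function(kidneyMask) {
  stopifnot(is(kidneyMask, "ROIMask"))
  present <- which(apply(kidneyMask@voxels, 3, any))
  if (!length(present)) stop("empty kidney mask")
  first <- min(present); last <- max(present)
  as.integer(first + roundHalfUp((last - first) * c(0.25, 0.5, 0.75)))
}

#' Automatic abdomen cross-section ROI
#'
#' Builds the abdomen region used to quantify global (technical) signal
#' drift: within the 10 axial slices centered on the GTV's median slice,
#' the body cross-section is segmented by Otsu thresholding, reduced to
#' the largest connected foreground component, holes are filled per
#' slice, and all GTV voxels are removed. If the volume has fewer than 10
#' slices, all slices are used with a warning.
#'
#' The thresholding recipe (Otsu + largest component + 2D hole fill) is
#' this package's parameter-free choice for body/background contrast; see
#' the methods vignette.
#'
#' @param volume an [ImageVolume-class].
#' @param gtvMask the GTV [ROIMask-class] on the same grid.
#' @return An [ROIMask-class] with role \code{abdomen} (possibly empty —
#'   a warning is issued and downstream medians propagate as missing).
#' @export
abdomenAutoRoi <- function(volume, gtvMask) {
  stopifnot(is(volume, "ImageVolume"), is(gtvMask, "ROIMask"))
  if (!identical(dim(volume@voxels), dim(gtvMask@voxels)))
    stop("mask and volume grids differ")
  dims <- dim(volume@voxels)
  nz <- dims[3]

  gtvSlices <- which(gtvMask@voxels, arr.ind = TRUE)[, 3]
  midSlice <- lowerMedian(gtvSlices)
  if (nz < 10) {
    warning("volume has fewer than 10 slices; using all slices")
    zr <- seq_len(nz)
  } else {
    z0 <- midSlice - 4L
    z0 <- max(1L, min(z0, nz - 9L))
    zr <- z0:(z0 + 9L)
  }

  sub <- volume@voxels[, , zr, drop = FALSE]
  thr <- otsuThreshold(as.vector(sub))
  fg <- sub > thr
  if (any(fg)) {
    comp <- connectedComponents3d(array(ifelse(fg, 1L, NA_integer_),
                                        dim(fg)), connectivity = 6)
    ids <- comp[!is.na(comp)]
    largest <- as.integer(names(which.max(table(ids))))
    fg <- !is.na(comp) & comp == largest
    for (k in seq_len(dim(fg)[3]))
      fg[, , k] <- fillHoles2d(fg[, , k])
  }
  out <- array(FALSE, dims)
  out[, , zr] <- fg
  out[gtvMask@voxels] <- FALSE
  if (!any(out)) warning("abdomen auto-ROI is empty")
  new("ROIMask", voxels = out, role = "abdomen",
      patientId = gtvMask@patientId)
}

#' Perturb a GTV mask by per-slice radial erosion or dilation
#'
#' Simulates slight differences in tumor delineation: each axial slice of
#' the mask is eroded or dilated with a disk structuring element whose
#' radius is \code{radialDeltaMm} expressed in pixels
#' (\code{round(radialDeltaMm / dx)}). At the native 1.5 mm in-plane
#' spacing the default 1.5 mm radius is one pixel and the disk
#' degenerates to the 4-connected cross. Morphology is strictly 2D: the
#' slice extent of the ROI never changes under erosion, and dilation
#' never leaks into neighbouring slices.
#'
#' @param gtvMask a non-empty [ROIMask-class].
#' @param spacing voxel spacing (dx, dy, dz) in mm.
#' @param mode \code{"erode"}, \code{"dilate"}, \code{"identity"}, or
#'   \code{"translate"} (an optional alternative perturbation: in-plane
#'   shift of every slice by \code{radialDeltaMm} in x and y).
#' @param radialDeltaMm radial perturbation in mm (default 1.5).
#' @return The perturbed [ROIMask-class]; \code{identity} returns the
#'   input unchanged.
#' @examples
#' m <- array(FALSE, c(12, 12, 1)); m[2:11, 2:11, 1] <- TRUE
#' sum(voxels(perturbRoi(ROIMask(m), mode = "erode")))  # 8 x 8
#' @export
perturbRoi <- function(gtvMask, spacing = c(1.5, 1.5, 3),
                       mode = c("erode", "dilate", "identity", "translate"),
                       radialDeltaMm = 1.5) {
  stopifnot(is(gtvMask, "ROIMask"))
  mode <- match.arg(mode)
  if (!any(gtvMask@voxels)) stop("empty mask")
  if (mode == "identity") return(gtvMask)
  if (radialDeltaMm <= 0) stop("radialDeltaMm must be > 0")
  radiusPx <- max(1L, as.integer(roundHalfUp(radialDeltaMm / spacing[1])))
  se <- diskOffsets(radiusPx)
  m <- gtvMask@voxels
  out <- array(FALSE, dim(m))
  for (k in seq_len(dim(m)[3])) {
    sl <- m[, , k]
    if (!any(sl)) next
    out[, , k] <- switch(mode,
      erode = erode2d(sl, se),
      dilate = dilate2d(sl, se),
      translate = shift2d(sl, radiusPx, radiusPx, FALSE))
  }
  if (mode == "erode" && !any(out))
    stop("ROI vanished under perturbation")
  new("ROIMask", voxels = out, role = gtvMask@role,
      patientId = gtvMask@patientId)
}

# ---- internal morphology / segmentation primitives ----

# offsets of a disk structuring element of integer radius r (includes
# center); r = 1 gives the 4-connected cross
diskOffsets <- function(r) {
  g <- expand.grid(dx = -r:r, dy = -r:r)
  as.matrix(g[g$dx^2 + g$dy^2 <= r^2, ])
}

shift2d <- function(m, dx, dy, fill) {
  out <- matrix(fill, nrow(m), ncol(m))
  xs <- seq_len(nrow(m)); ys <- seq_len(ncol(m))
  sx <- xs - dx; sy <- ys - dy
  okx <- sx >= 1 & sx <= nrow(m); oky <- sy >= 1 & sy <= ncol(m)
  out[xs[okx], ys[oky]] <- m[sx[okx], sy[oky]]
  out
}

# binary erosion: AND of shifts (outside-grid treated as background)
erode2d <- function(m, se) {
  out <- matrix(TRUE, nrow(m), ncol(m))
  for (i in seq_len(nrow(se)))
    out <- out & shift2d(m, -se[i, 1], -se[i, 2], FALSE)
  out
}

# binary dilation: OR of shifts
dilate2d <- function(m, se) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_len(nrow(se)))
    out <- out | shift2d(m, se[i, 1], se[i, 2], FALSE)
  out
}

# fill background regions not connected (4-conn) to the slice border
fillHoles2d <- function(m) {
  bg <- !m
  reach <- matrix(FALSE, nrow(m), ncol(m))
  reach[1, ] <- bg[1, ]; reach[nrow(m), ] <- bg[nrow(m), ]
  reach[, 1] <- reach[, 1] | bg[, 1]
  reach[, ncol(m)] <- reach[, ncol(m)] | bg[, ncol(m)]
  se <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  repeat {
    grown <- dilate2d(reach, se) & bg
    if (all(grown == reach)) break
    reach <- grown
  }
  m | (bg & !reach)
}

# histogram-based Otsu threshold (maximizes between-class variance)
otsuThreshold <- function(x, nbins = 256) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(nbins, floor(nbins * (x - rng[1]) / diff(rng)) + 1L),
                nbins = nbins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nbins) - 0.5) * diff(rng) / nbins
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[nbins]
  sigmaB <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  sigmaB[!is.finite(sigmaB)] <- 0
  mids[which.max(sigmaB)]
}

# lower median: for even counts, the lower of the two central values
lowerMedian <- function(x) {
  s <- sort(x)
  s[ceiling(length(s) / 2)]
}
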