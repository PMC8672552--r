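#' Rasterize planar closed polygons into a binary mask
#'
#' Converts per-slice contour polygons (physical in-plane coordinates,
#' mm) into an [ROIMask-class] on the grid of a reference volume. A voxel
#' is foreground iff its in-plane center lies inside the polygon of its
#' slice under the even-odd rule. Voxel centers follow the package's
#' coordinate convention: the center of voxel \code{[i, j]} (1-based R
#' indices) is at \code{((i - 1) dx, (j - 1) dy)}, i.e. physical position
#' \code{index * spacing} with 0-based indices, matching common DICOM
#' patient-coordinate practice.
#'
#' Multiple polygons on one slice combine by even-odd parity, so a
#' contour inside another carves a hole.
#'
#' @param contours list of polygons; each a list with \code{slice}
#'   (1-based slice index), \code{x}, \code{y} (vertex coordinates in
#'   mm; the polygon is closed implicitly).
#' @param ref the reference [ImageVolume-class].
#' @param role role tag for the resulting mask.
#' @return An [ROIMask-class] with the reference grid shape.
#' @examples
#' ref <- ImageVolume(array(0, c(8, 8, 2)))
#' sq <- list(slice = 1, x = c(0.75, 6.75, 6.75, 0.75),
#'            y = c(0.75, 0.75, 6.75, 6.75))
#' sum(voxels(rasterizeContours(list(sq), ref)))  # 4 x 4 voxel centers
#' @export
rasterizeContours <- function(contours, ref, role = "GTV") {
  stopifnot(is(ref, "ImageVolume"))
  dims <- dim(ref@voxels)
  sp <- ref@spacing
  out <- array(FALSE, dims)
  for (pg in contours) {
    if (length(pg$x) < 3 || length(pg$x) != length(pg$y))
      stop("degenerate polygon: need >= 3 vertices")
    s <- as.integer(pg$slice)
    if (s < 1 || s > dims[3])
      stop("polygon slice ", s, " outside the grid")
    cx <- (seq_len(dims[1]) - 1) * sp[1]
    cy <- (seq_len(dims[2]) - 1) * sp[2]
    pts <- expand.grid(x = cx, y = cy)
    inside <- pointInPolygonEvenOdd(pts$x, pts$y, pg$x, pg$y)
    out[, , s] <- xor(out[, , s], matrix(inside, dims[1], dims[2]))
  }
  new("ROIMask", voxels = out, role = role, patientId = ref@patientId)
}

# even-odd (crossing number) test, vectorized over query points
pointInPolygonEvenOdd <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py))
    if (any(crosses)) {
      xint <- vx[i] + (py - vy[i]) * (vx[j] - vx[i]) / (vy[j] - vy[i])
      flip <- crosses & (px < xint)
      inside <- xor(inside, flip)
    }
    j <- i
  }
  inside
}
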