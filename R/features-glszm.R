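#' Grey-level size-zone matrix and its 16 features
#'
#' \code{buildGlszm} groups ROI voxels into zones — 26-connected 3D
#' components of equal label — and tabulates them by level and zone size.
#' Unlike run-length analysis, zones are direction-free, so a single
#' matrix is produced and zone percentage is the zone count over the ROI
#' voxel count. \code{glszmFeatures} computes the 16 standardized
#' size-zone features.
#'
#' @param d a \code{DiscretizedROI} from [discretizeRoi()].
#' @param Z a zone count matrix from \code{buildGlszm} (attribute
#'   \code{nVoxels} carries ROI size).
#' @return \code{buildGlszm}: \code{nBins x maxZoneSize} count matrix.
#'   \code{glszmFeatures}: named numeric vector of 16 features (prefix
#'   \code{glszm_}).
#' @examples
#' v <- ImageVolume(array(runif(64), c(4, 4, 4)))
#' m <- ROIMask(array(TRUE, c(4, 4, 4)))
#' Z <- buildGlszm(discretizeRoi(v, m, nBins = 4))
#' glszmFeatures(Z)["glszm_zone_percentage"]
#' @export
buildGlszm <- function(d) {
  lab <- d$labels
  comp <- connectedComponents3d(lab, connectivity = 26)
  ids <- comp[!is.na(comp)]
  lv <- lab[!is.na(lab)]
  sizes <- tapply(rep(1L, length(ids)), ids, sum)
  levelOf <- tapply(lv, ids, function(v) v[1])
  maxZone <- max(sizes)
  tab <- tabulate((as.integer(levelOf) - 1L) * maxZone + as.integer(sizes),
                  nbins = d$nBins * maxZone)
  Z <- matrix(tab, d$nBins, maxZone, byrow = TRUE)
  attr(Z, "nVoxels") <- d$nVoxels
  Z
}

#' @rdname buildGlszm
#' @export
glszmFeatures <- function(Z) {
  nms <- registryNames("GLSZM")
  Nv <- attr(Z, "nVoxels")
  Ns <- sum(Z)
  i <- seq_len(nrow(Z)); j <- seq_len(ncol(Z))
  si <- rowSums(Z); sj <- colSums(Z)
  p <- Z / Ns
  mui <- sum(i * rowSums(p))
  muj <- sum(j * colSums(p))
  II <- matrix(i, nrow(Z), ncol(Z))
  JJ <- matrix(j, nrow(Z), ncol(Z), byrow = TRUE)
  vals <- c(
    sum(sj / j^2) / Ns,                       # small zone emphasis
    sum(sj * j^2) / Ns,                       # large zone emphasis
    sum(si / i^2) / Ns,                       # low grey level zone emphasis
    sum(si * i^2) / Ns,                       # high grey level zone emphasis
    sum(p / (II^2 * JJ^2)),                   # small zone low grey level
    sum(p * II^2 / JJ^2),                     # small zone high grey level
    sum(p * JJ^2 / II^2),                     # large zone low grey level
    sum(p * II^2 * JJ^2),                     # large zone high grey level
    sum(si^2) / Ns,                           # grey level non-uniformity
    sum(si^2) / Ns^2,                         # gln normalized
    sum(sj^2) / Ns,                           # zone size non-uniformity
    sum(sj^2) / Ns^2,                         # zsn normalized
    Ns / Nv,                                  # zone percentage
    sum((II - mui)^2 * p),                    # grey level variance
    sum((JJ - muj)^2 * p),                    # zone size variance
    -sum(p[p > 0] * log2(p[p > 0]))           # zone entropy
  )
  setNames(vals, nms)
}

# 26- or 6-connected component labeling of equal-valued cells in an
# integer 3D array (NA = background). Vectorized label propagation with
# pointer jumping; returns an array of component ids (NA outside).
connectedComponents3d <- function(lab, connectivity = 26) {
  dims <- dim(lab)
  n <- length(lab)
  offs <- if (connectivity == 26) DIRS13 else
    rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  comp <- ifelse(is.na(as.vector(lab)), NA_integer_, seq_len(n))
  pairList <- list()
  for (k in seq_len(nrow(offs))) {
    pr <- shiftPairs(dims, offs[k, ])
    if (is.null(pr)) next
    ok <- !is.na(lab[pr$src]) & !is.na(lab[pr$dst]) &
          lab[pr$src] == lab[pr$dst]
    if (any(ok)) pairList[[length(pairList) + 1L]] <-
        cbind(pr$src[ok], pr$dst[ok])
  }
  if (length(pairList)) {
    edges <- do.call(rbind, pairList)
    repeat {
      changed <- FALSE
      m <- pmin(comp[edges[, 1]], comp[edges[, 2]])
      if (any(m < comp[edges[, 1]], na.rm = TRUE) ||
          any(m < comp[edges[, 2]], na.rm = TRUE)) changed <- TRUE
      # min-reduce over duplicate targets
      upd1 <- tapply(m, edges[, 1], min)
      upd2 <- tapply(m, edges[, 2], min)
      i1 <- as.integer(names(upd1)); i2 <- as.integer(names(upd2))
      comp[i1] <- pmin(comp[i1], unname(upd1))
      comp[i2] <- pmin(comp[i2], unname(upd2))
      # pointer jumping to accelerate convergence
      act <- which(!is.na(comp))
      repeat {
        nxt <- comp[comp[act]]
        if (all(nxt == comp[act])) break
        comp[act] <- nxt
      }
      if (!changed) break
    }
  }
  # renumber compactly
  ids <- comp[!is.na(comp)]
  comp[!is.na(comp)] <- match(ids, sort(unique(ids)))
  array(comp, dims)
}
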