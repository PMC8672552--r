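#' Neighbourhood grey-tone difference matrix and its 5 features
#'
#' \code{buildNgtdm} computes, for each grey level \eqn{i}, the number of
#' ROI voxels of that level having at least one valid 26-neighbour inside
#' the ROI, and the summed absolute difference between the level and the
#' mean level of those neighbours. \code{ngtdmFeatures} derives the 5
#' standardized features: coarseness, contrast, busyness, complexity and
#' strength. Degenerate conventions: a uniform ROI has all differences 0
#' (contrast 0); coarseness is capped at \eqn{10^6} when its denominator
#' is 0 (e.g. a single-voxel ROI with no valid neighbourhood).
#'
#' @param d a \code{DiscretizedROI} from [discretizeRoi()].
#' @param tbl the table returned by \code{buildNgtdm}.
#' @return \code{buildNgtdm}: data.frame with one row per grey level:
#'   \code{level}, \code{count} (\eqn{n_i}), \code{prob} (\eqn{p_i}) and
#'   \code{s} (summed absolute differences). \code{ngtdmFeatures}: named
#'   numeric vector of 5 features (prefix \code{ngtdm_}).
#' @examples
#' v <- ImageVolume(array(runif(64), c(4, 4, 4)))
#' m <- ROIMask(array(TRUE, c(4, 4, 4)))
#' ngtdmFeatures(buildNgtdm(discretizeRoi(v, m, nBins = 4)))
#' @export
buildNgtdm <- function(d) {
  lab <- d$labels
  dims <- dim(lab)
  nsum <- array(0, dims)
  ncnt <- array(0L, dims)
  for (k in seq_len(nrow(DIRS13))) {
    pr <- shiftPairs(dims, DIRS13[k, ])
    if (is.null(pr)) next
    ok <- !is.na(lab[pr$src]) & !is.na(lab[pr$dst])
    s <- pr$src[ok]; t <- pr$dst[ok]
    nsum[s] <- nsum[s] + lab[t]
    ncnt[s] <- ncnt[s] + 1L
    nsum[t] <- nsum[t] + lab[s]
    ncnt[t] <- ncnt[t] + 1L
  }
  valid <- !is.na(lab) & ncnt > 0
  lv <- lab[valid]
  diffs <- abs(lv - nsum[valid] / ncnt[valid])
  counts <- tabulate(lv, nbins = d$nBins)
  ssum <- numeric(d$nBins)
  if (length(lv)) {
    agg <- rowsum(diffs, lv)
    ssum[as.integer(rownames(agg))] <- agg[, 1]
  }
  nvc <- sum(counts)
  data.frame(level = seq_len(d$nBins),
             count = counts,
             prob = if (nvc > 0) counts / nvc else rep(0, d$nBins),
             s = ssum)
}

#' @rdname buildNgtdm
#' @export
ngtdmFeatures <- function(tbl) {
  nms <- registryNames("NGTDM")
  occ <- tbl$count > 0
  nvc <- sum(tbl$count)
  if (nvc == 0) {
    # no voxel has a valid neighbourhood
    return(setNames(c(1e6, 0, 0, 0, 0), nms))
  }
  i <- tbl$level[occ]; p <- tbl$prob[occ]; s <- tbl$s[occ]
  ngp <- length(i)
  ps <- sum(p * s)

  coarseness <- if (ps > 0) 1 / ps else 1e6
  contrast <- if (ngp > 1)
    sum(outer(p, p) * outer(i, i, "-")^2) / (ngp * (ngp - 1)) *
      sum(s) / nvc else 0
  bd <- sum(abs(outer(i * p, i * p, "-")))
  busyness <- if (ngp > 1 && bd > 0) ps / bd else 0
  complexity <- if (ngp > 1) {
    PS <- outer(p * s, p * s, "+")
    PP <- outer(p, p, "+")
    sum(abs(outer(i, i, "-")) * PS / PP) / nvc
  } else 0
  strength <- if (sum(s) > 0)
    sum(outer(p, p, "+") * outer(i, i, "-")^2) / sum(s) else 0

  setNames(c(coarseness, contrast, busyness, complexity, strength), nms)
}
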