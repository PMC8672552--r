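# Independent brute-force oracles for the texture matrices. These
# deliberately use naive per-voxel loops (no shared code with the package
# internals) so they can certify the vectorized builders.

oracleNeighbors26 <- function() {
  d <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  d[rowSums(abs(d)) > 0, , drop = FALSE]
}

# all 26 ordered neighbor pairs -> symmetric merged GLCM
oracleGlcm <- function(lab, nBins) {
  dims <- dim(lab)
  offs <- oracleNeighbors26()
  M <- matrix(0, nBins, nBins)
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2]))
    for (z in seq_len(dims[3])) {
      a <- lab[x, y, z]
      if (is.na(a)) next
      for (r in seq_len(nrow(offs))) {
        p <- c(x, y, z) + offs[r, ]
        if (any(p < 1) || any(p > dims)) next
        b <- lab[p[1], p[2], p[3]]
        if (is.na(b)) next
        M[a, b] <- M[a, b] + 1
      }
    }
  if (sum(M) > 0) M / sum(M) else M
}

# runs per direction by explicit line walking
oracleGlrlm <- function(lab, nBins) {
  dims <- dim(lab)
  offs <- oracleNeighbors26()
  # 13 unique directions: first nonzero component positive
  offs <- offs[apply(offs, 1, function(o) o[o != 0][1] > 0), , drop = FALSE]
  recs <- list()
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    for (x in seq_len(dims[1])) for (y in seq_len(dims[2]))
      for (z in seq_len(dims[3])) {
        a <- lab[x, y, z]
        if (is.na(a)) next
        prev <- c(x, y, z) - off
        prevIn <- all(prev >= 1) && all(prev <= dims)
        if (prevIn && !is.na(lab[prev[1], prev[2], prev[3]]) &&
            lab[prev[1], prev[2], prev[3]] == a) next  # not a run start
        len <- 1
        cur <- c(x, y, z) + off
        while (all(cur >= 1) && all(cur <= dims) &&
               !is.na(lab[cur[1], cur[2], cur[3]]) &&
               lab[cur[1], cur[2], cur[3]] == a) {
          len <- len + 1
          cur <- cur + off
        }
        recs[[length(recs) + 1]] <- c(a, len)
      }
  }
  recs <- do.call(rbind, recs)
  R <- matrix(0, nBins, max(recs[, 2]))
  for (i in seq_len(nrow(recs))) {
    R[recs[i, 1], recs[i, 2]] <- R[recs[i, 1], recs[i, 2]] + 1
  }
  R
}

# zones by explicit stack-based flood fill, 26-connected
oracleGlszm <- function(lab, nBins) {
  dims <- dim(lab)
  offs <- oracleNeighbors26()
  seen <- array(FALSE, dims)
  zones <- list()
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2]))
    for (z in seq_len(dims[3])) {
      if (seen[x, y, z] || is.na(lab[x, y, z])) next
      lev <- lab[x, y, z]
      stack <- list(c(x, y, z))
      seen[x, y, z] <- TRUE
      size <- 0
      while (length(stack)) {
        c0 <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        size <- size + 1
        for (r in seq_len(nrow(offs))) {
          p <- c0 + offs[r, ]
          if (any(p < 1) || any(p > dims)) next
          if (seen[p[1], p[2], p[3]]) next
          b <- lab[p[1], p[2], p[3]]
          if (is.na(b) || b != lev) next
          seen[p[1], p[2], p[3]] <- TRUE
          stack[[length(stack) + 1]] <- p
        }
      }
      zones[[length(zones) + 1]] <- c(lev, size)
    }
  zones <- do.call(rbind, zones)
  Z <- matrix(0, nBins, max(zones[, 2]))
  for (i in seq_len(nrow(zones))) {
    Z[zones[i, 1], zones[i, 2]] <- Z[zones[i, 1], zones[i, 2]] + 1
  }
  Z
}

# per-level neighbourhood averaging by explicit voxel loops
oracleNgtdm <- function(lab, nBins) {
  dims <- dim(lab)
  offs <- oracleNeighbors26()
  counts <- numeric(nBins)
  ssum <- numeric(nBins)
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2]))
    for (z in seq_len(dims[3])) {
      a <- lab[x, y, z]
      if (is.na(a)) next
      nb <- c()
      for (r in seq_len(nrow(offs))) {
        p <- c(x, y, z) + offs[r, ]
        if (any(p < 1) || any(p > dims)) next
        b <- lab[p[1], p[2], p[3]]
        if (!is.na(b)) nb <- c(nb, b)
      }
      if (length(nb)) {
        counts[a] <- counts[a] + 1
        ssum[a] <- ssum[a] + abs(a - mean(nb))
      }
    }
  nvc <- sum(counts)
  data.frame(level = seq_len(nBins), count = counts,
             prob = if (nvc > 0) counts / nvc else rep(0, nBins),
             s = ssum)
}

# random discretized ROI on a small grid
randomLabelArray <- function(dims, nLevels, pIn = 0.8) {
  lab <- array(sample.int(nLevels, prod(dims), replace = TRUE), dims)
  lab[runif(prod(dims)) > pIn] <- NA_integer_
  lab
}

asDiscretized <- function(lab, nBins) {
  structure(list(labels = lab, nBins = as.integer(nBins),
                 binEdges = seq(0, 1, length.out = nBins + 1),
                 nVoxels = sum(!is.na(lab))),
            class = "DiscretizedROI")
}

# small synthetic study used across tests: elliptical body, ellipsoidal
# kidney and GTV on a modest grid (kept apart so masks never overlap)
makeTestStudy <- function(patientId = "pt01", dims = c(32, 32, 12),
                          seed = 42) {
  set.seed(seed)
  xs <- slice.index(array(0, dims), 1)
  ys <- slice.index(array(0, dims), 2)
  zs <- slice.index(array(0, dims), 3)
  body <- ((xs - 16)^2 / 14^2 + (ys - 16)^2 / 12^2) <= 1
  kidneyM <- ((xs - 23)^2 / 3^2 + (ys - 20)^2 / 3^2 + (zs - 6)^2 / 4^2) <= 1
  gtvM <- ((xs - 11)^2 / 4^2 + (ys - 13)^2 / 4^2 + (zs - 6)^2 / 3^2) <= 1
  mkScan <- function(label) {
    vox <- array(abs(rnorm(prod(dims), 0.05, 0.02)), dims)
    vox[body] <- rnorm(sum(body), 0.5, 0.05)
    vox[kidneyM] <- 1.0
    vox[gtvM] <- abs(rnorm(sum(gtvM), 0.8, 0.15))
    ImageVolume(vox, c(1.5, 1.5, 3), label, patientId)
  }
  scansL <- lapply(c("SIM", "F1", "F2", "F3", "F4", "F5"), mkScan)
  names(scansL) <- c("SIM", "F1", "F2", "F3", "F4", "F5")
  PatientStudy(
    patientId, scansL,
    gtv = ROIMask(gtvM, "GTV", patientId),
    kidney = ROIMask(kidneyM, "kidney", patientId),
    survival = data.frame(patient_id = patientId, pfs_days = 120, event = 1,
                          chemo = "FOLFIRINOX", resectability = "borderline")
  )
}
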