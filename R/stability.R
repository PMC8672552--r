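#' Lin's concordance correlation coefficient
#'
#' Agreement between two paired measurement vectors, penalizing both
#' imperfect correlation and location/scale shift:
#' \deqn{CCC = \frac{2\,cov(x, y)}{var(x) + var(y) + (\bar x - \bar y)^2}}
#' with population (1/n) moments, following Lin's original definition.
#' \code{CCC(x, x) = 1} exactly, the coefficient is symmetric, and
#' \eqn{|CCC| \le |r|} (it attenuates the Pearson correlation whenever
#' the two measurements differ in mean or variance). Returns \code{NaN}
#' with a warning when both vectors are constant with equal means (the
#' denominator vanishes).
#'
#' @param x,y numeric vectors of equal length >= 2, finite values.
#' @return The concordance coefficient in \eqn{[-1, 1]}.
#' @examples
#' linCCC(c(1, 2, 3), c(2, 2, 4))  # 2/3
#' @export
linCCC <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("x and y must have equal length >= 2")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("x and y must be finite")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- popMoment(x, 2); vy <- popMoment(y, 2)
  cxy <- mean((x - mx) * (y - my))
  den <- vx + vy + (mx - my)^2
  if (den == 0) {
    warning("degenerate input: both constant with equal means")
    return(NaN)
  }
  2 * cxy / den
}

# multi-rater overall concordance (Barnhart/Lin): pooled pairwise
# numerators over pooled pairwise denominators
overallCCC <- function(mat) {
  k <- ncol(mat)
  num <- 0; den <- 0
  for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    x <- mat[, a]; y <- mat[, b]
    num <- num + 2 * mean((x - mean(x)) * (y - mean(y)))
    den <- den + popMoment(x, 2) + popMoment(y, 2) + (mean(x) - mean(y))^2
  }
  if (den == 0) NaN else num / den
}

#' Spatial-stability report across ROI perturbations
#'
#' Quantifies how robust each feature is to slight differences in tumor
#' delineation: per patient, all 73 features are extracted on the
#' simulation scan with the original GTV and with per-slice eroded and
#' dilated variants ([perturbRoi()]); per feature, the concordance
#' between the original-ROI values and each perturbed-ROI values across
#' patients is computed, and the two pairwise CCCs are averaged (or an
#' overall multi-rater CCC is used, \code{method = "overall"}). Patients
#' whose GTV vanishes under erosion are excluded and listed. Features
#' with low CCC are the ones to avoid in downstream modeling.
#'
#' @param studies list of [PatientStudy-class] (>= 3 usable).
#' @param radialDeltaMm per-slice radial perturbation in mm (default
#'   1.5).
#' @param nBins intensity bins (default 64).
#' @param normalization \code{"kidney_median"} or \code{"none"}.
#' @param method \code{"mean_pairwise"} (default) or \code{"overall"}.
#' @param scan scan to perturb (default \code{"SIM"}).
#' @param modes perturbation modes compared against the original ROI.
#' @return A \code{StabilityReport}: list with \code{perFeature}
#'   (data.frame \code{feature, family, ccc, percentile}),
#'   \code{excluded} (data.frame of patients and reasons), and the
#'   configuration.
#' @export
stabilityReport <- function(studies, radialDeltaMm = 1.5, nBins = 64,
                            normalization = c("kidney_median", "none"),
                            method = c("mean_pairwise", "overall"),
                            scan = "SIM",
                            modes = c("identity", "erode", "dilate")) {
  normalization <- match.arg(normalization)
  method <- match.arg(method)
  vals <- list(); excl <- list()
  ids <- vapply(studies, function(s) s@patientId, character(1))
  for (st in studies[order(ids)]) {
    res <- tryCatch({
      v <- st@scans[[scan]]
      if (normalization == "kidney_median")
        v <- normalizeVolume(v, kidneyMedian(v, st@kidney))
      sapply(modes, function(md) {
        roi <- perturbRoi(st@gtv, v@spacing, mode = md,
                          radialDeltaMm = radialDeltaMm)
        extractFeatures(v, roi, nBins = nBins)
      })
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("excluding patient ", st@patientId, " from stability: ",
              conditionMessage(res))
      excl[[st@patientId]] <- data.frame(patient_id = st@patientId,
                                         reason = conditionMessage(res))
    } else {
      vals[[st@patientId]] <- res   # 73 x length(modes)
    }
  }
  if (length(vals) < 3)
    stop("stability analysis requires >= 3 patients with valid perturbed ROIs")

  cccOf <- function(fIdx) {
    mat <- t(vapply(vals, function(m) m[fIdx, ], numeric(length(modes))))
    if (any(!is.finite(mat))) return(NA_real_)
    ref <- mat[, 1]
    if (method == "overall") return(overallCCC(mat))
    # identical measurement vectors are perfect agreement even when the
    # feature is constant across patients (where Lin's formula is 0/0)
    mean(vapply(2:ncol(mat), function(c2) {
      if (all(ref == mat[, c2])) 1 else
        suppressWarnings(linCCC(ref, mat[, c2]))
    }, numeric(1)))
  }
  ccc <- vapply(seq_len(nrow(REGISTRY)), cccOf, numeric(1))
  pct <- rank(ccc, na.last = "keep") / sum(!is.na(ccc)) * 100
  structure(list(
    perFeature = data.frame(feature = REGISTRY$name,
                            family = REGISTRY$family,
                            ccc = ccc, percentile = pct,
                            stringsAsFactors = FALSE),
    excluded = if (length(excl)) do.call(rbind, excl) else
      data.frame(patient_id = character(0), reason = character(0)),
    radialDeltaMm = radialDeltaMm, method = method, scan = scan,
    normalization = normalization
  ), class = "StabilityReport")
}

#' @export
print.StabilityReport <- function(x, ...) {
  cat(sprintf("StabilityReport (%s, +/-%.1f mm on %s): %d features\n",
              x$method, x$radialDeltaMm, x$scan, nrow(x$perFeature)))
  byFam <- tapply(x$perFeature$ccc, x$perFeature$family, median,
                  na.rm = TRUE)
  for (f in names(byFam))
    cat(sprintf("  median CCC %-10s %.3f\n", f, byFam[f]))
  if (nrow(x$excluded)) cat(" ", nrow(x$excluded), "patients excluded\n")
  invisible(x)
}
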