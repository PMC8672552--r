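#' Feature ratio between two fractions
#'
#' Element-wise division of two registry feature vectors from the same
#' patient — by default last over first fraction (F5/F1), the package's
#' measure of imaging change over treatment. A zero denominator yields
#' \code{NaN} for that feature only, with a warning. Ratios are plain
#' signed division; for sign-crossing features (skewness, cluster shade)
#' a sign flip makes the ratio non-monotone in the underlying change —
#' see the methods vignette.
#'
#' @param fvNum numerator feature vector (e.g. F5), from
#'   [extractFeatures()].
#' @param fvDen denominator feature vector (e.g. F1).
#' @return Named numeric vector of 73 ratios in registry order.
#' @examples
#' v <- ImageVolume(array(runif(512), c(8, 8, 8)))
#' m <- ROIMask(array(TRUE, c(8, 8, 8)))
#' fv <- extractFeatures(v, m)
#' all(deltaRatio(fv, fv) == 1)
#' @export
deltaRatio <- function(fvNum, fvDen) {
  if (!identical(names(fvNum), REGISTRY$name) ||
      !identical(names(fvDen), REGISTRY$name))
    stop("feature vectors do not match the registry")
  zero <- !is.na(fvDen) & fvDen == 0
  if (any(zero))
    warning("zero denominator for: ",
            paste(names(fvDen)[zero], collapse = ", "))
  out <- as.numeric(fvNum) / as.numeric(fvDen)
  out[zero] <- NaN
  setNames(out, REGISTRY$name)
}

#' Build the cohort delta-feature table
#'
#' Runs the full per-patient chain — kidney-median normalization (unless
#' disabled), 64-bin feature extraction on the first and last fraction
#' GTV, and the feature ratio — and assembles the patients-by-features
#' analysis matrix. A patient whose extraction fails is dropped with the
#' reason recorded in the table's exclusions; the run is deterministic
#' given its inputs.
#'
#' @param studies list of [PatientStudy-class].
#' @param normalization \code{"kidney_median"} (default) or
#'   \code{"none"}.
#' @param nBins intensity bins (default 64).
#' @param pair character length-2: numerator and denominator scan labels
#'   (default \code{c("F5", "F1")}).
#' @return A [DeltaFeatureTable-class].
#' @export
buildDeltaTable <- function(studies,
                            normalization = c("kidney_median", "none"),
                            nBins = 64, pair = c("F5", "F1")) {
  normalization <- match.arg(normalization)
  stopifnot(length(pair) == 2, all(pair %in% SCAN_LABELS))
  rows <- list(); excl <- list()
  ids <- vapply(studies, function(s) s@patientId, character(1))
  for (st in studies[order(ids)]) {
    res <- tryCatch({
      fvs <- lapply(pair, function(lb) {
        v <- st@scans[[lb]]
        if (is.null(v)) stop("missing scan ", lb)
        if (normalization == "kidney_median")
          v <- normalizeVolume(v, kidneyMedian(v, st@kidney))
        extractFeatures(v, st@gtv, nBins = nBins)
      })
      suppressWarnings(deltaRatio(fvs[[1]], fvs[[2]]))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("excluding patient ", st@patientId, ": ",
              conditionMessage(res))
      excl[[st@patientId]] <- data.frame(patient_id = st@patientId,
                                         reason = conditionMessage(res))
    } else {
      rows[[st@patientId]] <- res
    }
  }
  if (!length(rows)) stop("no patient could be processed")
  m <- do.call(rbind, rows)
  colnames(m) <- REGISTRY$name
  new("DeltaFeatureTable", values = m, normalization = normalization,
      nBins = nBins, pair = pair,
      exclusions = if (length(excl)) do.call(rbind, excl) else
        data.frame(patient_id = character(0), reason = character(0)))
}
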