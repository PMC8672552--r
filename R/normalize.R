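#' Median kidney signal over the three selected slices
#'
#' The normalization reference: the median of all kidney-mask voxel
#' intensities pooled over exactly the three selected slices (see
#' [selectKidneySlices()]). The median of an even count is the mean of
#' the two central order statistics.
#'
#' @param volume an [ImageVolume-class].
#' @param kidneyMask kidney [ROIMask-class] on the same grid.
#' @param slices integer vector of 3 slice indices; default
#'   \code{selectKidneySlices(kidneyMask)}.
#' @return The median kidney intensity (scalar).
#' @export
kidneyMedian <- function(volume, kidneyMask,
                         slices = selectKidneySlices(kidneyMask)) {
  stopifnot(is(volume, "ImageVolume"), is(kidneyMask, "ROIMask"))
  if (!identical(dim(volume@voxels), dim(kidneyMask@voxels)))
    stop("mask and volume grids differ")
  vals <- numeric(0)
  for (s in unique(slices)) {
    sl <- kidneyMask@voxels[, , s]
    if (!any(sl))
      stop("no kidney voxels on selected slice ", s)
  }
  sel <- kidneyMask@voxels
  keep <- array(FALSE, dim(sel))
  keep[, , unique(slices)] <- sel[, , unique(slices)]
  median(volume@voxels[keep])
}

#' Divide a volume by a normalization value
#'
#' Linear intensity normalization: every voxel is divided by
#' \code{normValue} (typically the scan's own [kidneyMedian()]), leaving
#' spacing and label untouched. After normalization by the kidney median
#' the kidney's median signal is 1 by construction, and the result is
#' invariant to any global multiplicative rescaling of the raw scan —
#' the property that removes inter-session technical drift.
#'
#' @param volume an [ImageVolume-class].
#' @param normValue positive scalar divisor.
#' @return The normalized [ImageVolume-class].
#' @examples
#' v <- ImageVolume(array(6, c(2, 2, 2)))
#' range(voxels(normalizeVolume(v, 2)))
#' @export
normalizeVolume <- function(volume, normValue) {
  stopifnot(is(volume, "ImageVolume"))
  if (!is.finite(normValue) || normValue <= 0)
    stop("normValue must be > 0")
  new("ImageVolume", voxels = volume@voxels / normValue,
      spacing = volume@spacing, label = volume@label,
      patientId = volume@patientId)
}

#' Technical-drift correlation analysis
#'
#' Quantifies how much of the tumor's apparent intensity change between
#' the simulation scan and the first fraction — before any radiation
#' effect is possible — is a global, technical scaling drift. Per
#' patient, the ratio of median GTV signal (F1/SIM) is compared with the
#' same ratio over the automatic abdomen ROI; across patients the two
#' ratios are correlated (Pearson, two-sided p via the t-transform with
#' n-2 df). A strong positive correlation indicates shared technical
#' drift; after kidney-median normalization the correlation should
#' vanish.
#'
#' @param studies list of [PatientStudy-class] objects (>= 3 with a valid
#'   abdomen ROI).
#' @param normalized if \code{TRUE}, ratios are computed on
#'   kidney-median-normalized volumes.
#' @return A \code{DriftReport}: list with \code{perPatient} (data.frame
#'   \code{patient_id, gtv_ratio, abdomen_ratio}), \code{pearsonR},
#'   \code{pValue} and \code{normalized}.
#' @export
driftAnalysis <- function(studies, normalized = FALSE) {
  rows <- lapply(studies, function(st) {
    vs <- st@scans[["SIM"]]; vf <- st@scans[["F1"]]
    if (normalized) {
      vs <- normalizeVolume(vs, kidneyMedian(vs, st@kidney))
      vf <- normalizeVolume(vf, kidneyMedian(vf, st@kidney))
    }
    abd <- abdomenAutoRoi(vs, st@gtv)
    if (!any(abd@voxels)) return(NULL)
    gtvRatio <- median(vf@voxels[st@gtv@voxels]) /
                median(vs@voxels[st@gtv@voxels])
    abdRatio <- median(vf@voxels[abd@voxels]) /
                median(vs@voxels[abd@voxels])
    data.frame(patient_id = st@patientId, gtv_ratio = gtvRatio,
               abdomen_ratio = abdRatio)
  })
  per <- do.call(rbind, rows)
  if (is.null(per) || nrow(per) < 3)
    stop("drift analysis requires >= 3 patients with a valid abdomen ROI")
  if (sd(per$gtv_ratio) == 0 || sd(per$abdomen_ratio) == 0)
    stop("zero variance in signal ratios; correlation undefined")
  ct <- cor.test(per$gtv_ratio, per$abdomen_ratio, method = "pearson")
  structure(list(perPatient = per,
                 pearsonR = unname(ct$estimate),
                 pValue = ct$p.value,
                 normalized = normalized),
            class = "DriftReport")
}

#' @export
print.DriftReport <- function(x, ...) {
  cat(sprintf("DriftReport (%s): n = %d patients, Pearson r = %.3f, p = %.3g\n",
              if (x$normalized) "kidney-normalized" else "raw",
              nrow(x$perPatient), x$pearsonR, x$pValue))
  invisible(x)
}
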