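#' @import methods
NULL

SCAN_LABELS <- c("SIM", "F1", "F2", "F3", "F4", "F5")
ROI_ROLES <- c("GTV", "kidney", "abdomen")

#' ImageVolume: one 3D MR scan
#'
#' Container for a single 3D MR volume: a numeric voxel grid, its physical
#' voxel spacing in mm, the scan label within the treatment course
#' (\code{SIM}, the pre-treatment simulation scan, or \code{F1}..\code{F5},
#' the five fraction scans), and the patient identifier. Voxel intensities
#' are arbitrary MR signal units; no calibration is assumed.
#'
#' Voxel centers sit at \code{origin + index * spacing} with 0-based
#' indices, the convention used consistently by the contour rasterizer.
#'
#' @slot voxels numeric 3D array of signal intensities.
#' @slot spacing numeric length-3, voxel size (dx, dy, dz) in mm, all > 0.
#' @slot label scan label, one of \code{SIM, F1, F2, F3, F4, F5}.
#' @slot patientId patient identifier.
#'
#' @seealso [ImageVolume()] for construction, [ROIMask-class],
#'   [PatientStudy-class]
#' @exportClass ImageVolume
setClass("ImageVolume",
  representation(
    voxels = "array",
    spacing = "numeric",
    label = "character",
    patientId = "character"
  )
)

setValidity("ImageVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L || length(object@voxels) == 0L)
    msg <- c(msg, "voxels must be a non-empty 3D array")
  if (!all(is.finite(object@voxels)))
    msg <- c(msg, "all voxel values must be finite")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite values (mm)")
  if (length(object@label) != 1L || !(object@label %in% SCAN_LABELS))
    msg <- c(msg, paste("label must be one of", paste(SCAN_LABELS, collapse = ", ")))
  if (length(object@patientId) != 1L || !nzchar(object@patientId))
    msg <- c(msg, "patientId must be a non-empty string")
  if (length(msg)) msg else TRUE
})

#' ROIMask: binary region-of-interest mask
#'
#' A binary 3D mask aligned voxel-for-voxel with its reference
#' [ImageVolume-class], tagged with the anatomical role it delineates:
#' the gross tumor volume (\code{GTV}), the \code{kidney} reference
#' region used for intensity normalization, or the automatically derived
#' \code{abdomen} cross-section.
#'
#' @slot voxels logical 3D array; \code{TRUE} marks foreground.
#' @slot role one of \code{GTV}, \code{kidney}, \code{abdomen}.
#' @slot patientId patient identifier.
#'
#' @seealso [ROIMask()], [perturbRoi()], [abdomenAutoRoi()]
#' @exportClass ROIMask
setClass("ROIMask",
  representation(
    voxels = "array",
    role = "character",
    patientId = "character"
  )
)

setValidity("ROIMask", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L || length(object@voxels) == 0L)
    msg <- c(msg, "voxels must be a non-empty 3D array")
  if (!is.logical(object@voxels))
    msg <- c(msg, "mask voxels must be logical")
  if (length(object@role) != 1L || !(object@role %in% ROI_ROLES))
    msg <- c(msg, paste("role must be one of", paste(ROI_ROLES, collapse = ", ")))
  if (length(object@patientId) != 1L || !nzchar(object@patientId))
    msg <- c(msg, "patientId must be a non-empty string")
  if (object@role %in% c("GTV", "kidney") && !any(object@voxels))
    msg <- c(msg, paste(object@role, "mask has no foreground voxel"))
  if (length(msg)) msg else TRUE
})

#' PatientStudy: one patient's aligned longitudinal study
#'
#' Bundles the six grid-aligned scans of one patient (simulation plus five
#' fraction scans), the GTV and kidney masks drawn on that common grid, and
#' the survival record. All scans must share shape and spacing: online
#' rigid registration is a preprocessing responsibility of the treatment
#' system, not re-done here.
#'
#' @slot patientId patient identifier.
#' @slot scans named list of [ImageVolume-class], names \code{SIM, F1..F5}.
#' @slot gtv [ROIMask-class] with role \code{GTV}.
#' @slot kidney [ROIMask-class] with role \code{kidney}.
#' @slot survival one-row data.frame with columns \code{pfs_days},
#'   \code{event}, \code{chemo}, \code{resectability}.
#'
#' @seealso [PatientStudy()], [loadStudy()], [generateCohort()]
#' @exportClass PatientStudy
setClass("PatientStudy",
  representation(
    patientId = "character",
    scans = "list",
    gtv = "ROIMask",
    kidney = "ROIMask",
    survival = "data.frame"
  )
)

setValidity("PatientStudy", function(object) {
  msg <- character()
  missing <- setdiff(SCAN_LABELS, names(object@scans))
  if (length(missing))
    msg <- c(msg, paste("missing scan", paste(missing, collapse = ", ")))
  if (!length(msg)) {
    dims <- lapply(object@scans, function(v) dim(v@voxels))
    sps <- lapply(object@scans, function(v) v@spacing)
    if (!all(vapply(dims, identical, logical(1), dims[[1]])))
      msg <- c(msg, "all scans must share the same grid shape")
    if (!all(vapply(sps, identical, logical(1), sps[[1]])))
      msg <- c(msg, "all scans must share the same voxel spacing")
    if (!identical(dim(object@gtv@voxels), dims[[1]]))
      msg <- c(msg, "GTV mask shape differs from scan grid")
    if (!identical(dim(object@kidney@voxels), dims[[1]]))
      msg <- c(msg, "kidney mask shape differs from scan grid")
    if (identical(dim(object@gtv@voxels), dim(object@kidney@voxels)) &&
        any(object@gtv@voxels & object@kidney@voxels))
      msg <- c(msg, "GTV and kidney masks overlap")
  }
  if (nrow(object@survival) != 1L ||
      !all(c("pfs_days", "event") %in% names(object@survival)))
    msg <- c(msg, "survival must be a one-row data.frame with pfs_days and event")
  else {
    if (object@survival$pfs_days < 0) msg <- c(msg, "pfs_days must be >= 0")
    if (!(object@survival$event %in% c(0, 1))) msg <- c(msg, "event must be 0 or 1")
  }
  if (length(msg)) msg else TRUE
})

#' DeltaFeatureTable: patients-by-features ratio matrix
#'
#' The delta-radiomics analysis table: one row per patient, one column per
#' registry feature, each cell the ratio of the feature at the last
#' fraction to the first (F5/F1 by default). A ratio is \code{NaN} iff the
#' denominator is zero or either feature is missing. Metadata records the
#' normalization mode, bin count and scan pair so a table is
#' self-describing.
#'
#' @slot values numeric matrix, rownames = patient ids, colnames = the 73
#'   registry feature names.
#' @slot normalization \code{"kidney_median"} or \code{"none"}.
#' @slot nBins intensity bin count used for discretization.
#' @slot pair character length-2, (numerator scan, denominator scan).
#' @slot exclusions data.frame of dropped patients and reasons.
#'
#' @seealso [buildDeltaTable()], [deltaRatio()], [coxScreen()]
#' @exportClass DeltaFeatureTable
setClass("DeltaFeatureTable",
  representation(
    values = "matrix",
    normalization = "character",
    nBins = "numeric",
    pair = "character",
    exclusions = "data.frame"
  )
)

setValidity("DeltaFeatureTable", function(object) {
  msg <- character()
  if (is.null(rownames(object@values)) || anyDuplicated(rownames(object@values)))
    msg <- c(msg, "values must have unique patient-id rownames")
  if (!identical(colnames(object@values), featureRegistry()$name))
    msg <- c(msg, "columns must match the feature registry in order")
  if (length(msg)) msg else TRUE
})
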