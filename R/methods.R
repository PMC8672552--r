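#' Construct an ImageVolume
#'
#' @param voxels numeric 3D array of MR signal intensities.
#' @param spacing voxel size (dx, dy, dz) in mm; default 1.5 x 1.5 x 3 mm,
#'   the acquisition geometry of the 0.35T MRI-Linac protocol this package
#'   targets.
#' @param label scan label, one of \code{SIM, F1..F5}.
#' @param patientId patient identifier.
#' @return A validated [ImageVolume-class].
#' @examples
#' v <- ImageVolume(array(rnorm(32, 10), c(4, 4, 2)), label = "SIM")
#' v
#' @export
ImageVolume <- function(voxels, spacing = c(1.5, 1.5, 3), label = "SIM",
                        patientId = "anon") {
  new("ImageVolume", voxels = voxels * 1.0, spacing = as.numeric(spacing),
      label = label, patientId = patientId)
}

#' Construct an ROIMask
#'
#' @param voxels logical (or 0/1 numeric) 3D array; \code{TRUE}/1 marks
#'   foreground.
#' @param role one of \code{GTV}, \code{kidney}, \code{abdomen}.
#' @param patientId patient identifier.
#' @return A validated [ROIMask-class].
#' @export
ROIMask <- function(voxels, role = "GTV", patientId = "anon") {
  if (!is.logical(voxels)) {
    d <- dim(voxels)
    voxels <- array(voxels != 0, d)
  }
  new("ROIMask", voxels = voxels, role = role, patientId = patientId)
}

#' Assemble a PatientStudy
#'
#' @param patientId patient identifier.
#' @param scans named list of six [ImageVolume-class] objects
#'   (\code{SIM, F1..F5}) on one common grid.
#' @param gtv GTV [ROIMask-class].
#' @param kidney kidney [ROIMask-class].
#' @param survival one-row data.frame with \code{pfs_days}, \code{event}
#'   and optionally \code{chemo}, \code{resectability}.
#' @return A validated [PatientStudy-class].
#' @export
PatientStudy <- function(patientId, scans, gtv, kidney, survival) {
  new("PatientStudy", patientId = patientId, scans = scans[SCAN_LABELS],
      gtv = gtv, kidney = kidney, survival = survival)
}

#' @rdname accessors
setMethod("voxels", "ImageVolume", function(object) object@voxels)
#' @rdname accessors
setMethod("voxels", "ROIMask", function(object) object@voxels)
#' @rdname accessors
setMethod("spacing", "ImageVolume", function(object) object@spacing)
#' @rdname accessors
setMethod("spacing", "PatientStudy",
          function(object) object@scans[[1]]@spacing)
#' @rdname accessors
setMethod("scanLabel", "ImageVolume", function(object) object@label)
#' @rdname accessors
setMethod("patientId", "ImageVolume", function(object) object@patientId)
#' @rdname accessors
setMethod("patientId", "ROIMask", function(object) object@patientId)
#' @rdname accessors
setMethod("patientId", "PatientStudy", function(object) object@patientId)
#' @rdname accessors
setMethod("roiRole", "ROIMask", function(object) object@role)
#' @rdname accessors
setMethod("scans", "PatientStudy", function(object) object@scans)
#' @rdname accessors
setMethod("gtv", "PatientStudy", function(object) object@gtv)
#' @rdname accessors
setMethod("kidney", "PatientStudy", function(object) object@kidney)
#' @rdname accessors
setMethod("survivalRecord", "PatientStudy", function(object) object@survival)
#' @rdname accessors
setMethod("deltaValues", "DeltaFeatureTable", function(object) object@values)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageVolume '%s' scan %s: %d x %d x %d voxels @ %.2g x %.2g x %.2g mm\n",
              object@patientId, object@label, d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "ROIMask", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ROIMask '%s' role %s: %d / %d voxels foreground (%d x %d x %d grid)\n",
              object@patientId, object@role, sum(object@voxels),
              length(object@voxels), d[1], d[2], d[3]))
})

setMethod("show", "PatientStudy", function(object) {
  cat(sprintf("PatientStudy '%s': %d scans (%s), GTV %d voxels, kidney %d voxels\n",
              object@patientId, length(object@scans),
              paste(names(object@scans), collapse = " "),
              sum(object@gtv@voxels), sum(object@kidney@voxels)))
  sv <- object@survival
  cat(sprintf("  PFS %.0f days, event = %d\n", sv$pfs_days, sv$event))
})

setMethod("show", "DeltaFeatureTable", function(object) {
  cat(sprintf("DeltaFeatureTable: %d patients x %d features (%s / %s, %s normalization, %d bins)\n",
              nrow(object@values), ncol(object@values),
              object@pair[1], object@pair[2], object@normalization,
              as.integer(object@nBins)))
  if (nrow(object@exclusions))
    cat(sprintf("  %d patients excluded\n", nrow(object@exclusions)))
})
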