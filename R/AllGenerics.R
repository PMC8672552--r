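#' Accessors for imaging objects
#'
#' Bioconductor-style accessors: \code{voxels()} returns the raw 3D array,
#' \code{spacing()} the (dx, dy, dz) voxel size in mm, \code{scanLabel()}
#' the scan's position in the treatment course, \code{patientId()} the
#' patient identifier, \code{roiRole()} a mask's anatomical role, and
#' \code{scans()} the named list of a study's six volumes.
#'
#' @param object an [ImageVolume-class], [ROIMask-class] or
#'   [PatientStudy-class].
#' @return The slot value; see Details per generic.
#' @examples
#' v <- ImageVolume(array(1, c(4, 4, 2)), c(1.5, 1.5, 3), "F1", "pt01")
#' spacing(v)
#' scanLabel(v)
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))

#' @rdname accessors
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))

#' @rdname accessors
#' @export
setGeneric("scanLabel", function(object) standardGeneric("scanLabel"))

#' @rdname accessors
#' @export
setGeneric("patientId", function(object) standardGeneric("patientId"))

#' @rdname accessors
#' @export
setGeneric("roiRole", function(object) standardGeneric("roiRole"))

#' @rdname accessors
#' @export
setGeneric("scans", function(object) standardGeneric("scans"))

#' @rdname accessors
#' @export
setGeneric("gtv", function(object) standardGeneric("gtv"))

#' @rdname accessors
#' @export
setGeneric("kidney", function(object) standardGeneric("kidney"))

#' @rdname accessors
#' @export
setGeneric("survivalRecord", function(object) standardGeneric("survivalRecord"))

#' @rdname accessors
#' @export
setGeneric("deltaValues", function(object) standardGeneric("deltaValues"))
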