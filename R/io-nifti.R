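#' Load one patient's aligned longitudinal study
#'
#' Reads a study directory into a validated [PatientStudy-class].
#'
#' NIfTI layout (the canonical fixture format): files
#' \code{<patient>_<label>.nii.gz} for the six scans (\code{SIM, F1..F5}),
#' \code{<patient>_gtv.nii.gz} and \code{<patient>_kidney.nii.gz} binary
#' masks, and a \code{survival.csv} with columns \code{patient_id,
#' pfs_days, event, chemo, resectability}. Volumes are used exactly as
#' stored — no resampling or interpolation is ever applied; all six scans
#' must already share one grid.
#'
#' DICOM layout: one sub-directory \code{<patient>_<label>/} of
#' single-frame files per scan (see [readDicomSeries()]) plus a
#' \code{<patient>_contours.json} file of planar polygons (roles
#' \code{gtv}, \code{kidney}) rasterized through [rasterizeContours()],
#' and the same \code{survival.csv}.
#'
#' @param path study directory.
#' @param patientId patient identifier (must match file names and the
#'   survival row).
#' @param format \code{"nifti"} or \code{"dicom"}.
#' @return A validated [PatientStudy-class].
#' @seealso [writeCohort()], [loadCohort()]
#' @export
loadStudy <- function(path, patientId, format = c("nifti", "dicom")) {
  format <- match.arg(format)
  sv <- readSurvivalRow(file.path(path, "survival.csv"), patientId)
  if (format == "nifti") {
    vols <- lapply(SCAN_LABELS, function(lb) {
      f <- file.path(path, sprintf("%s_%s.nii.gz", patientId, lb))
      if (!file.exists(f)) stop("missing scan ", lb)
      readNiftiVolume(f, lb, patientId)
    })
    names(vols) <- SCAN_LABELS
    gtvF <- file.path(path, sprintf("%s_gtv.nii.gz", patientId))
    kidF <- file.path(path, sprintf("%s_kidney.nii.gz", patientId))
    if (!file.exists(gtvF)) stop("missing GTV mask for ", patientId)
    if (!file.exists(kidF)) stop("missing kidney mask for ", patientId)
    readMask <- function(f) {
      img <- RNifti::readNifti(f)
      array(as.numeric(img) != 0, dim(img))
    }
    gtvM <- ROIMask(readMask(gtvF), "GTV", patientId)
    kidM <- ROIMask(readMask(kidF), "kidney", patientId)
  } else {
    vols <- lapply(SCAN_LABELS, function(lb) {
      d <- file.path(path, sprintf("%s_%s", patientId, lb))
      if (!dir.exists(d)) stop("missing scan ", lb)
      readDicomSeries(d)
    })
    names(vols) <- SCAN_LABELS
    cj <- file.path(path, sprintf("%s_contours.json", patientId))
    if (!file.exists(cj)) stop("missing contour file for ", patientId)
    cont <- jsonlite::read_json(cj, simplifyVector = TRUE)
    getRole <- function(role) {
      cc <- cont[[role]]
      if (is.null(cc)) stop("missing ", role, " contours for ", patientId)
      polys <- lapply(seq_len(nrow(cc)), function(i)
        list(slice = cc$slice[i], x = cc$x[[i]], y = cc$y[[i]]))
      rasterizeContours(polys, vols[["SIM"]],
                        role = if (role == "gtv") "GTV" else "kidney")
    }
    gtvM <- getRole("gtv")
    kidM <- getRole("kidney")
  }
  if (!any(gtvM@voxels)) stop("empty GTV mask for ", patientId)
  PatientStudy(patientId, vols, gtvM, kidM, sv)
}

#' Load every patient listed in a cohort directory
#'
#' @param path cohort directory containing \code{survival.csv}.
#' @param format \code{"nifti"} or \code{"dicom"}.
#' @return Named list of [PatientStudy-class], ordered by patient id.
#' @export
loadCohort <- function(path, format = c("nifti", "dicom")) {
  sv <- read.csv(file.path(path, "survival.csv"), stringsAsFactors = FALSE)
  ids <- sort(unique(sv$patient_id))
  out <- lapply(ids, function(id) loadStudy(path, id, format))
  names(out) <- ids
  out
}

#' Write a cohort of studies in the canonical NIfTI + CSV layout
#'
#' Writes each study's six scans and two masks as \code{.nii.gz} files
#' (double precision, so read-back is bit-exact) and a single
#' \code{survival.csv}, the layout [loadStudy()] and [loadCohort()] read.
#'
#' @param studies list of [PatientStudy-class].
#' @param path output directory (created if needed).
#' @return \code{path}, invisibly.
#' @export
writeCohort <- function(studies, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  svRows <- list()
  for (st in studies) {
    id <- st@patientId
    for (lb in names(st@scans))
      writeNiftiVolume(st@scans[[lb]],
                       file.path(path, sprintf("%s_%s.nii.gz", id, lb)))
    writeNiftiMask(st@gtv, st@scans[[1]]@spacing,
                   file.path(path, sprintf("%s_gtv.nii.gz", id)))
    writeNiftiMask(st@kidney, st@scans[[1]]@spacing,
                   file.path(path, sprintf("%s_kidney.nii.gz", id)))
    svRows[[id]] <- st@survival
  }
  sv <- do.call(rbind, svRows)
  write.csv(sv, file.path(path, "survival.csv"), row.names = FALSE)
  invisible(path)
}

readNiftiVolume <- function(f, label, patientId) {
  img <- RNifti::readNifti(f)
  ImageVolume(array(as.numeric(img), dim(img)), RNifti::pixdim(img)[1:3],
              label, patientId)
}

writeNiftiVolume <- function(volume, f) {
  a <- volume@voxels
  attr(a, "pixdim") <- volume@spacing
  RNifti::writeNifti(RNifti::asNifti(a, datatype = "double"), f)
}

writeNiftiMask <- function(mask, spacing, f) {
  a <- array(as.integer(mask@voxels), dim(mask@voxels))
  attr(a, "pixdim") <- spacing
  RNifti::writeNifti(RNifti::asNifti(a, datatype = "uint8"), f)
}

readSurvivalRow <- function(f, patientId) {
  if (!file.exists(f)) stop("missing survival.csv")
  sv <- read.csv(f, stringsAsFactors = FALSE)
  row <- sv[sv$patient_id == patientId, , drop = FALSE]
  if (nrow(row) != 1)
    stop("survival.csv must contain exactly one row for ", patientId)
  row
}

#' Save a feature table as CSV
#'
#' One row per patient, one \code{patient_id} column plus one column per
#' registry feature in registry order; values are written with 15
#' significant digits so a write-then-read round-trip is lossless.
#'
#' @param table a [DeltaFeatureTable-class], or a numeric matrix with
#'   unique patient-id rownames and registry-ordered feature columns.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
saveFeatureTable <- function(table, path) {
  m <- if (is(table, "DeltaFeatureTable")) table@values else table
  if (is.null(dim(m)) || nrow(m) == 0) stop("empty feature table")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("duplicate or missing patient ids")
  df <- data.frame(patient_id = rownames(m),
                   signif(m, 15), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [saveFeatureTable()]
#'
#' @param path CSV path.
#' @return Numeric matrix with patient-id rownames.
#' @export
readFeatureTable <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$patient_id
  m
}
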