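# Minimal DICOM series codec: explicit-VR little-endian single-frame MR
# files, one per axial slice, with 16-bit unsigned pixel data plus
# rescale slope/intercept. Written and read by this package as its DICOM
# interchange surface; the tag set is the minimum that identifies the
# patient, scan label, geometry and pixel values.

TSUID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

#' Write / read a volume as a DICOM series
#'
#' \code{writeDicomSeries} stores an [ImageVolume-class] as one
#' single-frame explicit-VR little-endian DICOM file per axial slice
#' (\code{slice_###.dcm}). Intensities are linearly mapped onto the
#' 16-bit unsigned range and the mapping is recorded in rescale
#' slope/intercept tags, so \code{readDicomSeries} recovers values to
#' 16-bit quantization precision. Geometry is carried by pixel spacing,
#' slice thickness and slice location; identity by patient ID and series
#' description (the scan label).
#'
#' @param volume an [ImageVolume-class].
#' @param dir output directory for the series (created if needed).
#' @return \code{writeDicomSeries}: \code{dir}, invisibly.
#'   \code{readDicomSeries}: the reconstructed [ImageVolume-class].
#' @export
writeDicomSeries <- function(volume, dir) {
  stopifnot(is(volume, "ImageVolume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  a <- volume@voxels
  lo <- min(a); hi <- max(a)
  slope <- if (hi > lo) (hi - lo) / 65535 else 1
  stored <- round((a - lo) / slope)
  dims <- dim(a)
  for (k in seq_len(dims[3])) {
    sl <- stored[, , k]
    f <- file.path(dir, sprintf("slice_%03d.dcm", k))
    con <- file(f, "wb")
    writeBin(raw(128), con)
    writeChar("DICM", con, eos = NULL)
    meta <- dcmElement(0x0002, 0x0010, "UI", dcmPadString(TSUID_EXPLICIT_LE))
    writeBin(dcmElement(0x0002, 0x0000, "UL", dcmUint32(length(meta))), con)
    writeBin(meta, con)
    body <- c(
      dcmElement(0x0008, 0x0060, "CS", dcmPadString("MR")),
      dcmElement(0x0008, 0x103E, "LO", dcmPadString(volume@label)),
      dcmElement(0x0010, 0x0020, "LO", dcmPadString(volume@patientId)),
      dcmElement(0x0018, 0x0050, "DS", dcmPadString(dcmNum(volume@spacing[3]))),
      dcmElement(0x0020, 0x0013, "IS", dcmPadString(as.character(k))),
      dcmElement(0x0020, 0x1041, "DS",
                 dcmPadString(dcmNum((k - 1) * volume@spacing[3]))),
      dcmElement(0x0028, 0x0010, "US", dcmUint16(dims[1])),
      dcmElement(0x0028, 0x0011, "US", dcmUint16(dims[2])),
      dcmElement(0x0028, 0x0030, "DS",
                 dcmPadString(paste(dcmNum(volume@spacing[1]),
                                    dcmNum(volume@spacing[2]), sep = "\\"))),
      dcmElement(0x0028, 0x0100, "US", dcmUint16(16)),
      dcmElement(0x0028, 0x0101, "US", dcmUint16(16)),
      dcmElement(0x0028, 0x0102, "US", dcmUint16(15)),
      dcmElement(0x0028, 0x0103, "US", dcmUint16(0)),
      dcmElement(0x0028, 0x1052, "DS", dcmPadString(dcmNum(lo))),
      dcmElement(0x0028, 0x1053, "DS", dcmPadString(dcmNum(slope))),
      dcmElement(0x7FE0, 0x0010, "OW", dcmUint16(as.vector(sl)))
    )
    writeBin(body, con)
    close(con)
  }
  invisible(dir)
}

#' @rdname writeDicomSeries
#' @param dir directory holding one series written by
#'   \code{writeDicomSeries}.
#' @export
readDicomSeries <- function(dir) {
  files <- list.files(dir, pattern = "\\.dcm$", full.names = TRUE)
  if (!length(files)) stop("no DICOM files in ", dir)
  slices <- lapply(files, readDicomFile)
  ord <- order(vapply(slices, function(s) as.integer(s$instance), integer(1)))
  slices <- slices[ord]
  s1 <- slices[[1]]
  dims <- c(s1$rows, s1$cols, length(slices))
  a <- array(0, dims)
  for (k in seq_along(slices)) {
    s <- slices[[k]]
    a[, , k] <- matrix(s$pixels, s1$rows, s1$cols) * s$slope + s$intercept
  }
  ImageVolume(a, c(s1$pixelSpacing, s1$sliceThickness), s1$label, s1$patientId)
}

readDicomFile <- function(f) {
  sz <- file.info(f)$size
  con <- file(f, "rb")
  on.exit(close(con))
  readBin(con, "raw", 128)
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "DICM")) stop("not a DICOM file: ", f)
  els <- list()
  repeat {
    hdr <- readBin(con, "raw", 8)
    if (length(hdr) < 8) break
    group <- readBin(hdr[1:2], "integer", size = 2, signed = FALSE,
                     endian = "little")
    elem <- readBin(hdr[3:4], "integer", size = 2, signed = FALSE,
                    endian = "little")
    vr <- rawToChar(hdr[5:6])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- readBin(readBin(con, "raw", 4), "integer", size = 4,
                     endian = "little")
    } else {
      len <- readBin(hdr[7:8], "integer", size = 2, signed = FALSE,
                     endian = "little")
    }
    val <- readBin(con, "raw", len)
    els[[sprintf("%04X%04X", group, elem)]] <- list(vr = vr, val = val)
  }
  getStr <- function(tag) sub("\\s+$", "", rawToChar(els[[tag]]$val))
  getU16 <- function(tag) readBin(els[[tag]]$val, "integer", size = 2,
                                  signed = FALSE, endian = "little")
  ps <- as.numeric(strsplit(getStr("00280030"), "\\\\")[[1]])
  npix <- length(els[["7FE00010"]]$val) / 2
  list(
    label = getStr("0008103E"),
    patientId = getStr("00100020"),
    instance = getStr("00200013"),
    rows = getU16("00280010"),
    cols = getU16("00280011"),
    pixelSpacing = ps,
    sliceThickness = as.numeric(getStr("00180050")),
    intercept = as.numeric(getStr("00281052")),
    slope = as.numeric(getStr("00281053")),
    pixels = readBin(els[["7FE00010"]]$val, "integer", n = npix, size = 2,
                     signed = FALSE, endian = "little")
  )
}

# ---- byte-level helpers ----

dcmUint16 <- function(v) {
  v <- as.integer(round(v))
  as.raw(rbind(v %% 256L, v %/% 256L))
}

dcmUint32 <- function(v) {
  v <- as.numeric(v)
  as.raw(c(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256,
           (v %/% 16777216) %% 256))
}

dcmNum <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)

dcmPadString <- function(s) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, charToRaw(" "))
  r
}

dcmElement <- function(group, elem, vr, valueRaw) {
  hdr <- c(dcmUint16(group), dcmUint16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(hdr, raw(2), dcmUint32(length(valueRaw)), valueRaw)
  } else {
    c(hdr, dcmUint16(length(valueRaw)), valueRaw)
  }
}
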