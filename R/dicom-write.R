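## Minimal DICOM writer: single-frame monochrome images, Explicit VR Little
## Endian, with the geometry fields needed to position pixels in patient
## coordinates (ImagePositionPatient, ImageOrientationPatient, PixelSpacing).

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_CT_STORAGE <- "1.2.840.10008.5.1.4.1.1.2"
UID_ROOT <- "1.2.826.0.1.3680043.10.1457"   # generated-instance UID prefix

uint16le <- function(x) {
  x <- as.integer(x)
  as.raw(c(x %% 256L, x %/% 256L))
}

uint32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

## Encode one data element (explicit VR little endian). value must already be
## a raw vector; it is padded to even length (NUL for UI/OB, space otherwise).
dcmElement <- function(group, elem, vr, value) {
  if (length(value) %% 2L == 1L)
    value <- c(value, if (vr %in% c("UI", "OB")) as.raw(0L)
               else charToRaw(" "))
  head <- c(uint16le(group), uint16le(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN"))
    c(head, as.raw(c(0L, 0L)), uint32le(length(value)), value)
  else
    c(head, uint16le(length(value)), value)
}

dcmString <- function(group, elem, vr, s) {
  dcmElement(group, elem, vr, charToRaw(paste(s, collapse = "\\")))
}

dcmDS <- function(group, elem, values) {
  dcmString(group, elem, "DS", sprintf("%.10g", values))
}

dcmUS <- function(group, elem, value) {
  dcmElement(group, elem, "US", uint16le(value))
}

## 16-bit unsigned little-endian pixel payload, row-major (row by row).
grayToRaw16 <- function(gray) {
  v <- as.integer(round(t(gray)))             # t(): row-major order
  if (any(v < 0L | v > 65535L))
    stop("gray levels out of the 16-bit unsigned range")
  writeBin(ifelse(v > 32767L, v - 65536L, v), raw(), size = 2L,
           endian = "little")
}

#' Write one slice as a minimal DICOM file
#'
#' Emits a valid single-frame monochrome DICOM file (Explicit VR Little
#' Endian) carrying the slice's pose and gray matrix. Gray levels are stored
#' as 16-bit unsigned integers.
#'
#' @param slice a \linkS4class{SliceGeometry}.
#' @param path output file path.
#' @param instanceNumber integer instance number stored in the file.
#' @param uidSuffix string making the SOPInstanceUID unique in the series.
#' @return \code{path}, invisibly.
#' @export
writeDicomSlice <- function(slice, path, instanceNumber = 1L,
                            uidSuffix = as.character(instanceNumber)) {
  sopUID <- paste0(UID_ROOT, ".", uidSuffix)
  dataset <- c(
    dcmString(0x0008, 0x0016, "UI", UID_CT_STORAGE),
    dcmString(0x0008, 0x0018, "UI", sopUID),
    dcmString(0x0020, 0x0013, "IS", as.character(instanceNumber)),
    dcmDS(0x0020, 0x0032, slice@origin),
    ## ImageOrientationPatient: column direction cosines first, then row
    dcmDS(0x0020, 0x0037, c(slice@colDir, slice@rowDir)),
    dcmUS(0x0028, 0x0002, 1L),
    dcmString(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcmUS(0x0028, 0x0010, sliceRows(slice)),
    dcmUS(0x0028, 0x0011, sliceCols(slice)),
    ## PixelSpacing: spacing between rows first, then between columns
    dcmDS(0x0028, 0x0030, c(slice@spacingRow, slice@spacingCol)),
    dcmUS(0x0028, 0x0100, 16L),
    dcmUS(0x0028, 0x0101, 16L),
    dcmUS(0x0028, 0x0102, 15L),
    dcmUS(0x0028, 0x0103, 0L),
    dcmElement(0x7FE0, 0x0010, "OW", grayToRaw16(slice@gray)))
  metaBody <- c(
    dcmElement(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dcmString(0x0002, 0x0002, "UI", UID_CT_STORAGE),
    dcmString(0x0002, 0x0003, "UI", sopUID),
    dcmString(0x0002, 0x0010, "UI", UID_EXPLICIT_LE))
  meta <- c(dcmElement(0x0002, 0x0000, "UL", uint32le(length(metaBody))),
            metaBody)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), meta, dataset), con)
  invisible(path)
}

#' Write a volume as a DICOM series
#'
#' One file per slice, named \code{slice_0001.dcm, ...} in the volume's
#' slice order.
#'
#' @param volume a \linkS4class{DicomVolume}.
#' @param directory output directory (created if missing).
#' @return character vector of written file paths, invisibly.
#' @export
writeDicomSeries <- function(volume, directory) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  paths <- vapply(seq_along(volume@slices), function(k) {
    p <- file.path(directory, sprintf("slice_%04d.dcm", k))
    writeDicomSlice(volume@slices[[k]], p, instanceNumber = k)
    p
  }, character(1L))
  invisible(paths)
}
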