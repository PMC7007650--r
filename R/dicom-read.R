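## Minimal DICOM reader: single-frame uncompressed files, Explicit or
## Implicit VR Little Endian. Parses only the tags the geometry pipeline
## needs; everything else is skipped by length.

## Tags of interest, keyed "gggg,eeee" (lower case hex).
.dcmWanted <- c(
  imagePositionPatient    = "0020,0032",
  imageOrientationPatient = "0020,0037",
  pixelSpacing            = "0028,0030",
  rows                    = "0028,0010",
  columns                 = "0028,0011",
  bitsAllocated           = "0028,0100",
  pixelRepresentation     = "0028,0103",
  transferSyntax          = "0002,0010",
  pixelData               = "7fe0,0010")

.readU16 <- function(bytes, off) {
  as.integer(bytes[off]) + 256L * as.integer(bytes[off + 1L])
}

.readU32 <- function(bytes, off) {
  as.numeric(bytes[off]) + 256 * as.numeric(bytes[off + 1L]) +
    65536 * as.numeric(bytes[off + 2L]) + 16777216 * as.numeric(bytes[off + 3L])
}

## Parse one file into a named list of raw values for the wanted tags.
parseDicomFile <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  n <- length(bytes)
  off <- 1L
  if (n >= 132L && rawToChar(bytes[129:132]) == "DICM") off <- 133L
  out <- list()
  explicit <- TRUE                        # file meta group is always explicit
  metaEnd <- Inf
  vrLong <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  repeat {
    if (off + 7L > n) break
    group <- .readU16(bytes, off)
    elem <- .readU16(bytes, off + 2L)
    if (off > metaEnd && group == 2L)     # should not happen; guard anyway
      break
    inMeta <- group == 2L
    useExplicit <- explicit || inMeta
    if (useExplicit) {
      vr <- rawToChar(bytes[(off + 4L):(off + 5L)])
      if (!grepl("^[A-Z]{2}$", vr)) {
        if (inMeta)
          stop("unsupported or corrupt DICOM encoding in ", basename(path))
        explicit <- FALSE             # headerless implicit-VR dataset
        useExplicit <- FALSE
      }
    }
    if (useExplicit) {
      if (vr %in% vrLong) {
        len <- .readU32(bytes, off + 8L)
        hdr <- 12L
      } else {
        len <- .readU16(bytes, off + 6L)
        hdr <- 8L
      }
    } else {
      len <- .readU32(bytes, off + 4L)
      hdr <- 8L
    }
    if (len >= 4294967295)
      stop("undefined-length element (sequence/encapsulated data) in ",
           basename(path), ": unsupported")
    valOff <- off + hdr
    if (valOff + len - 1L > n)
      stop("truncated DICOM element in ", basename(path))
    key <- sprintf("%04x,%04x", group, elem)
    if (key %in% .dcmWanted)
      out[[names(.dcmWanted)[match(key, .dcmWanted)]]] <-
        bytes[seq.int(valOff, length.out = len)]
    if (inMeta && group == 2L && elem == 0L)
      metaEnd <- valOff + .readU32(bytes, valOff) + 3L
    if (key == "0002,0010") {
      ts <- trimws(rawToChar(out$transferSyntax[out$transferSyntax != as.raw(0L)]))
      if (ts == UID_IMPLICIT_LE) explicit <- FALSE
      else if (ts == UID_EXPLICIT_LE) explicit <- TRUE
      else stop("unsupported transfer syntax '", ts, "' in ", basename(path))
    }
    off <- valOff + len
  }
  out
}

.dcmStrings <- function(rawVal) {
  s <- rawToChar(rawVal[rawVal != as.raw(0L)])
  trimws(strsplit(s, "\\", fixed = TRUE)[[1L]])
}

.dcmNumbers <- function(rawVal) as.numeric(.dcmStrings(rawVal))

.dcmU16value <- function(rawVal) .readU16(rawVal, 1L)

## Decode PixelData into an nRows x nCols integer matrix (row-major payload).
.dcmPixels <- function(rawVal, nRows, nCols, bits, pixelRep) {
  npx <- nRows * nCols
  if (bits == 16L) {
    v <- readBin(rawVal, "integer", n = npx, size = 2L,
                 signed = FALSE, endian = "little")
    if (pixelRep == 1L) v <- ifelse(v > 32767L, v - 65536L, v)
  } else if (bits == 8L) {
    v <- as.integer(rawVal[seq_len(npx)])
  } else {
    stop("unsupported BitsAllocated: ", bits)
  }
  if (length(v) < npx) stop("pixel data shorter than Rows x Columns")
  matrix(v, nrow = nRows, ncol = nCols, byrow = TRUE)
}

#' Read one DICOM file as a positioned slice
#'
#' @param path a DICOM file (single-frame, uncompressed, little endian).
#' @return a \linkS4class{SliceGeometry}.
#' @export
readDicomSlice <- function(path) {
  el <- parseDicomFile(path)
  need <- c("imagePositionPatient", "imageOrientationPatient", "pixelSpacing",
            "rows", "columns", "pixelData")
  miss <- setdiff(need, names(el))
  if (length(miss))
    stop("DICOM file ", basename(path), " lacks required field(s): ",
         paste(miss, collapse = ", "))
  origin <- .dcmNumbers(el$imagePositionPatient)
  orient <- .dcmNumbers(el$imageOrientationPatient)
  spacing <- .dcmNumbers(el$pixelSpacing)
  if (length(origin) != 3L)
    stop("ImagePositionPatient in ", basename(path), " must have 3 values")
  if (length(orient) != 6L)
    stop("ImageOrientationPatient in ", basename(path), " must have 6 values")
  if (length(spacing) != 2L)
    stop("PixelSpacing in ", basename(path), " must have 2 values")
  nRows <- .dcmU16value(el$rows)
  nCols <- .dcmU16value(el$columns)
  bits <- if (is.null(el$bitsAllocated)) 16L else .dcmU16value(el$bitsAllocated)
  pixRep <- if (is.null(el$pixelRepresentation)) 0L
            else .dcmU16value(el$pixelRepresentation)
  gray <- .dcmPixels(el$pixelData, nRows, nCols, bits, pixRep)
  ## ImageOrientationPatient: first triplet = column direction (along a row),
  ## second = row direction; PixelSpacing: row spacing first.
  sliceGeometry(origin = origin, rowDir = orient[4:6], colDir = orient[1:3],
                spacingRow = spacing[1L], spacingCol = spacing[2L],
                gray = gray)
}
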