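## volume_io: place every pixel of a DICOM series in patient coordinates and
## expose the series as a scattered point set and, when valid, a regular grid.

#' 3D position of a pixel sample
#'
#' Pixel \code{(i, j)} (row, column; 0-based) of a slice sits at
#' \code{origin + i * spacingRow * rowDir + j * spacingCol * colDir}.
#'
#' @param slice a \linkS4class{SliceGeometry}.
#' @param i,j equal-length integer vectors of 0-based row/column indices.
#' @return \code{length(i) x 3} matrix of positions (mm).
#' @examples
#' s <- sliceGeometry(c(10, 20, 30), c(0, 1, 0), c(1, 0, 0), 0.5, 0.5,
#'                    matrix(0L, 8, 8))
#' pixelPosition(s, 2, 4)   # (12, 21, 30)
#' @export
pixelPosition <- function(slice, i, j) {
  i <- as.numeric(i); j <- as.numeric(j)
  stopifnot(length(i) == length(j))
  if (any(i < 0 | i > sliceRows(slice) - 1L) ||
      any(j < 0 | j > sliceCols(slice) - 1L))
    stop("pixel index out of range: rows 0..", sliceRows(slice) - 1L,
         ", cols 0..", sliceCols(slice) - 1L)
  cbind(slice@origin[1L] + i * slice@spacingRow * slice@rowDir[1L] +
          j * slice@spacingCol * slice@colDir[1L],
        slice@origin[2L] + i * slice@spacingRow * slice@rowDir[2L] +
          j * slice@spacingCol * slice@colDir[2L],
        slice@origin[3L] + i * slice@spacingRow * slice@rowDir[3L] +
          j * slice@spacingCol * slice@colDir[3L])
}

## All pixel positions of one slice, row index varying fastest.
slicePixelPositions <- function(slice) {
  idx <- expand.grid(i = 0:(sliceRows(slice) - 1L),
                     j = 0:(sliceCols(slice) - 1L))
  pixelPosition(slice, idx$i, idx$j)
}

## Gray levels in the same order as slicePixelPositions.
slicePixelGrays <- function(slice) as.numeric(slice@gray)

#' Regular-grid test for a slice stack
#'
#' \code{regular}: all slices share row/column directions, spacings, matrix
#' size and in-plane origin projection (tolerance 1e-6), so positioned
#' pixels form a 3D lattice. \code{uniform}: additionally the inter-slice
#' spacing is constant within a relative tolerance of 1e-3. Slices need not
#' be equidistant for trilinear interpolation: parallel-but-nonuniform
#' stacks are still regular and use each slab's actual extent.
#'
#' @param slices list of \linkS4class{SliceGeometry} (>= 2 for a meaningful
#'   answer; a single slice reports \code{regular = TRUE, uniform = TRUE}).
#' @return list with \code{regular}, \code{uniform}, and (when regular)
#'   \code{order} (slice order by normal projection), \code{zs} (normal
#'   offsets, mm) and \code{gridShape} \code{c(nCols, nRows, nSlices)}.
#' @export
isRegularGrid <- function(slices) {
  stopifnot(length(slices) >= 1L)
  ref <- slices[[1L]]
  nrm <- sliceNormal(ref)
  if (length(slices) == 1L)
    return(list(regular = TRUE, uniform = TRUE, order = 1L, zs = 0,
                gridShape = c(sliceCols(ref), sliceRows(ref), 1L)))
  tolPose <- 1e-6
  for (s in slices[-1L]) {
    if (max(abs(s@rowDir - ref@rowDir)) > tolPose ||
        max(abs(s@colDir - ref@colDir)) > tolPose ||
        abs(s@spacingRow - ref@spacingRow) > tolPose ||
        abs(s@spacingCol - ref@spacingCol) > tolPose ||
        sliceRows(s) != sliceRows(ref) || sliceCols(s) != sliceCols(ref))
      return(list(regular = FALSE, uniform = FALSE))
    d <- s@origin - ref@origin
    if (abs(sum(d * ref@rowDir)) > tolPose ||
        abs(sum(d * ref@colDir)) > tolPose)
      return(list(regular = FALSE, uniform = FALSE))
  }
  zsRaw <- unname(vapply(slices, function(s)
    sum((s@origin - ref@origin) * nrm), numeric(1L)))
  ord <- order(zsRaw)
  zs <- zsRaw[ord]
  dz <- diff(zs)
  if (any(dz <= 1e-9))                     # coincident slice planes
    return(list(regular = FALSE, uniform = FALSE))
  uniform <- (max(dz) - min(dz)) <= 1e-3 * mean(dz)
  list(regular = TRUE, uniform = uniform, order = ord, zs = zs,
       gridShape = c(sliceCols(ref), sliceRows(ref), length(slices)))
}

## Axis-aligned bounding box over all pixel positions. Positions are affine
## in (i, j), so per slice the 4 corner pixels suffice.
volumeBBox <- function(slices) {
  corners <- do.call(rbind, lapply(slices, function(s) {
    i <- c(0L, sliceRows(s) - 1L, 0L, sliceRows(s) - 1L)
    j <- c(0L, 0L, sliceCols(s) - 1L, sliceCols(s) - 1L)
    pixelPosition(s, i, j)
  }))
  c(min(corners[, 1L]), max(corners[, 1L]),
    min(corners[, 2L]), max(corners[, 2L]),
    min(corners[, 3L]), max(corners[, 3L]))
}

#' Assemble slices into a volume
#'
#' Sorts the slices by the projection of their origins onto the slice
#' normal (ties broken by \code{names(slices)}, i.e. file name), computes
#' the bounding box, and materializes the regular grid when the stack
#' qualifies.
#'
#' @param slices list of \linkS4class{SliceGeometry}, optionally named.
#' @return a \linkS4class{DicomVolume}.
#' @export
makeVolume <- function(slices) {
  stopifnot(length(slices) >= 1L)
  dims <- vapply(slices, function(s) dim(s@gray), integer(2L))
  if (length(slices) > 1L && (length(unique(dims[1L, ])) > 1L ||
                              length(unique(dims[2L, ])) > 1L))
    stop("inconsistent matrix sizes across slices: ",
         paste(unique(apply(dims, 2L, paste, collapse = "x")),
               collapse = ", "))
  nrm <- sliceNormal(slices[[1L]])
  proj <- vapply(slices, function(s) sum(s@origin * nrm), numeric(1L))
  tie <- if (!is.null(names(slices))) names(slices) else as.character(
    seq_along(slices))
  ord <- order(proj, tie)
  slices <- slices[ord]
  reg <- isRegularGrid(slices)
  vol <- new("DicomVolume", slices = slices, bbox = volumeBBox(slices),
             regular = reg$regular,
             uniform = if (reg$regular) reg$uniform else FALSE,
             frame = if (reg$regular) {
               ref <- slices[[1L]]
               cbind(ref@colDir, ref@rowDir, sliceNormal(ref))
             } else matrix(numeric(0L), 0L, 0L),
             xs = if (reg$regular)
               (0:(sliceCols(slices[[1L]]) - 1L)) * slices[[1L]]@spacingCol
             else numeric(0L),
             ys = if (reg$regular)
               (0:(sliceRows(slices[[1L]]) - 1L)) * slices[[1L]]@spacingRow
             else numeric(0L),
             zs = if (reg$regular) reg$zs else numeric(0L),
             gridValues = if (reg$regular) {
               sl <- slices[reg$order]
               array(unlist(lapply(sl, function(s) t(s@gray)),
                            use.names = FALSE),
                     dim = c(sliceCols(slices[[1L]]),
                             sliceRows(slices[[1L]]), length(sl)))
             } else array(numeric(0L), c(0L, 0L, 0L)))
  vol
}

#' Read a DICOM series into a positioned volume
#'
#' Reads every \code{.dcm} file in \code{directory} (falling back to all
#' files when none carry the extension), positions each slice in patient
#' coordinates, and assembles them into a \linkS4class{DicomVolume} sorted
#' by slice-normal projection.
#'
#' @param directory path holding one imaging series.
#' @return a \linkS4class{DicomVolume}.
#' @export
readDicomSeries <- function(directory) {
  if (!dir.exists(directory)) stop("no such directory: ", directory)
  files <- sort(list.files(directory, pattern = "\\.dcm$", ignore.case = TRUE,
                           full.names = TRUE))
  if (!length(files))
    files <- sort(list.files(directory, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (!length(files))
    stop("directory contains no readable DICOM files: ", directory)
  slices <- lapply(files, readDicomSlice)
  names(slices) <- basename(files)
  makeVolume(slices)
}

#' Read a plain-text point cloud
#'
#' Whitespace-separated text, three floats per line, millimetres.
#'
#' @param path text file path.
#' @return \code{n x 3} numeric matrix.
#' @export
readPointCloud <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 3L)
    stop("point cloud must have exactly 3 columns, found ", ncol(m))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}

#' @rdname readPointCloud
#' @param points \code{n x 3} matrix to write.
#' @export
writePointCloud <- function(points, path) {
  utils::write.table(format(points, digits = 12, trim = TRUE), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
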