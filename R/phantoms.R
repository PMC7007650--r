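## Synthetic phantom volumes: known analytic gray fields sampled by slice
## stacks with full DICOM geometry, in three pose regimes (parallel uniform,
## parallel non-uniform, non-parallel fan).

#' Construct a phantom specification
#'
#' @param field an \linkS4class{AnalyticField}.
#' @param nSlices number of slices.
#' @param matrixDim \code{c(rows, cols)} per slice.
#' @param spacing \code{c(rowSpacing, colSpacing, sliceSpacing)} mm.
#' @param poseMode \code{"parallel_uniform"} (axis-aligned equidistant
#'   stack), \code{"parallel_nonuniform"} (parallel, jittered slice gaps) or
#'   \code{"nonparallel_fan"} (pairwise non-parallel planes).
#' @param origin position (mm) of the first slice's pixel (0, 0).
#' @param seed integer; fully determines the generated volume.
#' @return a \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(field, nSlices = 16L, matrixDim = c(32L, 32L),
                        spacing = c(1, 1, 2), poseMode = "parallel_uniform",
                        origin = c(0, 0, 0), seed = 1L) {
  new("PhantomSpec", field = field, nSlices = as.integer(nSlices),
      matrixDim = as.integer(matrixDim), spacing = as.numeric(spacing),
      poseMode = poseMode, origin = as.numeric(origin),
      seed = as.integer(seed))
}

## Slice poses for a spec: list of list(origin, rowDir, colDir). All
## randomness (gap jitter, fan angles) flows from the spec seed.
phantomPoses <- function(spec) {
  n <- spec@nSlices
  dz <- spec@spacing[3L]
  withSeed(spec@seed, {
    switch(spec@poseMode,
      parallel_uniform = lapply(seq_len(n) - 1L, function(k)
        list(origin = spec@origin + c(0, 0, k * dz),
             rowDir = c(0, 1, 0), colDir = c(1, 0, 0))),
      parallel_nonuniform = {
        gaps <- dz * stats::runif(n - 1L, 0.5, 1.5)
        zs <- c(0, cumsum(gaps))
        lapply(seq_len(n), function(k)
          list(origin = spec@origin + c(0, 0, zs[k]),
               rowDir = c(0, 1, 0), colDir = c(1, 0, 0)))
      },
      nonparallel_fan = {
        ## planes rotated about the y axis by distinct angles: tilt the
        ## column direction and the advance direction together
        base <- pi / 36                      # 5 degrees between slices
        ang <- (seq_len(n) - 1L) * base +
          stats::runif(n, -base / 8, base / 8)
        lapply(seq_len(n), function(k) {
          ca <- cos(ang[k]); sa <- sin(ang[k])
          list(origin = spec@origin +
                 c(dz * (k - 1L) * sa, 0, dz * (k - 1L) * ca),
               rowDir = c(0, 1, 0), colDir = c(ca, 0, -sa))
        })
      },
      stop("unknown poseMode: ", spec@poseMode))
  })
}

#' Generate a synthetic phantom volume
#'
#' Each slice's gray matrix is the analytic field sampled at
#' \code{pixelPosition} of every (i, j), rounded to integer and clamped to
#' the field's value range. The same spec (including seed) always produces
#' an identical volume.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param directory optional: also write the volume as a DICOM series plus a
#'   JSON sidecar recording the spec.
#' @return a \linkS4class{DicomVolume}.
#' @examples
#' vol <- generatePhantom(phantomSpec(trilinearRampField(), nSlices = 4L,
#'                                    matrixDim = c(8L, 8L)))
#' vol
#' @export
generatePhantom <- function(spec, directory = NULL) {
  poses <- phantomPoses(spec)
  nr <- spec@matrixDim[1L]; nc <- spec@matrixDim[2L]
  slices <- lapply(poses, function(po) {
    s <- sliceGeometry(po$origin, po$rowDir, po$colDir,
                       spec@spacing[1L], spec@spacing[2L],
                       matrix(0L, nr, nc))
    g <- round(groundTruthGray(spec@field, slicePixelPositions(s)))
    s@gray <- matrix(as.integer(g), nr, nc)   # row index fastest, as sampled
    s
  })
  vol <- makeVolume(slices)
  if (!is.null(directory)) {
    writeDicomSeries(vol, directory)
    jsonlite::write_json(phantomSpecToList(spec),
                         file.path(directory, "phantom_spec.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  vol
}

## JSON-serializable description of a spec (sidecar for reproducibility).
phantomSpecToList <- function(spec) {
  serializable <- lapply(spec@field@params, function(x) {
    if (is(x, "BezierCurve")) x@controlPoints
    else if (is.function(x)) NULL
    else x
  })
  serializable <- serializable[!vapply(serializable, is.null, logical(1L))]
  serializable$samples <- NULL               # derivable from the curve
  serializable$tDense <- NULL
  list(kind = spec@field@kind,
       fieldParams = serializable,
       valueRange = spec@field@valueRange,
       nSlices = spec@nSlices, matrixDim = spec@matrixDim,
       spacing = spec@spacing, poseMode = spec@poseMode,
       origin = spec@origin, seed = spec@seed)
}
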