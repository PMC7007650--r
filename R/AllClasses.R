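## Central S4 data objects. All positions are DICOM patient coordinates in
## millimetres; pixel indices (i, j) = (row, column) are 0-based and the
## pixel's sample sits exactly at its positioned point.

#' One DICOM slice's pose and gray matrix
#'
#' @slot origin ImagePositionPatient: 3D position (mm) of pixel (0, 0).
#' @slot rowDir unit vector along increasing row index.
#' @slot colDir unit vector along increasing column index.
#' @slot spacingRow,spacingCol pixel spacing (mm) between adjacent rows /
#'   columns.
#' @slot gray \code{nRows x nCols} integer matrix of gray levels, stored as
#'   read (no rescale slope/intercept applied).
#' @export
setClass("SliceGeometry",
         representation(origin = "numeric", rowDir = "numeric",
                        colDir = "numeric", spacingRow = "numeric",
                        spacingCol = "numeric", gray = "matrix"),
         validity = function(object) {
           msgs <- character()
           if (length(object@origin) != 3L || any(!is.finite(object@origin)))
             msgs <- c(msgs, "origin must be a finite 3-vector")
           for (nm in c("rowDir", "colDir")) {
             d <- slot(object, nm)
             if (length(d) != 3L || abs(vnorm(d) - 1) > 1e-6)
               msgs <- c(msgs, paste(nm, "must be a unit 3-vector (tol 1e-6)"))
           }
           if (length(object@rowDir) == 3L && length(object@colDir) == 3L &&
               abs(sum(object@rowDir * object@colDir)) > 1e-6)
             msgs <- c(msgs, "rowDir and colDir must be orthogonal (tol 1e-6)")
           if (object@spacingRow <= 0 || object@spacingCol <= 0)
             msgs <- c(msgs, "pixel spacings must be positive")
           if (!is.numeric(object@gray) || any(dim(object@gray) < 1L))
             msgs <- c(msgs, "gray must be a non-empty numeric matrix")
           if (length(msgs)) msgs else TRUE
         })

#' @rdname SliceGeometry-class
#' @param origin,rowDir,colDir,spacingRow,spacingCol,gray see slots.
#' @return a \linkS4class{SliceGeometry}.
#' @export
sliceGeometry <- function(origin, rowDir, colDir, spacingRow, spacingCol,
                          gray) {
  new("SliceGeometry", origin = as.numeric(origin),
      rowDir = as.numeric(rowDir), colDir = as.numeric(colDir),
      spacingRow = as.numeric(spacingRow), spacingCol = as.numeric(spacingCol),
      gray = gray)
}

#' Number of rows / columns of a slice
#' @param slice a \linkS4class{SliceGeometry}.
#' @export
sliceRows <- function(slice) nrow(slice@gray)

#' @rdname sliceRows
#' @export
sliceCols <- function(slice) ncol(slice@gray)

#' Slice normal (rowDir x colDir)
#' @param slice a \linkS4class{SliceGeometry}.
#' @export
sliceNormal <- function(slice) unit3(cross3(slice@rowDir, slice@colDir))

setMethod("show", "SliceGeometry", function(object) {
  cat(sprintf("SliceGeometry %d x %d, spacing %.4g x %.4g mm\n",
              sliceRows(object), sliceCols(object),
              object@spacingRow, object@spacingCol))
  cat("  origin:", paste(signif(object@origin, 6), collapse = ", "), "mm\n")
})

#' An ordered DICOM slice collection with its 3D bounding box
#'
#' \code{regular} means all slices share pose (parallel, identical in-plane
#' geometry) so the positioned pixels form a grid; \code{uniform}
#' additionally means constant inter-slice spacing. Trilinear interpolation
#' requires \code{regular} (it copes with non-uniform slice spacing);
#' non-parallel stacks are served by the nearest-neighbor painter.
#'
#' @slot slices list of \linkS4class{SliceGeometry}, sorted by the projection
#'   of the origin onto the slice normal (file-name ties broken
#'   lexicographically).
#' @slot bbox \code{(x0, x1, y0, y1, z0, z1)} enclosing every pixel (mm).
#' @slot regular,uniform logical flags (see above).
#' @slot frame when regular: 3x3 matrix with columns colDir, rowDir, normal.
#' @slot xs,ys,zs when regular: lattice coordinates (mm) along colDir,
#'   rowDir and the normal, relative to the first slice's origin.
#' @slot gridValues when regular: \code{(nCols, nRows, nSlices)} array of
#'   gray levels (grid shape (nx, ny, nz)).
#' @export
setClass("DicomVolume",
         representation(slices = "list", bbox = "numeric",
                        regular = "logical", uniform = "logical",
                        frame = "matrix", xs = "numeric", ys = "numeric",
                        zs = "numeric", gridValues = "array"),
         validity = function(object) {
           msgs <- character()
           if (!length(object@slices))
             msgs <- c(msgs, "a volume needs at least one slice")
           if (length(object@bbox) != 6L)
             msgs <- c(msgs, "bbox must have 6 entries")
           else if (any(object@bbox[c(1, 3, 5)] > object@bbox[c(2, 4, 6)]))
             msgs <- c(msgs, "bbox must satisfy x0<=x1, y0<=y1, z0<=z1")
           if (length(msgs)) msgs else TRUE
         })

setMethod("show", "DicomVolume", function(object) {
  s1 <- object@slices[[1L]]
  cat(sprintf("DicomVolume: %d slice(s) of %d x %d (%s%s)\n",
              length(object@slices), sliceRows(s1), sliceCols(s1),
              if (object@regular) "regular grid" else "non-parallel stack",
              if (object@regular && !object@uniform)
                ", non-uniform slice spacing" else ""))
  b <- object@bbox
  cat(sprintf("  bbox (mm): [%.4g, %.4g] x [%.4g, %.4g] x [%.4g, %.4g]\n",
              b[1], b[2], b[3], b[4], b[5], b[6]))
  cat(sprintf("  data points: %.0f\n", nDataPoints(object)))
})

#' @describeIn DicomVolume-class total positioned pixels across all slices.
#' @export
setMethod("nDataPoints", "DicomVolume", function(x)
  sum(vapply(x@slices, function(s) prod(dim(s@gray)), numeric(1L))))

#' @describeIn DicomVolume-class the enclosing axis-aligned box (mm).
#' @export
setMethod("bbox", "DicomVolume", function(x) x@bbox)

#' Sub-box partition of a volume's data points
#'
#' The volume's axis-aligned bounding box is tiled by
#' \code{prod(divisions)} congruent sub-boxes; every data point lands in
#' exactly one bucket (half-open intervals, upper boundary closed on the
#' last sub-box). Works for arbitrarily posed (non-parallel) slices.
#'
#' @slot bbox numeric length-6 bounding box (mm).
#' @slot divisions integer length-3: sub-box counts per axis.
#' @slot points \code{N x 3} matrix of data-point positions (mm).
#' @slot gray length-N gray levels.
#' @slot buckets list over sub-boxes of integer index vectors into
#'   \code{points} (insertion order preserved).
#' @export
setClass("SubBoxPartition",
         representation(bbox = "numeric", divisions = "integer",
                        points = "matrix", gray = "numeric",
                        buckets = "list"),
         validity = function(object) {
           msgs <- character()
           if (length(object@divisions) != 3L || any(object@divisions < 1L))
             msgs <- c(msgs, "divisions must be 3 positive counts")
           if (length(object@buckets) != prod(object@divisions))
             msgs <- c(msgs, "bucket list length must equal prod(divisions)")
           if (sum(lengths(object@buckets)) != nrow(object@points))
             msgs <- c(msgs, "bucket sizes must sum to the data-point count")
           if (length(msgs)) msgs else TRUE
         })

#' Number of sub-boxes in a partition
#' @param partition a \linkS4class{SubBoxPartition}.
#' @export
subBoxCount <- function(partition) prod(partition@divisions)

setMethod("show", "SubBoxPartition", function(object) {
  cat(sprintf("SubBoxPartition: %d x %d x %d = %d sub-boxes, %d data points\n",
              object@divisions[1L], object@divisions[2L],
              object@divisions[3L], subBoxCount(object),
              nrow(object@points)))
  cat(sprintf("  empty sub-boxes: %d\n",
              sum(lengths(object@buckets) == 0L)))
})

#' @describeIn SubBoxPartition-class the partitioned bounding box.
#' @export
setMethod("bbox", "SubBoxPartition", function(x) x@bbox)

#' Virtual parametric surface: a map from the unit square to 3D (mm)
#' @export
setClass("ParametricSurface", representation("VIRTUAL"))

#' Patch of an ellipsoid of revolution, with radial offset
#'
#' Parametrized by longitude \code{u} (full turn) and latitude \code{v}
#' (equator at \code{v = 0} towards the selected pole). A radial offset
#' \code{delta} changes every latitude circle's radius about the axis by a
#' constant while keeping the axial coordinate; negative total offsets clip
#' the latitude domain to circles of positive radius.
#'
#' @slot center 3D center (mm).
#' @slot axis unit revolution axis.
#' @slot a semi-axis along the axis (mm).
#' @slot b equatorial semi-axis (mm).
#' @slot hemisphere +1 or -1: which half (side of the equatorial plane along
#'   \code{axis}) the patch covers.
#' @slot delta accumulated radial offset (mm).
#' @export
setClass("EllipsoidPatch", contains = "ParametricSurface",
         representation(center = "numeric", axis = "numeric", a = "numeric",
                        b = "numeric", hemisphere = "numeric",
                        delta = "numeric"),
         validity = function(object) {
           msgs <- character()
           if (length(object@center) != 3L)
             msgs <- c(msgs, "center must be a 3-vector")
           if (length(object@axis) != 3L || abs(vnorm(object@axis) - 1) > 1e-6)
             msgs <- c(msgs, "axis must be a unit 3-vector")
           if (object@a <= 0 || object@b <= 0)
             msgs <- c(msgs, "semi-axes a, b must be positive")
           if (!object@hemisphere %in% c(-1, 1))
             msgs <- c(msgs, "hemisphere must be +1 or -1")
           if (object@b + object@delta <= 0)
             msgs <- c(msgs, "radial offset collapses the equator circle")
           if (length(msgs)) msgs else TRUE
         })

setMethod("show", "EllipsoidPatch", function(object) {
  cat(sprintf(
    "EllipsoidPatch: a = %.4g, b = %.4g mm, hemisphere %+d, offset %.4g mm\n",
    object@a, object@b, as.integer(object@hemisphere), object@delta))
  cat("  center:", paste(signif(object@center, 6), collapse = ", "),
      " axis:", paste(signif(object@axis, 4), collapse = ", "), "\n")
})

#' Ruled surface x(t, u) = c(t) + u r(t) along a space curve
#'
#' @slot directrix the base \linkS4class{SpaceCurve} c(t).
#' @slot ruling function of scalar t returning the unit ruling direction
#'   r(t).
#' @slot rulingDot analytic derivative of the ruling, or \code{NULL}
#'   (finite differences used).
#' @slot extent \code{c(uMin, uMax)} in mm along the unit ruling.
#' @slot construction one of \code{"cylinder"}, \code{"envelope"},
#'   \code{"rectifying"}, \code{"custom"}.
#' @export
setClass("RuledSurface", contains = "ParametricSurface",
         representation(directrix = "SpaceCurve", ruling = "function",
                        rulingDot = "ANY", extent = "numeric",
                        construction = "character"),
         validity = function(object) {
           msgs <- character()
           if (length(object@extent) != 2L ||
               object@extent[1L] >= object@extent[2L])
             msgs <- c(msgs, "extent must be c(uMin, uMax) with uMin < uMax")
           if (length(msgs)) msgs else TRUE
         })

setMethod("show", "RuledSurface", function(object) {
  cat(sprintf("RuledSurface (%s construction), ruling extent [%.4g, %.4g] mm\n",
              object@construction, object@extent[1L], object@extent[2L]))
})

#' A discretized, painted surface
#'
#' @slot u,v parameter grids in \code{[0,1]}.
#' @slot points3d \code{(nU, nV, 3)} array of 3D sample positions (mm).
#' @slot gray \code{nU x nV} matrix; uninformed samples carry -1.
#' @slot informed \code{nU x nV} logical: FALSE where the sample's sub-box
#'   holds no data point or the sample lies outside the volume.
#' @slot method \code{"trilinear"} or \code{"nearest"}.
#' @export
setClass("TexturedSurface",
         representation(u = "numeric", v = "numeric", points3d = "array",
                        gray = "matrix", informed = "matrix",
                        method = "character"),
         validity = function(object) {
           msgs <- character()
           sh <- c(length(object@u), length(object@v))
           if (!all(dim(object@points3d) == c(sh, 3L)))
             msgs <- c(msgs, "points3d must be (nU, nV, 3)")
           if (!all(dim(object@gray) == sh) || !all(dim(object@informed) == sh))
             msgs <- c(msgs, "gray and informed must be nU x nV")
           if (any(object@gray[!object@informed] != -1))
             msgs <- c(msgs, "uninformed samples must carry sentinel gray -1")
           if (length(msgs)) msgs else TRUE
         })

setMethod("show", "TexturedSurface", function(object) {
  cat(sprintf("TexturedSurface %d x %d (%s), %d uninformed sample(s)\n",
              length(object@u), length(object@v), object@method,
              uninformedCount(object)))
})

#' Count of uninformed samples of a textured surface or flattened sheet
#' @param x a \linkS4class{TexturedSurface} or \linkS4class{FlattenedSheet}.
#' @export
uninformedCount <- function(x) sum(!x@informed)

#' Planar development of a curve (turning-angle form)
#'
#' @slot t parameter grid.
#' @slot phi turning angle per sample (radians), continuous (unwrapped).
#' @slot planePoints \code{n x 2} planar positions (mm).
#' @slot speed v(t) per sample (mm per unit parameter).
#' @export
setClass("DevelopedCurve",
         representation(t = "numeric", phi = "numeric",
                        planePoints = "matrix", speed = "numeric"),
         validity = function(object) {
           n <- length(object@t)
           if (length(object@phi) != n || length(object@speed) != n ||
               !all(dim(object@planePoints) == c(n, 2L)))
             return("t, phi, speed and planePoints must share length")
           if (any(diff(object@t) <= 0))
             return("t must be strictly increasing")
           TRUE
         })

setMethod("show", "DevelopedCurve", function(object) {
  cat(sprintf("DevelopedCurve: %d samples, planar arc length %.6g mm\n",
              length(object@t),
              sum(rowNorms(diff(object@planePoints)))))
})

#' Isometric planar development of a textured ruled surface
#'
#' @slot planeGrid \code{(nU, nV, 2)} planar positions of the (t, u) grid.
#' @slot gray,informed carried from the source \linkS4class{TexturedSurface}.
#' @slot u,v the source parameter grids.
#' @export
setClass("FlattenedSheet",
         representation(planeGrid = "array", gray = "matrix",
                        informed = "matrix", u = "numeric", v = "numeric"),
         validity = function(object) {
           sh <- c(length(object@u), length(object@v))
           if (!all(dim(object@planeGrid) == c(sh, 2L)))
             return("planeGrid must be (nU, nV, 2)")
           if (!all(dim(object@gray) == sh) || !all(dim(object@informed) == sh))
             return("gray and informed must match the grid shape")
           TRUE
         })

setMethod("show", "FlattenedSheet", function(object) {
  rngx <- range(object@planeGrid[, , 1L])
  rngy <- range(object@planeGrid[, , 2L])
  cat(sprintf(
    "FlattenedSheet %d x %d, planar extent %.4g x %.4g mm\n",
    length(object@u), length(object@v), diff(rngx), diff(rngy)))
})

#' Analytic gray-level field of a phantom
#'
#' @slot kind one of \code{"trilinear_ramp"}, \code{"bright_shell_with_defects"},
#'   \code{"bright_tube_with_bulge"}, \code{"dental_arch"}.
#' @slot params kind-specific parameter list.
#' @slot valueRange integer gray bounds the field clamps into.
#' @export
setClass("AnalyticField",
         representation(kind = "character", params = "list",
                        valueRange = "numeric"),
         validity = function(object) {
           kinds <- c("trilinear_ramp", "bright_shell_with_defects",
                      "bright_tube_with_bulge", "dental_arch")
           if (!object@kind %in% kinds)
             return(paste("kind must be one of:", paste(kinds, collapse = ", ")))
           if (length(object@valueRange) != 2L ||
               object@valueRange[1L] >= object@valueRange[2L])
             return("valueRange must be c(lo, hi) with lo < hi")
           TRUE
         })

setMethod("show", "AnalyticField", function(object) {
  cat(sprintf("AnalyticField '%s', gray range [%d, %d]\n", object@kind,
              object@valueRange[1L], object@valueRange[2L]))
})

#' Specification of a synthetic phantom volume
#'
#' @slot field the \linkS4class{AnalyticField} sampled by the slices.
#' @slot nSlices number of slices.
#' @slot matrixDim \code{c(rows, cols)} per slice.
#' @slot spacing \code{c(rowSpacing, colSpacing, sliceSpacing)} in mm.
#' @slot poseMode \code{"parallel_uniform"}, \code{"parallel_nonuniform"} or
#'   \code{"nonparallel_fan"}.
#' @slot origin 3D position of the first slice's pixel (0, 0) (mm).
#' @slot seed integer fully determining the generated volume.
#' @export
setClass("PhantomSpec",
         representation(field = "AnalyticField", nSlices = "integer",
                        matrixDim = "integer", spacing = "numeric",
                        poseMode = "character", origin = "numeric",
                        seed = "integer"),
         validity = function(object) {
           msgs <- character()
           if (object@nSlices < 1L) msgs <- c(msgs, "nSlices must be >= 1")
           if (length(object@matrixDim) != 2L || any(object@matrixDim < 2L))
             msgs <- c(msgs, "matrixDim must be c(rows, cols), each >= 2")
           if (length(object@spacing) != 3L || any(object@spacing <= 0))
             msgs <- c(msgs, "spacing must be 3 positive mm values")
           if (!object@poseMode %in% c("parallel_uniform",
                                       "parallel_nonuniform",
                                       "nonparallel_fan"))
             msgs <- c(msgs, "unknown poseMode")
           if (length(msgs)) msgs else TRUE
         })

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d slice(s) of %d x %d, pose '%s', seed %d\n",
              object@nSlices, object@matrixDim[1L], object@matrixDim[2L],
              object@poseMode, object@seed))
})
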