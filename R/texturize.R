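## Texturization: assign gray levels to surface samples from the volume,
## either by trilinear interpolation on the data-point lattice (Eq. form
## with the eight sub-box corner grays) or by the sub-box nearest-neighbor
## rule on arbitrarily scattered data points.

## Local lattice coordinates of query points in a regular volume's frame.
volumeLocalCoords <- function(volume, p) {
  q <- sweep(p, 2L, volume@slices[[1L]]@origin)
  q %*% volume@frame                        # columns: colDir, rowDir, normal
}

#' Trilinear gray-level interpolation
#'
#' Locates the unique data-point sub-box containing each query point,
#' computes local coordinates \code{alpha, beta, gamma} in \code{[0, 1]}
#' from the sub-box's actual extents (slices need not be equidistant) and
#' blends the eight corner gray levels with the trilinear weights
#' \code{(1-alpha)(1-beta)(1-gamma) ... alpha beta gamma}.
#'
#' @param volume a regular \linkS4class{DicomVolume} (parallel slices).
#' @param p a 3-vector or \code{n x 3} matrix of query positions (mm).
#' @param outside \code{"error"}: signal an out-of-volume condition for any
#'   query outside the pixel lattice; \code{"na"}: return \code{NA} there.
#' @return numeric vector of interpolated gray values.
#' @export
trilinearGray <- function(volume, p, outside = c("error", "na")) {
  outside <- match.arg(outside)
  if (!volume@regular)
    stop(nonRegularError(
      "trilinear interpolation requires a regular (parallel-slice) volume; use the nearest-neighbor painter"))
  if (is.null(dim(p))) p <- matrix(p, ncol = 3L)
  loc <- volumeLocalCoords(volume, p)
  xs <- volume@xs; ys <- volume@ys; zs <- volume@zs
  gv <- volume@gridValues
  tol <- 1e-9
  out <- rep(NA_real_, nrow(p))
  locCell <- function(x, brk) {
    x <- ifelse(abs(x - brk[1L]) < tol, brk[1L], x)
    x <- ifelse(abs(x - brk[length(brk)]) < tol, brk[length(brk)], x)
    i <- findInterval(x, brk, rightmost.closed = TRUE)
    i[x < brk[1L] | x > brk[length(brk)]] <- NA_integer_
    list(i = i, x = x)
  }
  cx <- locCell(loc[, 1L], xs)
  cy <- locCell(loc[, 2L], ys)
  cz <- if (length(zs) > 1L) locCell(loc[, 3L], zs) else {
    z <- loc[, 3L]
    list(i = ifelse(abs(z) < 1e-6, 1L, NA_integer_), x = z)
  }
  ok <- !is.na(cx$i) & !is.na(cy$i) & !is.na(cz$i)
  if (any(!ok) && outside == "error")
    stop(outOfVolumeError(sprintf(
      "%d query point(s) outside the volume lattice", sum(!ok))))
  if (any(ok)) {
    ix <- cx$i[ok]; iy <- cy$i[ok]
    singleSlice <- length(zs) == 1L
    iz <- if (singleSlice) rep(1L, sum(ok)) else cz$i[ok]
    a <- (cx$x[ok] - xs[ix]) / (xs[ix + 1L] - xs[ix])
    b <- (cy$x[ok] - ys[iy]) / (ys[iy + 1L] - ys[iy])
    g <- if (singleSlice) rep(0, sum(ok))
         else (cz$x[ok] - zs[iz]) / (zs[iz + 1L] - zs[iz])
    dx <- dim(gv)[1L]; dy <- dim(gv)[2L]
    izp <- if (singleSlice) iz else iz + 1L
    at <- function(i, j, k) gv[cbind(i, j, k)]
    val <-
      (1 - a) * (1 - b) * (1 - g) * at(ix, iy, iz) +
      a       * (1 - b) * (1 - g) * at(pmin(ix + 1L, dx), iy, iz) +
      (1 - a) * b       * (1 - g) * at(ix, pmin(iy + 1L, dy), iz) +
      a       * b       * (1 - g) * at(pmin(ix + 1L, dx), pmin(iy + 1L, dy), iz) +
      (1 - a) * (1 - b) * g * at(ix, iy, izp) +
      a       * (1 - b) * g * at(pmin(ix + 1L, dx), iy, izp) +
      (1 - a) * b       * g * at(ix, pmin(iy + 1L, dy), izp) +
      a       * b       * g * at(pmin(ix + 1L, dx), pmin(iy + 1L, dy), izp)
    out[ok] <- val
  }
  out
}

## Sub-box index (1-based, column-major over x, y, z) of points in a bbox.
## Half-open intervals; the upper boundary closes the last sub-box.
subBoxIndex <- function(p, bb, divisions) {
  tol <- 1e-9
  idx1 <- function(x, lo, hi, m) {
    w <- hi - lo
    i <- if (w <= 0) rep(0L, length(x)) else floor((x - lo) / w * m)
    i <- pmin(as.integer(i), m - 1L)        # close the upper boundary
    i[x < lo - tol | x > hi + tol] <- NA_integer_
    pmax(i, 0L)
  }
  ix <- idx1(p[, 1L], bb[1L], bb[2L], divisions[1L])
  iy <- idx1(p[, 2L], bb[3L], bb[4L], divisions[2L])
  iz <- idx1(p[, 3L], bb[5L], bb[6L], divisions[3L])
  ix + divisions[1L] * (iy + divisions[2L] * iz) + 1L
}

#' Partition scattered data points into sub-boxes
#'
#' @param points \code{N x 3} matrix of data-point positions (mm).
#' @param gray length-N gray levels.
#' @param divisions sub-box counts per axis (length 1 is recycled).
#' @param bb bounding box; defaults to the componentwise point range.
#' @return a \linkS4class{SubBoxPartition}.
#' @export
pointPartition <- function(points, gray, divisions, bb = NULL) {
  points <- as.matrix(points)
  divisions <- as.integer(rep_len(divisions, 3L))
  stopifnot(ncol(points) == 3L, length(gray) == nrow(points),
            all(divisions >= 1L))
  if (is.null(bb))
    bb <- c(min(points[, 1L]), max(points[, 1L]),
            min(points[, 2L]), max(points[, 2L]),
            min(points[, 3L]), max(points[, 3L]))
  id <- subBoxIndex(points, bb, divisions)
  if (anyNA(id))
    stop("data point(s) outside the bounding box")
  buckets <- split(seq_len(nrow(points)),
                   factor(id, levels = seq_len(prod(divisions))))
  names(buckets) <- NULL
  new("SubBoxPartition", bbox = as.numeric(bb), divisions = divisions,
      points = points, gray = as.numeric(gray), buckets = buckets)
}

#' Partition a volume's data points into sub-boxes
#'
#' Places every positioned pixel of every slice into exactly one sub-box of
#' the volume's bounding box. Makes no assumption about slice parallelism,
#' so it serves arbitrarily posed stacks.
#'
#' @param volume a \linkS4class{DicomVolume}.
#' @param divisions sub-box counts per axis (length 1 is recycled to 3).
#' @return a \linkS4class{SubBoxPartition}.
#' @examples
#' vol <- generatePhantom(phantomSpec(trilinearRampField(), nSlices = 3L,
#'                                    matrixDim = c(8L, 8L)))
#' subBoxCount(buildPartition(vol, 17L))   # 4913
#' @export
buildPartition <- function(volume, divisions) {
  pts <- do.call(rbind, lapply(volume@slices, slicePixelPositions))
  gr <- unlist(lapply(volume@slices, slicePixelGrays), use.names = FALSE)
  pointPartition(pts, gr, divisions, bb = volume@bbox)
}

## Offsets of the 26 neighboring sub-boxes plus self, as index triples.
.neighborOffsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))

#' Nearest-neighbor gray lookup within a point's own sub-box
#'
#' Returns the gray level of the Euclidean-nearest data point inside the
#' query's sub-box only; when that sub-box holds no data point the sample
#' is uninformed (sentinel gray -1). Distance ties break to the lowest
#' data-point insertion index. \code{extended = TRUE} is an extension beyond
#' the plain rule: it also searches the 26 adjacent sub-boxes.
#'
#' @param partition a \linkS4class{SubBoxPartition}.
#' @param p a 3-vector or \code{n x 3} matrix of query positions (mm).
#' @param extended search the 26 neighboring sub-boxes too (default off).
#' @param outside \code{"error"} or \code{"na"} for queries outside the
#'   partition's bounding box (an \code{NA} query is uninformed).
#' @return list with numeric \code{gray} (-1 where uninformed) and logical
#'   \code{informed}.
#' @export
nearestNeighborGray <- function(partition, p, extended = FALSE,
                                outside = c("error", "na")) {
  outside <- match.arg(outside)
  if (is.null(dim(p))) p <- matrix(p, ncol = 3L)
  id <- subBoxIndex(p, partition@bbox, partition@divisions)
  if (anyNA(id) && outside == "error")
    stop(outOfVolumeError(sprintf(
      "%d query point(s) outside the partition's bounding box",
      sum(is.na(id)))))
  m <- partition@divisions
  gray <- rep(-1, nrow(p))
  informed <- rep(FALSE, nrow(p))
  for (k in seq_len(nrow(p))) {
    if (is.na(id[k])) next
    cand <- partition@buckets[[id[k]]]
    if (extended) {
      i0 <- (id[k] - 1L) %% m[1L]
      rest <- (id[k] - 1L) %/% m[1L]
      j0 <- rest %% m[2L]
      k0 <- rest %/% m[2L]
      ii <- i0 + .neighborOffsets[, 1L]
      jj <- j0 + .neighborOffsets[, 2L]
      kk <- k0 + .neighborOffsets[, 3L]
      okn <- ii >= 0L & ii < m[1L] & jj >= 0L & jj < m[2L] &
        kk >= 0L & kk < m[3L]
      ids <- ii[okn] + m[1L] * (jj[okn] + m[2L] * kk[okn]) + 1L
      cand <- sort(unlist(partition@buckets[ids], use.names = FALSE))
    }
    if (!length(cand)) next
    d <- sweep(partition@points[cand, , drop = FALSE], 2L, p[k, ])
    best <- cand[which.min(rowSums(d * d))]   # first match = lowest index
    gray[k] <- partition@gray[best]
    informed[k] <- TRUE
  }
  list(gray = gray, informed = informed)
}

#' Paint a parametric surface from a volume
#'
#' Samples the unit square on an \code{nU x nV} grid, evaluates the 3D
#' sample positions and assigns each a gray level by the chosen painter.
#' Samples outside the volume (or in empty sub-boxes for the nearest
#' method) are marked uninformed rather than clamped.
#'
#' @param surface a \linkS4class{ParametricSurface}.
#' @param volume a \linkS4class{DicomVolume}.
#' @param method \code{"trilinear"} (regular volumes only) or
#'   \code{"nearest"}.
#' @param resolution \code{c(nU, nV)} sample counts.
#' @param divisions sub-box counts for the nearest method (required there).
#' @param partition optional prebuilt \linkS4class{SubBoxPartition}
#'   (overrides \code{divisions}).
#' @param extended passed to \code{\link{nearestNeighborGray}}.
#' @return a \linkS4class{TexturedSurface}.
#' @export
texturizeSurface <- function(surface, volume, method = c("trilinear",
                                                         "nearest"),
                             resolution = c(64L, 64L), divisions = NULL,
                             partition = NULL, extended = FALSE) {
  method <- match.arg(method)
  stopifnot(length(resolution) == 2L, all(resolution >= 2L))
  u <- seq(0, 1, length.out = resolution[1L])
  v <- seq(0, 1, length.out = resolution[2L])
  gridUV <- expand.grid(u = u, v = v)       # u varies fastest
  pts <- evalSurface(surface, gridUV$u, gridUV$v)
  if (method == "trilinear") {
    g <- trilinearGray(volume, pts, outside = "na")
    informed <- !is.na(g)
    g[!informed] <- -1
  } else {
    if (is.null(partition)) {
      if (is.null(divisions))
        stop("the nearest method needs 'divisions' (or a prebuilt partition)")
      partition <- buildPartition(volume, divisions)
    }
    nn <- nearestNeighborGray(partition, pts, extended = extended,
                              outside = "na")
    g <- nn$gray
    informed <- nn$informed
  }
  new("TexturedSurface", u = u, v = v,
      points3d = array(pts, dim = c(length(u), length(v), 3L)),
      gray = matrix(g, length(u), length(v)),
      informed = matrix(informed, length(u), length(v)),
      method = method)
}
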