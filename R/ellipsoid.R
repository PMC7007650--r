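## Ellipsoids of revolution: patch parametrization, radial offsets, and
## nonlinear least-squares fitting to point clouds (e.g. humerus-head
## surface points).

#' Construct an ellipsoid-of-revolution patch
#'
#' @param center 3D center (mm).
#' @param axis revolution axis (normalized internally).
#' @param a semi-axis along the axis (mm).
#' @param b equatorial semi-axis (mm).
#' @param hemisphere +1 or -1: which half along the axis the patch covers.
#' @param delta radial offset (mm); see \code{\link{offsetRevolution}}.
#' @return an \linkS4class{EllipsoidPatch}.
#' @export
ellipsoidPatch <- function(center, axis, a, b, hemisphere = 1, delta = 0) {
  new("EllipsoidPatch", center = as.numeric(center), axis = unit3(axis),
      a = as.numeric(a), b = as.numeric(b),
      hemisphere = as.numeric(hemisphere), delta = as.numeric(delta))
}

## Maximal latitude of the patch: the full quarter turn, clipped to circles
## of positive radius when the accumulated radial offset is negative.
patchLambdaMax <- function(surface) {
  if (surface@delta >= 0) pi / 2
  else acos(min(1, -surface@delta / surface@b))
}

#' @describeIn evalSurface longitude \code{u} (full turn), latitude \code{v}
#'   (equator at \code{v = 0} towards the selected pole); latitude circles
#'   have radius \code{b cos(lambda) + delta} about the axis.
#' @export
setMethod("evalSurface", "EllipsoidPatch", function(surface, u, v) {
  stopifnot(length(u) == length(v))
  fr <- orthoFrame(surface@axis)
  th <- 2 * pi * u
  la <- patchLambdaMax(surface) * v
  rad <- surface@b * cos(la) + surface@delta
  h <- surface@hemisphere * surface@a * sin(la)
  cbind(surface@center[1L] + rad * (cos(th) * fr$f1[1L] +
          sin(th) * fr$f2[1L]) + h * surface@axis[1L],
        surface@center[2L] + rad * (cos(th) * fr$f1[2L] +
          sin(th) * fr$f2[2L]) + h * surface@axis[2L],
        surface@center[3L] + rad * (cos(th) * fr$f1[3L] +
          sin(th) * fr$f2[3L]) + h * surface@axis[3L])
})

#' @describeIn surfaceUVPartials analytic partials of the revolution patch.
#' @export
setMethod("surfaceUVPartials", "EllipsoidPatch", function(surface, u, v) {
  stopifnot(length(u) == length(v))
  fr <- orthoFrame(surface@axis)
  lmax <- patchLambdaMax(surface)
  th <- 2 * pi * u
  la <- lmax * v
  rad <- surface@b * cos(la) + surface@delta
  circ <- function(w) cos(th) * fr$f1[w] + sin(th) * fr$f2[w]
  dcirc <- function(w) -sin(th) * fr$f1[w] + cos(th) * fr$f2[w]
  du <- cbind(2 * pi * rad * dcirc(1L), 2 * pi * rad * dcirc(2L),
              2 * pi * rad * dcirc(3L))
  dh <- surface@hemisphere * surface@a * cos(la) * lmax
  drad <- -surface@b * sin(la) * lmax
  dv <- cbind(drad * circ(1L) + dh * surface@axis[1L],
              drad * circ(2L) + dh * surface@axis[2L],
              drad * circ(3L) + dh * surface@axis[3L])
  list(du = du, dv = dv)
})

#' Radially offset a surface of revolution
#'
#' Changes every latitude circle's radius about the axis by \code{delta}
#' millimetres while keeping the axial coordinate unchanged (a radial
#' offset, not a surface-normal offset). Offsets accumulate, so
#' \code{offsetRevolution(offsetRevolution(s, d), -d)} restores \code{s}
#' exactly. For negative total offsets the latitude domain is clipped to
#' circles of positive radius; collapsing the equator itself is an error.
#'
#' @param surface an \linkS4class{EllipsoidPatch}.
#' @param delta signed radial offset (mm).
#' @return an \linkS4class{EllipsoidPatch} with the accumulated offset.
#' @export
offsetRevolution <- function(surface, delta) {
  total <- surface@delta + delta
  if (surface@b + total <= 0)
    stop("radial offset ", signif(total, 6),
         " mm collapses the equator circle (b = ", signif(surface@b, 6),
         " mm) to non-positive radius")
  ellipsoidPatch(surface@center, surface@axis, surface@a, surface@b,
                 surface@hemisphere, total)
}

#' Deterministic sample points on a full ellipsoid of revolution
#'
#' Fibonacci-lattice directions mapped to the ellipsoid, handy as fitting
#' fixtures with known ground truth.
#'
#' @param center,axis,a,b ellipsoid parameters (axis is normalized).
#' @param n number of points.
#' @return \code{n x 3} matrix (mm).
#' @export
sampleEllipsoid <- function(center, axis, a, b, n = 200L) {
  axis <- unit3(axis)
  fr <- orthoFrame(axis)
  k <- seq_len(n) - 0.5
  sinLat <- 1 - 2 * k / n                  # uniform in the axial coordinate
  cosLat <- sqrt(pmax(0, 1 - sinLat^2))
  th <- pi * (1 + sqrt(5)) * k
  t(vapply(seq_len(n), function(i)
    center + b * cosLat[i] * (cos(th[i]) * fr$f1 + sin(th[i]) * fr$f2) +
      a * sinLat[i] * axis, numeric(3L)))
}

## Residuals (h/a)^2 + (r/b)^2 - 1 in the axis-aligned frame.
.ellipsoidResiduals <- function(par, points) {
  ctr <- par[1:3]
  e <- c(sin(par[4L]) * cos(par[5L]), sin(par[4L]) * sin(par[5L]),
         cos(par[4L]))
  a <- par[6L]; b <- par[7L]
  q <- sweep(points, 2L, ctr)
  h <- as.numeric(q %*% e)
  r2 <- pmax(0, rowSums(q^2) - h^2)
  (h / a)^2 + r2 / b^2 - 1
}

#' Fit an ellipsoid of revolution to a point cloud
#'
#' Levenberg--Marquardt least squares on the algebraic residual
#' \code{(h/a)^2 + (r/b)^2 - 1}, where \code{h} and \code{r} are a point's
#' axial and radial coordinates about the candidate axis. Initialization:
#' cloud centroid and each of the three principal directions; the
#' best-converged candidate wins. The axis is determined up to sign (and,
#' for a sphere, not at all).
#'
#' @param points \code{n x 3} matrix of surface samples (mm), \code{n >= 7}.
#' @param maxIter maximal LM iterations per start.
#' @return an \linkS4class{EllipsoidPatch} (hemisphere chosen on the side
#'   of the cloud centroid mass along the fitted axis; +1 when balanced)
#'   with attributes \code{"rms"} (root-mean-square residual, dimensionless)
#'   and \code{"converged"}.
#' @export
fitEllipsoidRevolution <- function(points, maxIter = 200L) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L)
  if (nrow(points) < 7L)
    stop("need at least 7 points to determine an ellipsoid of revolution")
  ctr0 <- colMeans(points)
  ev <- eigen(stats::cov(points), symmetric = TRUE)$vectors
  fits <- lapply(1:3, function(k) {
    e <- ev[, k]
    th <- acos(clamp(e[3L], -1, 1))
    ph <- atan2(e[2L], e[1L])
    q <- sweep(points, 2L, ctr0)
    h <- as.numeric(q %*% e)
    a0 <- max(abs(h)); a0 <- if (a0 > 0) a0 else 1
    r0 <- sqrt(max(pmax(0, rowSums(q^2) - h^2)))
    b0 <- if (r0 > 0) r0 else 1
    try(minpack.lm::nls.lm(
      par = c(ctr0, th, ph, a0, b0),
      fn = .ellipsoidResiduals, points = points,
      lower = c(rep(-Inf, 5L), 1e-6, 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = maxIter)),
      silent = TRUE)
  })
  ok <- !vapply(fits, inherits, logical(1L), "try-error")
  if (!any(ok)) stop("ellipsoid fit failed from every principal-axis start")
  dev <- vapply(fits, function(f) if (inherits(f, "try-error")) Inf
                else f$deviance, numeric(1L))
  best <- fits[[which.min(dev)]]
  par <- best$par
  converged <- best$info %in% 1:4
  if (!converged) {
    cond <- structure(
      class = c("fitConvergenceError", "error", "condition"),
      list(message = paste0(
        "ellipsoid fit did not converge within ", maxIter,
        " iterations (nls.lm info ", best$info, "); best iterate in ",
        "attr(condition, 'best')"), call = sys.call()))
    attr(cond, "best") <- par
    stop(cond)
  }
  e <- c(sin(par[4L]) * cos(par[5L]), sin(par[4L]) * sin(par[5L]),
         cos(par[4L]))
  h <- as.numeric(sweep(points, 2L, par[1:3]) %*% e)
  hemi <- if (sum(h) >= 0) 1 else -1
  out <- ellipsoidPatch(par[1:3], e, par[6L], par[7L], hemisphere = hemi)
  attr(out, "rms") <- sqrt(best$deviance / nrow(points))
  attr(out, "converged") <- TRUE
  out
}
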