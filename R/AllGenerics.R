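#' @import methods
NULL

#' Evaluate a curve (or one of its derivatives)
#'
#' @param curve a curve object (\linkS4class{BezierCurve} or
#'   \linkS4class{FunctionCurve}).
#' @param t numeric vector of parameters in \code{[0, 1]}.
#' @param order derivative order: 0 for the position, up to 3.
#' @return a \code{length(t) x 3} matrix.
#' @export
setGeneric("curveEval", function(curve, t, order = 0L)
  standardGeneric("curveEval"))

#' Evaluate a parametric surface on the unit square
#'
#' Surfaces map \code{[0,1] x [0,1]} to 3D patient coordinates (mm).
#'
#' @param surface a \linkS4class{ParametricSurface}.
#' @param u,v numeric vectors of equal length with parameters in \code{[0,1]}.
#' @return a \code{length(u) x 3} matrix of 3D points.
#' @export
setGeneric("evalSurface", function(surface, u, v)
  standardGeneric("evalSurface"))

#' First partial derivatives of a parametric surface
#'
#' @inheritParams evalSurface
#' @return list with \code{du} and \code{dv}, each \code{length(u) x 3},
#'   derivatives with respect to the unit-square parameters.
#' @export
setGeneric("surfaceUVPartials", function(surface, u, v)
  standardGeneric("surfaceUVPartials"))

#' Number of positioned data points in a volume
#' @param x a \linkS4class{DicomVolume}.
#' @return integer (double for large volumes): total pixel count across slices.
#' @export
setGeneric("nDataPoints", function(x) standardGeneric("nDataPoints"))

#' Bounding box accessor
#' @param x an object with a 3D bounding box.
#' @return numeric length-6 vector \code{(x0, x1, y0, y1, z0, z1)} in mm.
#' @export
setGeneric("bbox", function(x) standardGeneric("bbox"))

#' Geodesic curvature of a curve lying on a surface
#'
#' The in-surface component of the curve's curvature,
#' \eqn{\kappa_g = \langle \ddot\alpha, n \times T\rangle / \|\dot\alpha\|^2},
#' invariant under isometric unfolding.
#'
#' @param surface a \linkS4class{ParametricSurface}.
#' @param curve curve on the surface; for a \linkS4class{RuledSurface} it may
#'   be omitted, meaning the directrix (sharing the surface parameter).
#' @param t numeric vector of curve parameters.
#' @param tol maximal allowed distance (mm) between curve point and surface.
#' @return numeric vector of signed geodesic curvatures (1/mm).
#' @export
setGeneric("geodesicCurvature", function(surface, curve, t, tol = 1e-6)
  standardGeneric("geodesicCurvature"))
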