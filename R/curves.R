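## Space curves: Bezier curves (the fitting workhorse) and closure-backed
## analytic curves (circles, helices, ...) sharing one evaluation generic.

#' Virtual space-curve class
#' @export
setClass("SpaceCurve", representation("VIRTUAL"))

#' Bezier space curve
#'
#' A polynomial curve in Bernstein--Bezier form on \code{[0, 1]}.
#'
#' @slot controlPoints \code{(degree + 1) x 3} numeric matrix, mm.
#' @export
setClass("BezierCurve", contains = "SpaceCurve",
         representation(controlPoints = "matrix"),
         validity = function(object) {
           cp <- object@controlPoints
           if (!is.numeric(cp) || ncol(cp) != 3L)
             return("controlPoints must be a numeric n x 3 matrix")
           if (nrow(cp) < 2L)
             return("a Bezier curve needs degree >= 1 (>= 2 control points)")
           if (any(!is.finite(cp)))
             return("controlPoints must be finite")
           TRUE
         })

#' Analytic (closure-backed) space curve
#'
#' Wraps an arbitrary parametrization \code{f(t)} on \code{[0,1]} with
#' optional analytic derivatives; missing derivatives fall back to
#' 4th-order central finite differences.
#'
#' @slot f function of a scalar t returning a 3-vector (mm).
#' @slot d1,d2,d3 derivative functions or \code{NULL}.
#' @export
setClass("FunctionCurve", contains = "SpaceCurve",
         representation(f = "function", d1 = "ANY", d2 = "ANY", d3 = "ANY"))

#' Construct a Bezier curve
#' @param controlPoints \code{(degree+1) x 3} matrix of control points (mm).
#' @return a \linkS4class{BezierCurve}.
#' @examples
#' bezierCurve(rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0)))
#' @export
bezierCurve <- function(controlPoints) {
  new("BezierCurve", controlPoints = as.matrix(controlPoints))
}

#' Construct an analytic curve from closures
#' @param f parametrization on \code{[0,1]}, returns a 3-vector.
#' @param d1,d2,d3 optional analytic derivative closures.
#' @return a \linkS4class{FunctionCurve}.
#' @export
functionCurve <- function(f, d1 = NULL, d2 = NULL, d3 = NULL) {
  new("FunctionCurve", f = f, d1 = d1, d2 = d2, d3 = d3)
}

#' Degree of a Bezier curve
#' @param curve a \linkS4class{BezierCurve}.
#' @export
curveDegree <- function(curve) nrow(curve@controlPoints) - 1L

setMethod("show", "BezierCurve", function(object) {
  cat("BezierCurve of degree", curveDegree(object), "\n")
  cat("  start:", paste(signif(object@controlPoints[1L, ], 6), collapse = ", "),
      "\n  end:  ",
      paste(signif(object@controlPoints[nrow(object@controlPoints), ], 6),
            collapse = ", "), "\n")
})

## de Casteljau evaluation of one Bezier point (matrix cp, scalar t).
deCasteljau <- function(cp, t) {
  n <- nrow(cp)
  while (n > 1L) {
    cp <- (1 - t) * cp[-n, , drop = FALSE] + t * cp[-1L, , drop = FALSE]
    n <- n - 1L
  }
  cp[1L, ]
}

## Control points of the derivative (hodograph) curve.
hodograph <- function(cp) {
  n <- nrow(cp) - 1L
  n * (cp[-1L, , drop = FALSE] - cp[-(n + 1L), , drop = FALSE])
}

#' @describeIn curveEval de Casteljau evaluation; derivatives are exact
#'   (hodograph); orders above the degree return zero vectors.
#' @export
setMethod("curveEval", "BezierCurve", function(curve, t, order = 0L) {
  stopifnot(all(is.finite(t)), order >= 0L, order <= 3L)
  cp <- curve@controlPoints
  k <- 0L
  while (k < order) {
    if (nrow(cp) == 1L) return(matrix(0, length(t), 3L))
    cp <- hodograph(cp)
    k <- k + 1L
  }
  out <- t(vapply(t, function(ti) deCasteljau(cp, ti), numeric(3L)))
  dimnames(out) <- NULL
  out
})

#' @describeIn curveEval analytic derivatives when provided, else 4th-order
#'   finite differences of the next-lower order.
#' @export
setMethod("curveEval", "FunctionCurve", function(curve, t, order = 0L) {
  stopifnot(all(is.finite(t)), order >= 0L, order <= 3L)
  fs <- list(curve@f, curve@d1, curve@d2, curve@d3)
  f <- fs[[order + 1L]]
  if (!is.null(f))
    return(t(vapply(t, function(ti) as.numeric(f(ti)), numeric(3L))))
  ## differentiate the highest available analytic order by finite differences
  base <- order
  while (base > 0L && is.null(fs[[base + 1L]])) base <- base - 1L
  g <- fs[[base + 1L]]
  val <- function(tt, k) {                      # k extra FD differentiations
    if (k == 0L) return(as.numeric(g(tt)))
    fdDeriv(function(s) val(s, k - 1L), tt)[, 1L]
  }
  t(vapply(t, function(ti) val(ti, order - base), numeric(3L)))
})

#' Frenet data of a space curve
#'
#' @param curve a curve object.
#' @param t numeric vector of parameters.
#' @return list of \code{length(t) x 3} matrices \code{point}, \code{d1},
#'   \code{d2}, \code{d3}, \code{T}, \code{N}, \code{B} plus vectors
#'   \code{speed}, \code{kappa} (curvature, 1/mm) and \code{tau} (torsion).
#'   \code{N}, \code{B}, \code{tau} are \code{NA} where curvature vanishes.
#' @export
curveFrenet <- function(curve, t) {
  p <- curveEval(curve, t, 0L)
  d1 <- curveEval(curve, t, 1L)
  d2 <- curveEval(curve, t, 2L)
  d3 <- curveEval(curve, t, 3L)
  v <- rowNorms(d1)
  cr <- t(vapply(seq_along(t), function(i) cross3(d1[i, ], d2[i, ]),
                 numeric(3L)))
  ncr <- rowNorms(cr)
  kappa <- ncr / v^3
  Tm <- d1 / v
  Bm <- cr / ifelse(ncr > 0, ncr, NA_real_)
  Nm <- t(vapply(seq_along(t), function(i) cross3(Bm[i, ], Tm[i, ]),
                 numeric(3L)))
  tau <- vapply(seq_along(t), function(i)
    det3(d1[i, ], d2[i, ], d3[i, ]), numeric(1L)) / ncr^2
  list(point = p, d1 = d1, d2 = d2, d3 = d3, T = Tm, N = Nm, B = Bm,
       speed = v, kappa = kappa, tau = tau)
}

#' Arc length of a curve by composite trapezoid quadrature
#' @param curve a curve object.
#' @param n number of samples on \code{[0,1]}.
#' @return length in mm.
#' @export
curveArcLength <- function(curve, n = 2001L) {
  t <- seq(0, 1, length.out = n)
  v <- rowNorms(curveEval(curve, t, 1L))
  utils::tail(cumTrapz(t, v), 1L)
}

## Bernstein design matrix: rows = parameters, cols = basis functions.
bernsteinMatrix <- function(t, degree) {
  j <- 0:degree
  outer(t, j, function(tt, jj)
    choose(degree, jj) * tt^jj * (1 - tt)^(degree - jj))
}

#' Chord-length parameter assignment
#' @param points \code{n x 3} matrix of ordered samples.
#' @return numeric vector in \code{[0,1]}, 0 at the first point.
#' @export
chordParameters <- function(points) {
  d <- c(0, rowNorms(diff(points)))
  s <- cumsum(d)
  if (s[length(s)] <= 0) stop("all points coincide: chord length is zero")
  s / s[length(s)]
}

#' Least-squares Bezier fit to ordered 3D samples
#'
#' Minimizes the sum of squared distances between the samples and the curve
#' evaluated at chord-length parameters, solving the linear least-squares
#' problem in the Bernstein basis by QR. Near-rank-deficient systems
#' (duplicate parameters, too few distinct samples) are ridge-regularized
#' with a warning.
#'
#' @param points \code{n x 3} matrix of ordered samples (mm),
#'   \code{n >= degree + 1}.
#' @param degree Bezier degree of the fit.
#' @param params optional explicit parameter assignment in \code{[0, 1]}
#'   (one value per point); the default is the chord-length rule.
#' @return a \linkS4class{BezierCurve}; attribute \code{"rms"} carries the
#'   root-mean-square residual at the assigned parameters (mm).
#' @export
fitBezierLsq <- function(points, degree, params = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L, degree >= 1L)
  if (nrow(points) < degree + 1L)
    stop("need at least degree + 1 = ", degree + 1L, " points, got ",
         nrow(points))
  t <- if (is.null(params)) chordParameters(points) else {
    stopifnot(length(params) == nrow(points))
    as.numeric(params)
  }
  B <- bernsteinMatrix(t, degree)
  ## the Bernstein basis is ill-conditioned but rarely truly deficient;
  ## rank-test at a tolerance below its typical condition level
  qrB <- qr(B, tol = 1e-12)
  if (qrB$rank < degree + 1L) {
    warning("rank-deficient Bezier design matrix; ridge-regularized solve")
    lam <- 1e-8 * sum(B^2) / (degree + 1L)
    cp <- solve(crossprod(B) + lam * diag(degree + 1L), crossprod(B, points))
  } else {
    cp <- qr.coef(qrB, points)
  }
  curve <- bezierCurve(cp)
  res <- curveEval(curve, t, 0L) - points
  attr(curve, "rms") <- sqrt(mean(rowSums(res^2)))
  curve
}
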