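## Ruled and developable surfaces along space curves: generalized cylinders,
## envelope-of-planes developables, and the rectifying developable (Darboux
## rulings), each checkable by the developability defect det[c', r, r'].

#' Construct a ruled surface directly
#'
#' \code{x(t, u) = c(t) + u r(t)} with \code{u} in \code{extent} (mm along
#' the unit ruling). Prefer \code{\link{buildDevelopable}} for guaranteed
#' developable constructions; this constructor also admits non-developable
#' rulings (e.g. negative controls, cones through an apex).
#'
#' @param directrix a \linkS4class{SpaceCurve}.
#' @param ruling function of scalar t returning the ruling direction
#'   (normalized internally).
#' @param extent \code{c(uMin, uMax)} in mm.
#' @param rulingDot optional analytic derivative of the unit ruling.
#' @param construction label stored on the object.
#' @return a \linkS4class{RuledSurface}.
#' @export
ruledSurface <- function(directrix, ruling, extent, rulingDot = NULL,
                         construction = "custom") {
  rl <- function(t) unit3(ruling(t))
  new("RuledSurface", directrix = directrix, ruling = rl,
      rulingDot = rulingDot, extent = as.numeric(extent),
      construction = construction)
}

## Unit rulings at a parameter vector: n x 3 matrix.
rulingAt <- function(surface, t) {
  t(vapply(t, surface@ruling, numeric(3L)))
}

## Derivative of the unit ruling: analytic when available, else 4th-order
## central finite differences.
rulingDerivAt <- function(surface, t) {
  if (!is.null(surface@rulingDot))
    return(t(vapply(t, surface@rulingDot, numeric(3L))))
  t(fdDeriv(surface@ruling, t))
}

## Physical u (mm) from the unit-square parameter v.
rulingOffset <- function(surface, v) {
  surface@extent[1L] + v * (surface@extent[2L] - surface@extent[1L])
}

#' @describeIn evalSurface \code{u} runs along the directrix, \code{v} along
#'   the ruling extent.
#' @export
setMethod("evalSurface", "RuledSurface", function(surface, u, v) {
  stopifnot(length(u) == length(v))
  c0 <- curveEval(surface@directrix, u, 0L)
  r <- rulingAt(surface, u)
  c0 + rulingOffset(surface, v) * r
})

#' @describeIn surfaceUVPartials directrix/ruling partials; the ruling
#'   derivative uses the analytic form when available.
#' @export
setMethod("surfaceUVPartials", "RuledSurface", function(surface, u, v) {
  stopifnot(length(u) == length(v))
  d1 <- curveEval(surface@directrix, u, 1L)
  rd <- rulingDerivAt(surface, u)
  r <- rulingAt(surface, u)
  w <- surface@extent[2L] - surface@extent[1L]
  list(du = d1 + rulingOffset(surface, v) * rd, dv = w * r)
})

#' Developability defect of a ruled surface
#'
#' \code{|det[c'(t), r(t), r'(t)]|} normalized by
#' \code{||c'(t)|| * ||r'(t)||}; zero characterizes developable ruled
#' surfaces (and is returned exactly when \code{r' = 0}, i.e. cylinders).
#'
#' @param surface a \linkS4class{RuledSurface}.
#' @param t numeric vector of parameters.
#' @return nonnegative numeric vector.
#' @export
developabilityDefect <- function(surface, t) {
  d1 <- curveEval(surface@directrix, t, 1L)
  r <- rulingAt(surface, t)
  rd <- rulingDerivAt(surface, t)
  vapply(seq_along(t), function(i) {
    nrd <- vnorm(rd[i, ])
    if (nrd < 1e-9) return(0)
    abs(det3(d1[i, ], r[i, ], rd[i, ])) / (vnorm(d1[i, ]) * nrd)
  }, numeric(1L))
}

#' Build a developable surface along a space curve
#'
#' Three constructions, all satisfying the developability condition
#' \code{det[c', r, r'] = 0}:
#' \describe{
#'   \item{cylinder}{constant ruling \code{r(t) = d}: a generalized
#'     cylinder through the curve.}
#'   \item{envelope}{the envelope of the plane family through \code{c(t)}
#'     with normal \code{N(t) = unit(c'(t) x d)}; its characteristic
#'     (ruling) direction is \code{unit(N x N')}. The surface contains the
#'     curve and varies with the reference direction \code{d}, so two
#'     orthogonal choices of \code{d} give a transversal pair along the
#'     same curve.}
#'   \item{rectifying}{rulings along the Darboux direction
#'     \code{tau T + kappa B}; the directrix is then a geodesic of the
#'     surface and flattens to a straight line.}
#' }
#'
#' @param curve a \linkS4class{SpaceCurve}.
#' @param construction \code{"cylinder"}, \code{"envelope"} or
#'   \code{"rectifying"}.
#' @param extent \code{c(uMin, uMax)} ruling extent in mm.
#' @param d reference direction for cylinder/envelope (must never be
#'   parallel to the tangent).
#' @param nCheck number of parameters at which preconditions are verified.
#' @return a \linkS4class{RuledSurface}.
#' @export
buildDevelopable <- function(curve, construction = c("cylinder", "envelope",
                                                     "rectifying"),
                             extent = c(-5, 5), d = c(0, 0, 1),
                             nCheck = 100L) {
  construction <- match.arg(construction)
  tChk <- seq(0, 1, length.out = nCheck)
  if (construction %in% c("cylinder", "envelope")) {
    d <- unit3(d)
    d1 <- curveEval(curve, tChk, 1L)
    sinAng <- rowNorms(t(vapply(seq_len(nCheck), function(i)
      cross3(d1[i, ] / vnorm(d1[i, ]), d), numeric(3L))))
    if (any(sinAng < 1e-6))
      stop("reference direction d is (near-)parallel to the tangent at t = ",
           signif(tChk[which.min(sinAng)], 4))
  }
  surf <- switch(construction,
    cylinder = ruledSurface(curve, function(t) d, extent,
                            rulingDot = function(t) c(0, 0, 0),
                            construction = "cylinder"),
    envelope = {
      raw <- function(t) {
        d1 <- curveEval(curve, t, 1L)[1L, ]
        d2 <- curveEval(curve, t, 2L)[1L, ]
        w <- cross3(d1, d)
        wd <- cross3(d2, d)
        N <- w / vnorm(w)
        Nd <- (wd - sum(wd * N) * N) / vnorm(w)
        unit3(cross3(N, Nd))
      }
      ## rulings are lines, so unit(N x N') carries a sign ambiguity that
      ## flips where N' passes through zero; fix a continuous orientation
      ## by sign-propagation along a dense grid
      tg <- seq(0, 1, length.out = 1001L)
      rg <- t(vapply(tg, raw, numeric(3L)))
      for (i in 2:nrow(rg))
        if (sum(rg[i, ] * rg[i - 1L, ]) < 0) rg[i, ] <- -rg[i, ]
      ruling <- function(t) {
        r0 <- raw(t)
        ref <- rg[which.min(abs(tg - t)), ]
        if (sum(r0 * ref) < 0) -r0 else r0
      }
      ruledSurface(curve, ruling, extent, construction = "envelope")
    },
    rectifying = {
      fr <- curveFrenet(curve, tChk)
      if (any(!is.finite(fr$kappa)) || any(fr$kappa < 1e-8))
        stop("rectifying construction needs curvature > 0 everywhere; ",
             "kappa vanishes near t = ",
             signif(tChk[which.min(fr$kappa)], 4))
      ruling <- function(t) {
        f <- curveFrenet(curve, t)
        unit3(f$tau[1L] * f$T[1L, ] + f$kappa[1L] * f$B[1L, ])
      }
      ruledSurface(curve, ruling, extent, construction = "rectifying")
    })
  surf
}
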