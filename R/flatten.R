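## Isometric unfolding of developable surfaces. The development preserves
## the geodesic curvature of any surface curve, so the planar image of the
## directrix is reconstructed from phi(t) = int v kappa_g dt and
## alpha(t) = int v [cos phi, sin phi] dt, and the rulings are drawn at the
## same angle to the planar curve as in 3D, with their lengths preserved.

## Project a point onto a parametric surface: coarse grid then bounded
## quasi-Newton refinement. Returns list(u, v, dist).
projectToSurface <- function(surface, point, gridN = c(121L, 25L)) {
  ug <- seq(0, 1, length.out = gridN[1L])
  vg <- seq(0, 1, length.out = gridN[2L])
  gr <- expand.grid(u = ug, v = vg)
  d2 <- rowSums(sweep(evalSurface(surface, gr$u, gr$v), 2L, point)^2)
  i0 <- which.min(d2)
  obj <- function(uv) {
    sum((evalSurface(surface, uv[1L], uv[2L])[1L, ] - point)^2)
  }
  grad <- function(uv) {
    dd <- evalSurface(surface, uv[1L], uv[2L])[1L, ] - point
    pp <- surfaceUVPartials(surface, uv[1L], uv[2L])
    2 * c(sum(dd * pp$du[1L, ]), sum(dd * pp$dv[1L, ]))
  }
  fit <- stats::optim(c(gr$u[i0], gr$v[i0]), obj, grad, method = "L-BFGS-B",
                      lower = c(0, 0), upper = c(1, 1))
  list(u = fit$par[1L], v = fit$par[2L], dist = sqrt(fit$value))
}

#' Unit surface normal at parameters
#' @param surface a \linkS4class{ParametricSurface}.
#' @param u,v parameters (scalars or equal-length vectors).
#' @return \code{length(u) x 3} matrix of unit normals
#'   (\code{unit(x_u x x_v)}).
#' @export
surfaceNormal <- function(surface, u, v) {
  pp <- surfaceUVPartials(surface, u, v)
  t(vapply(seq_along(u), function(i)
    unit3(cross3(pp$du[i, ], pp$dv[i, ])), numeric(3L)))
}

## kappa_g of the directrix of a ruled surface at t (shared parameter),
## with the surface normal oriented as unit(c' x r).
.directrixKappaG <- function(surface, t) {
  d1 <- curveEval(surface@directrix, t, 1L)
  d2 <- curveEval(surface@directrix, t, 2L)
  r <- rulingAt(surface, t)
  vapply(seq_along(t), function(i) {
    v2 <- sum(d1[i, ]^2)
    Tm <- d1[i, ] / sqrt(v2)
    n <- unit3(cross3(Tm, r[i, ]))
    sum(d2[i, ] * cross3(n, Tm)) / v2
  }, numeric(1L))
}

#' @describeIn geodesicCurvature directrix of a ruled surface (shared
#'   parameter; the curve argument is omitted).
#' @export
setMethod("geodesicCurvature",
          signature(surface = "RuledSurface", curve = "missing"),
          function(surface, curve, t, tol = 1e-6) {
  .directrixKappaG(surface, t)
})

#' @describeIn geodesicCurvature arbitrary curve on an arbitrary surface:
#'   each curve point is projected onto the surface (failure beyond
#'   \code{tol} mm) and the normal taken from the surface partials there.
#' @export
setMethod("geodesicCurvature",
          signature(surface = "ParametricSurface", curve = "SpaceCurve"),
          function(surface, curve, t, tol = 1e-6) {
  d1 <- curveEval(curve, t, 1L)
  d2 <- curveEval(curve, t, 2L)
  p <- curveEval(curve, t, 0L)
  vapply(seq_along(t), function(i) {
    pr <- projectToSurface(surface, p[i, ])
    if (pr$dist > tol)
      stop("curve point at t = ", signif(t[i], 4), " lies ",
           signif(pr$dist, 3), " mm off the surface (tolerance ", tol, ")")
    n <- surfaceNormal(surface, pr$u, pr$v)[1L, ]
    v2 <- sum(d1[i, ]^2)
    Tm <- d1[i, ] / sqrt(v2)
    sum(d2[i, ] * cross3(n, Tm)) / v2
  }, numeric(1L))
})

#' Develop a curve into the plane from sampled geodesic curvature
#'
#' Composite-trapezoid quadrature of \code{phi(t) = int v kappa_g dt} and
#' \code{alpha(t) = int v [cos phi, sin phi] dt}, anchored at
#' \code{phi = 0}, \code{alpha = (0, 0)} at the first sample (one
#' representative of the family of congruent solutions). The planar curve
#' has curvature \code{kappa_g} up to discretization error (order 2 in the
#' grid spacing).
#'
#' @param kappaG sampled geodesic curvature (1/mm).
#' @param speed sampled curve speed v(t) (mm per unit parameter), > 0.
#' @param tSamples strictly increasing parameter grid (>= 3 samples).
#' @return a \linkS4class{DevelopedCurve}.
#' @examples
#' d <- developCurve(rep(0, 11), rep(1, 11), seq(0, 1, 0.1))
#' d@planePoints[11, ]   # (1, 0): a straight unit segment
#' @export
developCurve <- function(kappaG, speed, tSamples) {
  n <- length(tSamples)
  stopifnot(length(kappaG) == n, length(speed) == n)
  if (n < 3L) stop("need at least 3 samples")
  if (any(diff(tSamples) <= 0)) stop("tSamples must be strictly increasing")
  if (any(speed <= 0)) stop("speed must be positive")
  phi <- cumTrapz(tSamples, speed * kappaG)
  x <- cumTrapz(tSamples, speed * cos(phi))
  y <- cumTrapz(tSamples, speed * sin(phi))
  new("DevelopedCurve", t = as.numeric(tSamples), phi = phi,
      planePoints = unname(cbind(x, y)), speed = as.numeric(speed))
}

#' Isometrically unfold a textured developable surface
#'
#' Develops the directrix via its geodesic curvature, then draws each
#' planar ruling at the same angle to the developed curve as the 3D ruling
#' makes with the tangent, preserving ruling lengths; the texture and
#' informed-mask ride along per sample. Refuses non-developable input.
#'
#' @param surface the \linkS4class{RuledSurface} that was texturized.
#' @param textured the matching \linkS4class{TexturedSurface} (its u grid is
#'   the directrix parameter, its v grid the ruling extent).
#' @param directrixChoice \code{"directrix"}; or \code{"pregeodesic"}, which
#'   additionally requires the directrix's geodesic curvature to vanish
#'   numerically, so its planar image is a straight line.
#' @param defectTol maximal admissible developability defect.
#' @param anchorIndex sample index where the development is anchored
#'   (\code{phi = 0}, \code{alpha = (0, 0)}); changing it yields a
#'   congruent sheet.
#' @return a \linkS4class{FlattenedSheet}.
#' @export
unfoldSurface <- function(surface, textured,
                          directrixChoice = c("directrix", "pregeodesic"),
                          defectTol = 1e-5, anchorIndex = 1L) {
  directrixChoice <- match.arg(directrixChoice)
  t <- textured@u
  n <- length(t)
  stopifnot(anchorIndex >= 1L, anchorIndex <= n)
  defect <- developabilityDefect(surface, t)
  if (max(defect) > defectTol)
    stop("surface is not developable: max developability defect ",
         signif(max(defect), 4), " exceeds ", defectTol)
  d1 <- curveEval(surface@directrix, t, 1L)
  v <- rowNorms(d1)
  kg <- .directrixKappaG(surface, t)
  if (directrixChoice == "pregeodesic") {
    turn <- sum(diff(t) * (abs(v * kg)[-n] + abs(v * kg)[-1L]) / 2)
    if (turn > 1e-6)
      stop("directrix is not a pregeodesic: total geodesic turning ",
           signif(turn, 4), " rad")
  }
  dc <- developCurve(kg, v, t)
  phi <- dc@phi - dc@phi[anchorIndex]
  base <- sweep(dc@planePoints, 2L, dc@planePoints[anchorIndex, ])
  phi0 <- dc@phi[anchorIndex]               # undo the anchor's turning angle
  rot <- matrix(c(cos(phi0), sin(phi0), -sin(phi0), cos(phi0)), 2L, 2L)
  base <- base %*% rot
  r <- rulingAt(surface, t)
  e1 <- cbind(cos(phi), sin(phi))
  e2 <- cbind(-sin(phi), cos(phi))
  rbar <- t(vapply(seq_len(n), function(i) {
    Tm <- d1[i, ] / v[i]
    nrm <- unit3(cross3(Tm, r[i, ]))
    comp1 <- sum(r[i, ] * Tm)
    comp2 <- sum(r[i, ] * cross3(nrm, Tm))
    w <- comp1 * e1[i, ] + comp2 * e2[i, ]
    w / vnorm(w)                            # exact unit planar ruling
  }, numeric(2L)))
  uMM <- rulingOffset(surface, textured@v)
  plane <- array(0, dim = c(n, length(textured@v), 2L))
  for (j in seq_along(uMM)) {
    plane[, j, 1L] <- base[, 1L] + uMM[j] * rbar[, 1L]
    plane[, j, 2L] <- base[, 2L] + uMM[j] * rbar[, 2L]
  }
  new("FlattenedSheet", planeGrid = plane, gray = textured@gray,
      informed = textured@informed, u = textured@u, v = textured@v)
}

## First-fundamental-form coefficients of a sampled grid by central
## differences over the parameter grids (interior nodes only).
.fffGrid <- function(pts, u, v) {
  nu <- length(u); nv <- length(v)
  iu <- 2:(nu - 1L); iv <- 2:(nv - 1L)
  du <- (pts[iu + 1L, iv, , drop = FALSE] - pts[iu - 1L, iv, , drop = FALSE])
  dv <- (pts[iu, iv + 1L, , drop = FALSE] - pts[iu, iv - 1L, , drop = FALSE])
  su <- array(rep(u[iu + 1L] - u[iu - 1L], length(iv) * dim(pts)[3L]),
              dim = dim(du))
  sv <- array(rep(v[iv + 1L] - v[iv - 1L], each = length(iu)),
              dim = dim(dv))
  du <- du / su
  dv <- dv / sv
  list(E = apply(du * du, c(1L, 2L), sum),
       F = apply(du * dv, c(1L, 2L), sum),
       G = apply(dv * dv, c(1L, 2L), sum))
}

## Total sampled area of a grid by triangulated quads.
.gridArea <- function(pts) {
  nu <- dim(pts)[1L]; nv <- dim(pts)[2L]
  p <- function(i, j) pts[i, j, ]
  tot <- 0
  for (i in seq_len(nu - 1L)) for (j in seq_len(nv - 1L)) {
    a <- p(i, j); b <- p(i + 1L, j); cc <- p(i, j + 1L); d <- p(i + 1L, j + 1L)
    if (dim(pts)[3L] == 2L) {
      a <- c(a, 0); b <- c(b, 0); cc <- c(cc, 0); d <- c(d, 0)
    }
    tot <- tot + vnorm(cross3(b - a, cc - a)) / 2 +
      vnorm(cross3(b - d, cc - d)) / 2
  }
  tot
}

#' Audit the metric distortion of a flattening
#'
#' Compares the first-fundamental-form coefficients E, F, G of the 3D
#' parametrization against the planar one at every interior grid node
#' (central differences), plus the total sampled areas. An exact isometry
#' gives deviations at the discretization level only.
#'
#' @param surface the \linkS4class{RuledSurface}.
#' @param sheet the \linkS4class{FlattenedSheet} produced from it.
#' @return list with \code{maxRelDeviation} (max over nodes of
#'   \code{(|dE| + |dF| + |dG|) / (E + G)}), \code{areaRatio}
#'   (planar / 3D), and the per-node deviation matrix \code{relDeviation}.
#' @export
flatteningDistortion <- function(surface, sheet) {
  u <- sheet@u; v <- sheet@v
  gridUV <- expand.grid(u = u, v = v)
  p3 <- array(evalSurface(surface, gridUV$u, gridUV$v),
              dim = c(length(u), length(v), 3L))
  f3 <- .fffGrid(p3, u, v)
  f2 <- .fffGrid(sheet@planeGrid, u, v)
  rel <- (abs(f3$E - f2$E) + abs(f3$F - f2$F) + abs(f3$G - f2$G)) /
    (f3$E + f3$G)
  list(maxRelDeviation = max(rel),
       areaRatio = .gridArea(sheet@planeGrid) / .gridArea(p3),
       relDeviation = rel)
}
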