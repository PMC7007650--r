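## Shared fixtures, all generated in code.

## Small trilinear-ramp phantom volume.
rampVolume <- function(nSlices = 5L, dim = 16L, spacing = c(1, 1, 2),
                       poseMode = "parallel_uniform", seed = 1L) {
  generatePhantom(phantomSpec(trilinearRampField(), nSlices = nSlices,
                              matrixDim = c(dim, dim), spacing = spacing,
                              poseMode = poseMode, seed = seed))
}

## Circular helix with exact derivatives (radius r0, pitch per turn 2*pi*p).
helixCurve <- function(r0 = 10, p = 3, turns = 1) {
  w <- 2 * pi * turns
  functionCurve(
    f = function(t) c(r0 * cos(w * t), r0 * sin(w * t), p * w * t),
    d1 = function(t) c(-w * r0 * sin(w * t), w * r0 * cos(w * t), p * w),
    d2 = function(t) c(-w^2 * r0 * cos(w * t), -w^2 * r0 * sin(w * t), 0),
    d3 = function(t) c(w^3 * r0 * sin(w * t), -w^3 * r0 * cos(w * t), 0))
}

## Planar circle of radius r in the z = z0 plane, exact derivatives.
circleCurve <- function(r, z0 = 0) {
  w <- 2 * pi
  functionCurve(
    f = function(t) c(r * cos(w * t), r * sin(w * t), z0),
    d1 = function(t) c(-w * r * sin(w * t), w * r * cos(w * t), 0),
    d2 = function(t) c(-w^2 * r * cos(w * t), -w^2 * r * sin(w * t), 0),
    d3 = function(t) c(w^3 * r * sin(w * t), -w^3 * r * cos(w * t), 0))
}

## Nonplanar degree-8 Bezier with curvature bounded away from zero,
## built by least squares on a perturbed helix.
helixBezier <- function(seed = 11L, sd = 0.3) {
  th <- seq(0, 3 * pi, length.out = 60)
  hp <- cbind(12 * cos(th), 12 * sin(th), 4 * th)
  set.seed(seed)
  hp <- hp + matrix(stats::rnorm(length(hp), sd = sd), ncol = 3)
  fitBezierLsq(hp, 8L)
}

## Uniformly textured stand-in surface (unit gray) for unfolding tests.
mkTexture <- function(surf, nu, nv) {
  u <- seq(0, 1, length.out = nu)
  v <- seq(0, 1, length.out = nv)
  gr <- expand.grid(u = u, v = v)
  new("TexturedSurface", u = u, v = v,
      points3d = array(evalSurface(surf, gr$u, gr$v), c(nu, nv, 3L)),
      gray = matrix(0, nu, nv), informed = matrix(TRUE, nu, nv),
      method = "nearest")
}

## Max distance of planar points from the straight line through the ends.
collinearityResidual <- function(pp) {
  dirv <- pp[nrow(pp), ] - pp[1L, ]
  dirv <- dirv / sqrt(sum(dirv^2))
  nrm <- c(-dirv[2L], dirv[1L])
  max(abs(sweep(pp, 2L, pp[1L, ]) %*% nrm))
}

## Polyline length of an n x k matrix of points.
polylineLength <- function(pp) sum(sqrt(rowSums(diff(pp)^2)))

## Deliberately twisted (non-developable) ruled surface over a curve.
twistedSurface <- function(curve, extent = c(-4, 4)) {
  ruledSurface(curve, function(t) {
    a <- 4 * pi * t
    c(0, sin(a), cos(a))
  }, extent)
}
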