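test_that("Bezier evaluation and derivatives are exact", {
  lin <- bezierCurve(rbind(c(1, 2, 3), c(4, 6, 3)))
  for (t in c(0, 0.3, 1))
    expect_equal(curveEval(lin, t, 1L)[1, ], c(3, 4, 0))
  cub <- bezierCurve(rbind(c(0, 0, 0), c(1, 2, -1), c(3, 1, 2), c(4, 4, 4)))
  expect_equal(curveEval(cub, 0, 0L)[1, ], c(0, 0, 0))
  expect_equal(curveEval(cub, 1, 0L)[1, ], c(4, 4, 4))
  ## first derivative vs central finite differences
  h <- 1e-6
  fd <- (curveEval(cub, 0.3 + h, 0L) - curveEval(cub, 0.3 - h, 0L)) / (2 * h)
  expect_lt(max(abs(curveEval(cub, 0.3, 1L) - fd)), 1e-6)
  ## orders above the degree are exactly zero
  expect_equal(curveEval(lin, 0.5, 2L)[1, ], c(0, 0, 0))
  expect_equal(curveEval(lin, 0.5, 3L)[1, ], c(0, 0, 0))
})

test_that("Frenet data matches helix closed forms", {
  r0 <- 10; p <- 3
  hx <- helixCurve(r0, p)
  fr <- curveFrenet(hx, seq(0.1, 0.9, length.out = 7))
  expect_equal(fr$kappa, rep(r0 / (r0^2 + p^2), 7), tolerance = 1e-9)
  expect_equal(fr$tau, rep(p / (r0^2 + p^2), 7), tolerance = 1e-9)
  expect_equal(fr$speed, rep(2 * pi * sqrt(r0^2 + p^2), 7),
               tolerance = 1e-9)
})

test_that("least-squares Bezier fitting recovers and regularizes", {
  ## two points, degree 1: the segment, residual 0
  seg <- fitBezierLsq(rbind(c(0, 0, 0), c(2, 2, 2)), 1L)
  expect_equal(attr(seg, "rms"), 0)
  expect_equal(curveEval(seg, 0.5, 0L)[1, ], c(1, 1, 1))
  ## degree-8 recovery from noiseless samples with known parameters
  set.seed(2)
  cv <- bezierCurve(matrix(rnorm(27, sd = 10), 9, 3))
  t <- sort(c(0, runif(48), 1))
  pts <- curveEval(cv, t, 0L)
  fit <- fitBezierLsq(pts, 8L, params = t)
  expect_lt(max(abs(curveEval(fit, t, 0L) - pts)), 1e-6)
  ## noisy centerline: residual bounded by 3 sigma
  sigma <- 0.2
  noisy <- pts + matrix(rnorm(length(pts), sd = sigma), ncol = 3)
  fitN <- fitBezierLsq(noisy, 8L, params = t)
  expect_lt(attr(fitN, "rms"), 3 * sigma)
  ## duplicate parameters: rank-deficient, ridge with warning
  expect_warning(fitBezierLsq(pts[1:10, ], 3L,
                              params = rep(c(0, 1), each = 5)),
                 "rank-deficient")
})

test_that("ellipsoid-of-revolution fit recovers exact parameters", {
  ctr <- c(10, -5, 30); ax <- c(1, 2, 2) / 3
  pts <- sampleEllipsoid(ctr, ax, a = 25, b = 18, n = 200)
  fit <- fitEllipsoidRevolution(pts)
  expect_lt(max(abs(fit@center - ctr)), 1e-4)
  expect_lt(abs(fit@a - 25), 1e-4)
  expect_lt(abs(fit@b - 18), 1e-4)
  expect_lt(acos(min(1, abs(sum(fit@axis * ax)))), 1e-4)
  expect_lt(attr(fit, "rms"), 1e-8)
})

test_that("sphere clouds fit with a equal to b, any axis", {
  pts <- sampleEllipsoid(c(0, 0, 0), c(0, 0, 1), a = 12, b = 12, n = 150)
  fit <- fitEllipsoidRevolution(pts)
  expect_lt(abs(fit@a - fit@b), 1e-4)
  expect_lt(abs(fit@a - 12), 1e-4)
})

test_that("noisy ellipsoid fits stay inside the Monte-Carlo envelope", {
  ctr <- c(10, -5, 30); ax <- c(1, 2, 2) / 3
  sigma <- 0.5; n <- 200L
  bound <- 5 * 3 * sigma / sqrt(n)
  for (s in 1:20) {
    set.seed(s)
    pts <- sampleEllipsoid(ctr, ax, 25, 18, n) +
      matrix(rnorm(3 * n, sd = sigma), ncol = 3)
    fit <- fitEllipsoidRevolution(pts)
    expect_lt(max(abs(fit@center - ctr)), bound)
    expect_lt(abs(fit@a - 25), bound)
    expect_lt(abs(fit@b - 18), bound)
  }
})

test_that("ellipsoid residual is invariant under rigid motion", {
  set.seed(21)
  pts <- sampleEllipsoid(c(1, 2, 3), c(0, 0, 1), 20, 14, 120) +
    matrix(rnorm(360, sd = 0.3), ncol = 3)
  rms1 <- attr(fitEllipsoidRevolution(pts), "rms")
  qrot <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(qrot) < 0) qrot[, 1] <- -qrot[, 1]
  pts2 <- pts %*% t(qrot) + matrix(c(5, -40, 13), nrow(pts), 3, byrow = TRUE)
  rms2 <- attr(fitEllipsoidRevolution(pts2), "rms")
  expect_lt(abs(rms1 - rms2), 1e-8)
})

test_that("radial offsets move latitude circles and invert exactly", {
  surf <- ellipsoidPatch(c(32, 32, 24), c(0, 0, 1), 14, 18)
  u <- c(0.1, 0.4, 0.8); v <- c(0, 0.3, 0.7)
  ## delta = 0: identity
  expect_equal(evalSurface(offsetRevolution(surf, 0), u, v),
               evalSurface(surf, u, v))
  ## equator circle radius b + 6 at delta = +6 ("outward 6 mm")
  eq <- evalSurface(offsetRevolution(surf, 6), 0.25, 0)
  expect_equal(sqrt(sum((eq - c(32, 32, 24))^2)), 24)
  ## axial coordinate unchanged by the offset
  p0 <- evalSurface(surf, u, v)
  p6 <- evalSurface(offsetRevolution(surf, 6), u, v)
  expect_equal(p0[, 3], p6[, 3])
  ## +4 then -4: exact inverse
  back <- offsetRevolution(offsetRevolution(surf, 4), -4)
  expect_lt(max(abs(evalSurface(back, u, v) - p0)), 1e-9)
  ## collapsing the equator fails
  expect_error(offsetRevolution(surf, -18), "collapses")
  ## inward offsets clip the latitude domain to positive radii
  inw <- offsetRevolution(surf, -4)
  radii <- sqrt(rowSums((evalSurface(inw, rep(0, 5),
                                     seq(0, 1, 0.25))[, 1:2] -
                           matrix(c(32, 32), 5, 2, byrow = TRUE))^2))
  expect_true(all(radii >= -1e-9))
})

test_that("developable constructions satisfy the defect condition", {
  tt <- seq(0, 1, length.out = 100)
  ## planar curve, cylinder with d perpendicular to its plane: defect 0
  arc <- bezierCurve(rbind(c(0, 0, 0), c(10, 15, 0), c(25, 12, 0),
                           c(40, 0, 0)))
  cyl <- buildDevelopable(arc, "cylinder", extent = c(-5, 5), d = c(0, 0, 1))
  expect_equal(max(developabilityDefect(cyl, tt)), 0)
  ## helix rectifying: Darboux rulings, defect at the 1e-9 level
  rect <- buildDevelopable(helixCurve(), "rectifying", extent = c(-4, 4))
  expect_lt(max(developabilityDefect(rect, tt)), 1e-9)
  ## envelope on a generic nonplanar curve
  env <- buildDevelopable(helixBezier(), "envelope", extent = c(-3, 3),
                          d = c(1, 0, 0))
  expect_lt(max(developabilityDefect(env, tt)), 1e-6)
  ## twisted ruling rotating about the curve: strictly positive defect
  tw <- twistedSurface(arc)
  expect_gt(max(developabilityDefect(tw, tt)), 0.1)
})

test_that("developable preconditions fail fast with the offending t", {
  ## cylinder d parallel to the tangent somewhere
  lin <- bezierCurve(rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_error(buildDevelopable(lin, "cylinder", d = c(1, 0, 0)),
               "parallel")
  ## rectifying requires positive curvature
  expect_error(buildDevelopable(lin, "rectifying"), "curvature")
})

test_that("envelope surfaces with orthogonal references form a transversal pair", {
  cv <- helixBezier()
  e1 <- buildDevelopable(cv, "envelope", extent = c(-3, 3), d = c(1, 0, 0))
  e2 <- buildDevelopable(cv, "envelope", extent = c(-3, 3), d = c(0, 1, 0))
  tt <- seq(0.05, 0.95, length.out = 20)
  ## both contain the directrix (ruling offset 0 at v = 0.5)
  onCurve <- curveEval(cv, tt, 0L)
  expect_lt(max(abs(evalSurface(e1, tt, rep(0.5, 20)) - onCurve)), 1e-9)
  expect_lt(max(abs(evalSurface(e2, tt, rep(0.5, 20)) - onCurve)), 1e-9)
  ## and cross it transversally: ruling directions differ markedly
  r1 <- t(vapply(tt, e1@ruling, numeric(3)))
  r2 <- t(vapply(tt, e2@ruling, numeric(3)))
  ang <- acos(pmin(1, abs(rowSums(r1 * r2))))
  expect_gt(min(ang), 0.1)
})

test_that("surface partials agree with finite differences", {
  h <- 1e-6
  fdCheck <- function(surf, u, v) {
    pp <- surfaceUVPartials(surf, u, v)
    du <- (evalSurface(surf, u + h, v) - evalSurface(surf, u - h, v)) /
      (2 * h)
    dv <- (evalSurface(surf, u, v + h) - evalSurface(surf, u, v - h)) /
      (2 * h)
    scale <- max(1, max(abs(pp$du)), max(abs(pp$dv)))
    expect_lt(max(abs(pp$du - du)) / scale, 1e-5)
    expect_lt(max(abs(pp$dv - dv)) / scale, 1e-5)
  }
  u <- seq(0.1, 0.9, length.out = 5); v <- seq(0.1, 0.9, length.out = 5)
  fdCheck(ellipsoidPatch(c(1, 2, 3), c(1, 1, 0) / sqrt(2), 12, 20), u, v)
  fdCheck(offsetRevolution(
    ellipsoidPatch(c(1, 2, 3), c(0, 0, 1), 12, 20), -4), u, v)
  fdCheck(buildDevelopable(helixBezier(), "envelope", extent = c(-3, 3),
                           d = c(1, 0, 0)), u, v)
})
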