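test_that("geodesic curvature closed forms: cylinder and cone", {
  r <- 6
  ## generalized cylinder over its cross circle: the circle is a geodesic
  ## of nothing -- its kappa_g on the cylinder vanishes
  cyl <- ruledSurface(circleCurve(r), function(t) c(0, 0, 1),
                      extent = c(0, 10))
  tt <- seq(0, 1, length.out = 50)
  expect_lt(max(abs(geodesicCurvature(cyl, t = tt))), 1e-9)
  ## straight ruling on the cylinder: a geodesic, via the projection path
  t0 <- 0.3
  p0 <- curveEval(circleCurve(r), t0, 0L)[1, ]
  line <- bezierCurve(rbind(p0 + c(0, 0, 1), p0 + c(0, 0, 9)))
  kg <- geodesicCurvature(cyl, line, c(0.2, 0.5, 0.8))
  expect_lt(max(abs(kg)), 1e-6)
  ## base circle of a right circular cone: kappa_g = 1 / slant length
  H <- 15; L <- sqrt(r^2 + H^2)
  apex <- c(0, 0, H)
  cone <- ruledSurface(circleCurve(r), function(t) {
    d <- apex - curveEval(circleCurve(r), t, 0L)[1, ]
    d / sqrt(sum(d^2))
  }, extent = c(0, L))
  expect_equal(geodesicCurvature(cone, t = c(0.2, 0.7)), rep(1 / L, 2),
               tolerance = 1e-9)
})

test_that("developCurve reproduces lines, circles, and order-2 convergence", {
  ## kappa_g = 0, v = 1 on [0,1]: the unit segment
  d0 <- developCurve(rep(0, 11), rep(1, 11), seq(0, 1, 0.1))
  expect_equal(d0@planePoints[11, ], c(1, 0))
  expect_equal(max(abs(d0@planePoints[, 2])), 0)
  ## kappa_g = 1/r over a full turn: a closed circle of radius r
  r <- 7; n <- 2000
  ts <- seq(0, 2 * pi * r, length.out = n)
  dc <- developCurve(rep(1 / r, n), rep(1, n), ts)
  gap <- sqrt(sum((dc@planePoints[n, ] - dc@planePoints[1, ])^2))
  expect_lt(gap, 1e-4 * r)
  ## radius check: center at (0, r)
  expect_lt(max(abs(sqrt(dc@planePoints[, 1]^2 +
                           (dc@planePoints[, 2] - r)^2) - r)), 1e-4 * r)
  ## arc length preserved within quadrature tolerance
  expect_lt(abs(polylineLength(dc@planePoints) - 2 * pi * r) / (2 * pi * r),
            1e-5)
  ## half circle endpoint error decays at order 2
  err <- vapply(c(500, 1000, 2000), function(m) {
    th <- seq(0, pi * r, length.out = m)
    d <- developCurve(rep(1 / r, m), rep(1, m), th)
    sqrt(sum((d@planePoints[m, ] - c(0, 2 * r))^2))
  }, numeric(1))
  expect_gt(err[1] / err[2], 3.5)
  expect_gt(err[2] / err[3], 3.5)
  ## invalid inputs
  expect_error(developCurve(c(0, 0, 0), c(1, 1, 1), c(0, 0.5, 0.2)),
               "increasing")
})

test_that("cylinder unfolding preserves widths, lengths and the metric", {
  arc <- bezierCurve(rbind(c(0, 0, 0), c(15, 20, 0), c(35, 22, 0),
                           c(50, 0, 0)))
  cyl <- buildDevelopable(arc, "cylinder", extent = c(-8, 8), d = c(0, 0, 1))
  tex <- mkTexture(cyl, 401, 17)
  sheet <- unfoldSurface(cyl, tex)
  ## every planar ruling is straight with the 3D length (16 mm)
  for (i in c(1, 200, 401)) {
    seg <- sheet@planeGrid[i, , ]
    expect_equal(polylineLength(seg), 16)
    expect_lt(collinearityResidual(seg), 1e-9)
  }
  ## directrix length preserved within quadrature tolerance at 401 samples
  ## (v = 0.5 is the u-offset-0 row)
  p3 <- curveEval(arc, tex@u, 0L)
  expect_lt(abs(polylineLength(sheet@planeGrid[, 9, ]) -
                  polylineLength(p3)) / polylineLength(p3), 1e-5)
  ## straight-directrix cylinder: machine-precision isometry
  lin <- bezierCurve(rbind(c(0, 0, 0), c(30, 10, 0)))
  flat <- buildDevelopable(lin, "cylinder", extent = c(-5, 5),
                           d = c(0, 0, 1))
  d0 <- flatteningDistortion(flat, unfoldSurface(flat, mkTexture(flat, 101,
                                                                 11)))
  expect_lt(d0$maxRelDeviation, 1e-8)
  expect_lt(abs(d0$areaRatio - 1), 1e-8)
})

test_that("the rectifying developable flattens its directrix straight", {
  cv <- helixBezier()
  rect <- buildDevelopable(cv, "rectifying", extent = c(-3, 3))
  tex <- mkTexture(rect, 400, 21)
  sheet <- unfoldSurface(rect, tex, directrixChoice = "pregeodesic")
  pp <- sheet@planeGrid[, 11, ]
  expect_lt(collinearityResidual(pp), 1e-6 * polylineLength(pp))
  ## a nonplanar directrix on its generalized cylinder is no pregeodesic
  ## (a planar one perpendicular to the rulings would be: cross-sections of
  ## cylinders are geodesics)
  cyl <- buildDevelopable(cv, "cylinder", extent = c(-8, 8), d = c(0, 0, 1))
  expect_error(unfoldSurface(cyl, mkTexture(cyl, 101, 5),
                             directrixChoice = "pregeodesic"),
               "pregeodesic")
})

test_that("a cone patch develops into the classical sector", {
  r <- 8; H <- 15; L <- sqrt(r^2 + H^2)
  apex <- c(0, 0, H)
  circ <- circleCurve(r)
  cone <- ruledSurface(circ, function(t) {
    d <- apex - curveEval(circ, t, 0L)[1, ]
    d / sqrt(sum(d^2))
  }, extent = c(0, L))
  n <- 2001
  sheet <- unfoldSurface(cone, mkTexture(cone, n, 5))
  base <- sheet@planeGrid[, 1, ]          # developed base circle
  ang <- 2 * pi * r / L                   # sector angle
  ## chord between the sector's boundary radii
  chord <- sqrt(sum((base[n, ] - base[1, ])^2))
  expect_lt(abs(chord - 2 * L * sin(ang / 2)) / (2 * L * sin(ang / 2)),
            1e-4)
  ## the developed base keeps distance L from the developed apex
  apex2d <- sheet@planeGrid[1, 5, ]
  expect_lt(max(abs(sqrt(rowSums(sweep(base, 2, apex2d)^2)) - L)) / L, 1e-4)
  ## the apex row collapses to one point
  expect_lt(max(dist(sheet@planeGrid[seq(1, n, by = 200), 5, ])), 1e-4)
})

test_that("developments from different anchors are congruent", {
  cv <- helixBezier()
  env <- buildDevelopable(cv, "envelope", extent = c(-3, 3), d = c(1, 0, 0))
  tex <- mkTexture(env, 150, 15)
  s1 <- unfoldSurface(env, tex)
  s2 <- unfoldSurface(env, tex, anchorIndex = 75L)
  a <- cbind(as.numeric(s1@planeGrid[, , 1]), as.numeric(s1@planeGrid[, , 2]))
  b <- cbind(as.numeric(s2@planeGrid[, , 1]), as.numeric(s2@planeGrid[, , 2]))
  ## Procrustes: align b to a by the optimal rigid motion
  ca <- sweep(a, 2, colMeans(a)); cb <- sweep(b, 2, colMeans(b))
  sv <- svd(crossprod(cb, ca))
  rot <- sv$u %*% diag(c(1, det(sv$u %*% t(sv$v)))) %*% t(sv$v)
  expect_lt(max(abs(cb %*% rot - ca)), 1e-6)
})

test_that("isometry holds for all constructions; twisted surfaces fail", {
  mkCurve <- function(seed) helixBezier(seed = seed, sd = 0.5)
  for (seed in c(31L, 32L, 33L)) {
    cv <- mkCurve(seed)
    surfs <- list(
      buildDevelopable(cv, "cylinder", extent = c(-3, 3), d = c(0, 0, 1)),
      buildDevelopable(cv, "envelope", extent = c(-3, 3), d = c(1, 0, 0)),
      buildDevelopable(cv, "rectifying", extent = c(-3, 3)))
    for (s in surfs) {
      tex <- mkTexture(s, 200, 51)          # odd nv: v = 0.5 is on the grid
      sheet <- unfoldSurface(s, tex)
      ## ruling lengths exact, directrix length and area within 1e-3
      expect_equal(polylineLength(sheet@planeGrid[100, , ]), 6,
                   tolerance = 1e-9)
      L3 <- polylineLength(curveEval(cv, tex@u, 0L))
      expect_lt(abs(polylineLength(sheet@planeGrid[, 26, ]) - L3) / L3,
                1e-3)
      d <- flatteningDistortion(s, sheet)
      expect_lt(abs(d$areaRatio - 1), 1e-3)
    }
  }
  ## negative control: audit a twisted ruled surface (defect gate bypassed)
  cv <- mkCurve(31L)
  tw <- twistedSurface(cv, extent = c(-3, 3))
  sheetT <- unfoldSurface(tw, mkTexture(tw, 200, 50), defectTol = Inf)
  expect_gt(flatteningDistortion(tw, sheetT)$maxRelDeviation, 1e-2)
  ## and the defect gate refuses it by default
  expect_error(unfoldSurface(tw, mkTexture(tw, 50, 5)), "not developable")
})
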