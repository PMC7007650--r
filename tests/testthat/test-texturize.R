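test_that("trilinear interpolation is exact on lattice points and constants", {
  vol <- rampVolume(nSlices = 5L, dim = 12L, spacing = c(1, 1, 2))
  ## lattice point: stored gray
  s <- vol@slices[[2]]
  p <- pixelPosition(s, 3, 7)
  expect_equal(trilinearGray(vol, p), as.numeric(s@gray[4, 8]))
  ## constant volume: any interior point returns the constant
  const <- generatePhantom(phantomSpec(
    trilinearRampField(c(c0 = 42)), nSlices = 4L, matrixDim = c(8L, 8L)))
  set.seed(3)
  q <- cbind(runif(20, 0, 7), runif(20, 0, 7), runif(20, 0, 6))
  expect_equal(trilinearGray(const, q), rep(42, 20))
})

test_that("trilinear interpolation reproduces a trilinear field to rounding", {
  vol <- rampVolume(nSlices = 6L, dim = 16L, spacing = c(1, 1, 2))
  set.seed(4)
  p <- cbind(runif(200, 0, 15), runif(200, 0, 15), runif(200, 0, 10))
  g <- trilinearGray(vol, p)
  gt <- groundTruthGray(trilinearRampField(), p)
  expect_lte(max(abs(g - gt)), 0.5)
  ## non-uniform slice spacing is handled through actual slab extents
  vol2 <- rampVolume(nSlices = 6L, dim = 16L, spacing = c(1, 1, 2),
                     poseMode = "parallel_nonuniform", seed = 5L)
  expect_true(vol2@regular)
  expect_false(vol2@uniform)
  zmax <- max(vol2@zs)
  p2 <- cbind(runif(200, 0, 15), runif(200, 0, 15), runif(200, 0, zmax))
  expect_lte(max(abs(trilinearGray(vol2, p2) -
                       groundTruthGray(trilinearRampField(), p2))), 0.5)
})

test_that("trilinear output is bounded and continuous across cell faces", {
  set.seed(6)
  vol <- generatePhantom(phantomSpec(
    brightShellField(center = c(8, 8, 6), a = 4, b = 5, thickness = 0.4),
    nSlices = 7L, matrixDim = c(16L, 16L)))
  p <- cbind(runif(100, 0, 15), runif(100, 0, 15), runif(100, 0, 12))
  g <- trilinearGray(vol, p)
  rng <- range(unlist(lapply(vol@slices, slot, "gray")))
  expect_true(all(g >= rng[1] - 1e-9 & g <= rng[2] + 1e-9))
  ## continuity across interior lattice planes (ramp: O(1) gray gradients,
  ## so a 1e-9 mm straddle moves the value by ~1e-8 gray at most)
  ramp <- rampVolume(nSlices = 7L, dim = 16L, spacing = c(1, 1, 2))
  for (x0 in c(3, 7, 11)) {
    pa <- cbind(x0 - 1e-9, runif(20, 0, 15), runif(20, 0, 12))
    pb <- cbind(x0 + 1e-9, pa[, 2], pa[, 3])
    expect_lt(max(abs(trilinearGray(ramp, pa) - trilinearGray(ramp, pb))),
              1e-6)
  }
})

test_that("trilinear signals out-of-volume and non-regular geometry", {
  vol <- rampVolume(nSlices = 3L, dim = 8L)
  expect_error(trilinearGray(vol, c(100, 0, 0)), class = "outOfVolumeError")
  expect_true(is.na(trilinearGray(vol, c(100, 0, 0), outside = "na")))
  fan <- rampVolume(nSlices = 3L, dim = 8L, poseMode = "nonparallel_fan")
  expect_error(trilinearGray(fan, c(1, 1, 1)), class = "nonRegularError")
})

test_that("sub-box partition conserves data points and counts sub-boxes", {
  vol <- rampVolume(nSlices = 4L, dim = 10L)
  expect_equal(subBoxCount(buildPartition(vol, 17L)), 4913)
  expect_equal(subBoxCount(buildPartition(vol, 20L)), 8000)
  part <- buildPartition(vol, c(3L, 4L, 5L))
  expect_equal(subBoxCount(part), 60)
  expect_equal(sum(lengths(part@buckets)), nDataPoints(vol))
  ## scattered points: conservation for any divisions
  set.seed(8)
  pts <- matrix(runif(30, 0, 10), ncol = 3)
  for (m in list(1L, 2L, c(2L, 3L, 4L))) {
    pp <- pointPartition(pts, seq_len(10), m)
    expect_equal(sum(lengths(pp@buckets)), 10L)
  }
  ## works for non-parallel stacks too
  fan <- rampVolume(nSlices = 3L, dim = 6L, poseMode = "nonparallel_fan")
  pf <- buildPartition(fan, 4L)
  expect_equal(sum(lengths(pf@buckets)), nDataPoints(fan))
})

test_that("nearest-neighbor lookup matches an exhaustive in-box search", {
  set.seed(9)
  pts <- matrix(runif(1500, 0, 20), ncol = 3)
  gray <- sample.int(4000, nrow(pts), replace = TRUE)
  part <- pointPartition(pts, gray, 5L, bb = c(0, 20, 0, 20, 0, 20))
  q <- matrix(runif(300, 0, 20), ncol = 3)
  nn <- nearestNeighborGray(part, q)
  ids <- curvedslices:::subBoxIndex(q, part@bbox, part@divisions)
  idsPts <- curvedslices:::subBoxIndex(pts, part@bbox, part@divisions)
  for (k in seq_len(nrow(q))) {
    inBox <- which(idsPts == ids[k])
    if (!length(inBox)) {
      expect_false(nn$informed[k])
      expect_equal(nn$gray[k], -1)
    } else {
      d <- sqrt(rowSums(sweep(pts[inBox, , drop = FALSE], 2, q[k, ])^2))
      expect_equal(nn$gray[k], as.numeric(gray[inBox[which.min(d)]]))
    }
  }
  ## a query on a data point returns that point's gray
  nn2 <- nearestNeighborGray(part, pts[17, ])
  expect_true(nn2$informed)
  expect_equal(nn2$gray, as.numeric(gray[17]))
  ## idempotent under data-point duplication
  part2 <- pointPartition(rbind(pts, pts), c(gray, gray), 5L,
                          bb = c(0, 20, 0, 20, 0, 20))
  nnDup <- nearestNeighborGray(part2, q)
  expect_equal(nnDup$gray, nn$gray)
  ## outside the box
  expect_error(nearestNeighborGray(part, c(99, 0, 0)),
               class = "outOfVolumeError")
})

test_that("extended neighbor search only fills uninformed samples", {
  set.seed(10)
  pts <- matrix(runif(90, 0, 10), ncol = 3)
  part <- pointPartition(pts, seq_len(30), 6L, bb = c(0, 10, 0, 10, 0, 10))
  q <- matrix(runif(150, 0, 10), ncol = 3)
  plain <- nearestNeighborGray(part, q)
  ext <- nearestNeighborGray(part, q, extended = TRUE)
  expect_true(all(ext$informed >= plain$informed))
  ## where the own sub-box already had a point, results can differ only if a
  ## neighbor box holds a closer point; informed stays TRUE
  expect_true(all(ext$informed[plain$informed]))
})

test_that("a surface coincident with a slice reads that slice's pixels", {
  vol <- rampVolume(nSlices = 4L, dim = 9L)
  s <- vol@slices[[2]]
  ## ruled 'plane': directrix along rows, rulings along columns
  n <- sliceRows(s)
  dtx <- bezierCurve(rbind(s@origin, s@origin + (n - 1) * s@spacingRow *
                             s@rowDir))
  plane <- ruledSurface(dtx, function(t) s@colDir,
                        extent = c(0, (sliceCols(s) - 1) * s@spacingCol))
  tex <- texturizeSurface(plane, vol, "nearest",
                          resolution = c(sliceRows(s), sliceCols(s)),
                          divisions = 3L)
  expect_true(all(tex@informed))
  expect_equal(tex@gray, matrix(as.numeric(s@gray), sliceRows(s)))
})

test_that("texturized ellipsoid matches the analytic field under trilinear", {
  vol <- rampVolume(nSlices = 8L, dim = 24L, spacing = c(1, 1, 2))
  surf <- ellipsoidPatch(c(11, 11, 7), c(0, 0, 1), 5, 8)
  tex <- texturizeSurface(surf, vol, "trilinear", resolution = c(24L, 24L))
  gr <- expand.grid(u = tex@u, v = tex@v)
  gt <- groundTruthGray(trilinearRampField(), evalSurface(surf, gr$u, gr$v))
  expect_true(all(tex@informed))
  expect_lte(max(abs(tex@gray - matrix(gt, 24))), 0.5)
  ## samples outside the volume are uninformed, not clamped
  big <- ellipsoidPatch(c(11, 11, 7), c(0, 0, 1), 40, 40)
  texBig <- texturizeSurface(big, vol, "trilinear", resolution = c(16L, 16L))
  expect_gt(uninformedCount(texBig), 0)
  expect_true(all(texBig@gray[!texBig@informed] == -1))
})

test_that("uninformed counts grow with the sub-box divisions", {
  fld <- brightShellField(center = c(32, 32, 30), axis = c(0, 0, 1),
                          a = 18, b = 18, thickness = 0.15)
  vol <- generatePhantom(phantomSpec(fld, nSlices = 16L,
                                     matrixDim = c(64L, 64L),
                                     spacing = c(1, 1, 4)))
  set.seed(12)
  nSurf <- 8L
  for (k in seq_len(nSurf)) {
    surf <- ellipsoidPatch(c(32, 32, 30) + runif(3, -2, 2), c(0, 0, 1),
                           18 + runif(1, -3, 3), 18 + runif(1, -3, 3))
    t17 <- texturizeSurface(surf, vol, "nearest", resolution = c(40L, 40L),
                            divisions = 17L)
    t20 <- texturizeSurface(surf, vol, "nearest", resolution = c(40L, 40L),
                            divisions = 20L)
    expect_gte(uninformedCount(t20), uninformedCount(t17))
  }
})
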