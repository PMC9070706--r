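test_that("Ram-Lak filtering kills DC and matches the band-integral oracle", {
  cst <- matrix(5, 3, 64)
  out <- ramlakFilter(cst)
  expect_lt(max(abs(out)), 1e-10 * 5)
  # impulse response: even, sign-alternating, equal to the quadrature of
  # the continuous band integral of |f| at the central taps
  n <- 256
  imp <- numeric(n); imp[n / 2 + 1] <- 1
  q <- ramlakFilter(matrix(imp, 1), padMode = "zero")[1, ]
  quad <- function(x) {
    f <- seq(-0.5, 0.5, length.out = 20001)
    sum(abs(f) * cos(2 * pi * f * x)) * (f[2] - f[1])
  }
  taps <- -8:8
  expect_equal(q[n / 2 + 1 + taps], vapply(taps, quad, numeric(1)),
               tolerance = 1e-3)
  expect_equal(q[n / 2 + 1], 0.25, tolerance = 1e-4)
  expect_equal(q[n / 2 + 1 + 1:8], q[n / 2 + 1 - 1:8])        # even
  expect_true(all(q[n / 2 + 1 + c(1, 3, 5)] < 0))             # odd taps < 0
  expect_lt(max(abs(q[n / 2 + 1 + c(2, 4, 6)])), 1e-10)       # even taps ~ 0
})

test_that("Ram-Lak filtering is a linear operator", {
  set.seed(71)
  a <- matrix(rnorm(5 * 100), 5, 100)
  b <- matrix(rnorm(5 * 100), 5, 100)
  expect_equal(ramlakFilter(2 * a - 3 * b, padMode = "zero"),
               2 * ramlakFilter(a, padMode = "zero") -
                 3 * ramlakFilter(b, padMode = "zero"),
               tolerance = 1e-12)
})

test_that("parallel FBP reconstructs the quantitative voxel contract", {
  # centered uniform disk, 256 angles, 128^2 grid: interior ~ dx * mu
  ph <- diskPhantom(cx = 0, cy = 0, r = 2, mu = 0.5)
  W <- 128
  g <- scanGeometry("parallel", nProj = 256, axisU = (W - 1) / 2, axisV = 0,
                    pixelPitch = 100)
  sino <- phantomSinogram(ph, g, W)
  sl <- fbpParallel(sino, n = W)
  xs <- (1:W) - (W + 1) / 2
  interior <- sl[outer(xs^2, xs^2, "+") < 14^2]
  exterior <- sl[outer(xs^2, xs^2, "+") > 30^2 & outer(xs^2, xs^2, "+") < 50^2]
  dxmu <- 0.1 * 0.5
  expect_lt(abs(mean(interior) - dxmu) / dxmu, 0.03)
  expect_lt(abs(mean(exterior)), 5e-4 * mean(interior))
  # all-zero sinogram gives an all-zero slice
  z <- sinogram(matrix(0, 32, 64), (0:31) * pi / 32)
  expect_equal(fbpParallel(z, n = 32), matrix(0, 32, 32))
})

test_that("a point-like phantom reconstructs at the correct voxel", {
  ph <- phantomSpec(data.frame(shape = "cylinder", cx = 0.8, cy = -0.5,
                               cz = 0, ax = 0.08, ay = 0.08, az = 2,
                               mu = 5), extent = 6)
  W <- 96
  g <- scanGeometry("parallel", nProj = 192, axisU = (W - 1) / 2, axisV = 0,
                    pixelPitch = 100)
  sl <- fbpParallel(phantomSinogram(ph, g, W), n = W)
  pk <- which(sl == max(sl), arr.ind = TRUE)
  xs <- (1:W) - (W + 1) / 2
  # phantom at (+8, -5) voxels; slice is [y, x]
  expect_equal(xs[pk[1, "col"]], 8, tolerance = 0.51)
  expect_equal(xs[pk[1, "row"]], -5, tolerance = 0.51)
})

test_that("angular subsampling consistency: more angles, lower interior error", {
  ph <- diskPhantom(cx = 0.3, cy = 0.1, r = 1.6, mu = 0.5)
  W <- 96
  err <- vapply(c(24L, 48L, 96L), function(np) {
    g <- scanGeometry("parallel", nProj = np, axisU = (W - 1) / 2, axisV = 0,
                      pixelPitch = 100)
    sl <- fbpParallel(phantomSinogram(ph, g, W), n = W)
    truth <- rasterizePhantom(ph, g, centeredRegion(W, 1))[, , 1] * 0.1
    xs <- (1:W) - (W + 1) / 2
    circ <- outer(xs^2, xs^2, "+") < 40^2   # streaks live off the disk too
    sqrt(mean((sl - truth)[circ]^2))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("FBP warns on short angular spans and off-detector axes", {
  s <- sinogram(matrix(1, 16, 32), (0:15) * (pi / 2) / 16)
  expect_warning(fbpParallel(s, n = 16), "180")
  s2 <- sinogram(matrix(1, 16, 32), (0:15) * pi / 16, axisU = 40)
  expect_warning(fbpParallel(s2, n = 16), "axis")
})

test_that("reconstruction is linear in the projections", {
  set.seed(72)
  W <- 48
  g <- scanGeometry("parallel", nProj = 32, axisU = (W - 1) / 2,
                    axisV = (W - 1) / 2, pixelPitch = 100)
  a <- array(rnorm(W * W * 32), c(W, W, 32))
  b <- array(rnorm(W * W * 32), c(W, W, 32))
  reg <- centeredRegion(24, 2)
  va <- reconstructVolume(a, g, reg)
  vb <- reconstructVolume(b, g, reg)
  vab <- reconstructVolume(a + b, g, reg)
  expect_equal(vab, va + vb, tolerance = 1e-9)
})

test_that("general back projection agrees with fbpParallel slice by slice", {
  ph <- diskPhantom(cx = 0.3, cy = 0.1, r = 1.5, mu = 0.5)
  W <- 64
  g <- scanGeometry("parallel", nProj = 96, axisU = (W - 1) / 2,
                    axisV = (W - 1) / 2, pixelPitch = 100)
  L <- projectScan(ph, g, c(W, W))
  # pick z so the sampled detector row is exactly an integer row
  reg <- volumeRegion(c(-23.5, 23.5, 1), c(-23.5, 23.5, 1), c(-0.5, -0.5, 1))
  vol <- reconstructVolume(L, g, reg)
  sino <- makeSinograms(L, W / 2, g)[[1]]
  sl <- fbpParallel(sino, region = reg)
  expect_lt(max(abs(vol[, , 1] - sl)), 1e-6 * max(abs(sl)))
})

test_that("cone beam at huge source distance converges to parallel beam", {
  ph <- phantomSpec(data.frame(shape = "ellipsoid", cx = 0.3, cy = 0.1,
                               cz = 0, ax = 1.5, ay = 1.5, az = 1.5,
                               mu = 0.5), extent = 6)
  W <- 64
  gp <- scanGeometry("parallel", nProj = 96, axisU = (W - 1) / 2,
                     axisV = (W - 1) / 2, pixelPitch = 100)
  gc <- scanGeometry("cone", nProj = 96, angles = gp@angles,
                     axisU = (W - 1) / 2, axisV = (W - 1) / 2,
                     sourcePosition = c(0, -1e6, 0),
                     detectorPosition = c(0, 10, 0), pixelPitch = 100)
  reg <- volumeRegion(c(-23.5, 23.5, 1), c(-23.5, 23.5, 1), c(-0.5, -0.5, 1))
  vp <- reconstructVolume(projectScan(ph, gp, c(W, W)), gp, reg)
  vc <- reconstructVolume(projectScan(ph, gc, c(W, W)), gc, reg)
  expect_rel_rms(vc, vp, 0.01)
})

test_that("zero laminographic tilt equals the tomographic path exactly", {
  ph <- phantomSpec(data.frame(shape = "ellipsoid", cx = 0.4, cy = 0.2,
                               cz = 0.1, ax = 1, ay = 1, az = 0.5, mu = 0.8),
                    extent = 6)
  W <- 64
  g0 <- scanGeometry("parallel", nProj = 64, angleStep = 2 * pi / 64,
                     axisU = (W - 1) / 2, axisV = (W - 1) / 2,
                     laminoTilt = 0, pixelPitch = 100)
  gEps <- scanGeometry("parallel", nProj = 64, angleStep = 2 * pi / 64,
                       axisU = (W - 1) / 2, axisV = (W - 1) / 2,
                       laminoTilt = 1e-13, pixelPitch = 100)
  L <- projectScan(ph, g0, c(W, W))
  reg <- centeredRegion(32, 4)
  v0 <- reconstructVolume(L, g0, reg)
  vE <- reconstructVolume(L, gEps, reg)
  expect_equal(vE, v0, tolerance = 1e-9)
})

test_that("a tilted-axis scan reconstructs the object in place", {
  ph <- phantomSpec(data.frame(shape = "ellipsoid", cx = 0.4, cy = 0.2,
                               cz = 0.1, ax = 1, ay = 1, az = 0.5, mu = 0.8),
                    extent = 6)
  W <- 64
  g <- scanGeometry("parallel", nProj = 128, angleStep = 2 * pi / 128,
                    axisU = (W - 1) / 2, axisV = (W - 1) / 2,
                    laminoTilt = 20.91 * pi / 180, pixelPitch = 100)
  L <- projectScan(ph, g, c(W, W))
  reg <- centeredRegion(48, 16)
  v <- reconstructVolume(L, g, reg)
  idx <- which(v > 0.5 * max(v), arr.ind = TRUE)
  w <- v[idx]
  axx <- seq(-23.5, 23.5); axz <- seq(-7.5, 7.5)
  centroid <- c(sum(axx[idx[, 2]] * w), sum(axx[idx[, 1]] * w),
                sum(axz[idx[, 3]] * w)) / sum(w)
  expect_equal(centroid, c(4, 2, 1), tolerance = 0.15)
})

test_that("helical cone trajectories recover sphere centroids within a voxel", {
  ph <- phantomSpec(data.frame(shape = "ellipsoid",
                               cx = c(0.3, 0, -0.3), cy = c(0, 0.3, 0),
                               cz = c(-0.75, 0, 0.75),
                               ax = 0.3, ay = 0.3, az = 0.3, mu = 1),
                    extent = 6)
  np <- 240; turns <- 3
  ang <- (0:(np - 1)) * turns * 2 * pi / np
  z <- (ang / (2 * pi)) * 0.8
  z <- z - mean(z)
  g <- scanGeometry("cone", angles = ang, axisU = 23.5, axisV = 23.5,
                    sourcePosition = cbind(0, -50, z),
                    detectorPosition = cbind(0, 50, z), pixelPitch = 100)
  expect_equal(g@voxelSize, 50)   # 2x magnification
  L <- projectScan(ph, g, c(48L, 48L))
  reg <- volumeRegion(c(-23.5, 23.5, 1), c(-23.5, 23.5, 1), c(-21, 21, 1))
  vol <- reconstructVolume(L, g, reg)
  axx <- seq(-23.5, 23.5); axz <- seq(-21, 21)
  voxmm <- g@voxelSize / 1000
  truthX <- c(0.3, 0, -0.3) / voxmm
  truthY <- c(0, 0.3, 0) / voxmm
  truthZ <- c(-0.75, 0, 0.75) / voxmm
  for (k in 1:3) {
    sel <- which(abs(axz - truthZ[k]) <= 7)
    sub <- vol[, , sel]
    idx <- which(sub > 0.5 * max(sub), arr.ind = TRUE)
    w <- sub[idx]
    cent <- c(sum(axx[idx[, 2]] * w), sum(axx[idx[, 1]] * w),
              sum(axz[sel][idx[, 3]] * w)) / sum(w)
    expect_lt(sqrt(sum((cent - c(truthX[k], truthY[k], truthZ[k]))^2)), 1)
  }
})

test_that("regions outside the reconstructable support warn and return zeros", {
  g <- scanGeometry("parallel", nProj = 8, axisU = 3.5, axisV = 3.5,
                    pixelPitch = 100)
  a <- array(1, c(8, 8, 8))
  farRegion <- volumeRegion(c(-2, 2, 1), c(-2, 2, 1), c(500, 504, 1))
  expect_warning(v <- reconstructVolume(a, g, farRegion), "detector|region")
  expect_true(all(v == 0))
})

test_that("parameter sweeps find the true axis and degrade away from it", {
  ph <- diskPhantom(cx = 0.6, cy = 0.25, r = 1.2, mu = 0.5)
  W <- 96
  trueAxis <- 52.25
  g <- scanGeometry("parallel", nProj = 96, axisU = trueAxis, axisV = 0,
                    pixelPitch = 100)
  L <- projectScan(ph, g, c(1L, W))
  sweep <- sweepSpec("axis_u", seq(trueAxis - 3, trueAxis + 3, by = 0.25))
  reg <- volumeRegion(c(-31.5, 31.5, 1), c(-31.5, 31.5, 1))
  stack <- sweepReconstruct(L, g, sweep, reg)
  expect_equal(dim(stack), c(64L, 64L, length(sweep@values)))
  metric <- sliceMetric(stack)
  best <- sweep@values[which.max(metric)]
  expect_lt(abs(best - trueAxis), 0.5)
  # monotone blur on both sides of the optimum
  k <- which.max(metric)
  expect_true(all(diff(metric[1:k]) > 0))
  expect_true(all(diff(metric[k:length(metric)]) < 0))
  # a single-element sweep equals the plain reconstruction
  one <- sweepReconstruct(L, g, sweepSpec("axis_u", trueAxis), reg)
  direct <- reconstructVolume(L, g, volumeRegion(reg@xRange, reg@yRange,
                                                 c(0, 0, 1)))
  expect_equal(one[, , 1], direct[, , 1])
})

test_that("slice metrics report masked standard deviations", {
  cst <- matrix(3, 32, 32)
  expect_equal(sliceMetric(cst), 0)
  # half/half slice inside the full (unmasked) frame: analytic sd
  half <- cbind(matrix(0, 16, 8), matrix(1, 16, 8))
  expect_equal(sliceMetric(half, circularMask = FALSE),
               sd(c(rep(0, 128), rep(1, 128))))
  # ranking matches direct recomputation
  set.seed(73)
  st <- array(rnorm(16 * 16 * 5, sd = rep(1:5, each = 256)), c(16, 16, 5))
  m <- sliceMetric(st)
  ref <- vapply(1:5, function(k) {
    sl <- st[, , k]
    cy <- 7.5; r <- 7.5
    msk <- outer(((0:15) - cy)^2, ((0:15) - cy)^2, "+") <= r^2
    sd(sl[msk])
  }, numeric(1))
  expect_equal(m, ref)
  expect_equal(order(m), order(ref))
})

test_that("both axis estimators localize the rotation axis to sub-pixel", {
  ph <- diskPhantom(cx = 0.6, cy = 0.25, r = 1.2, mu = 0.5)
  W <- 128
  trueAxis <- 70.25
  g <- scanGeometry("parallel", nProj = 180, angleStep = 2 * pi / 180,
                    axisU = trueAxis, axisV = 0, pixelPitch = 100)
  L <- projectScan(ph, g, c(1L, W))
  aPair <- estimateAxis(L, "pair_correlation", angles = g@angles)
  expect_lt(abs(aPair - trueAxis), 0.5)
  sino <- sinogram(t(matrix(L, W, 180)), g@angles)
  aSweep <- estimateAxis(sino, "sweep_metric",
                         searchRange = c(trueAxis - 8, trueAxis + 8))
  expect_lt(abs(aSweep - trueAxis), 0.5)
  # the two methods agree on noisy data within a pixel
  set.seed(74)
  Ln <- L + array(rnorm(length(L), sd = 0.01 * max(L)), dim(L))
  n1 <- estimateAxis(Ln, "pair_correlation", angles = g@angles)
  n2 <- estimateAxis(sinogram(t(matrix(Ln, W, 180)), g@angles),
                     "sweep_metric",
                     searchRange = c(trueAxis - 8, trueAxis + 8))
  expect_lt(abs(n1 - n2), 1)
  # centered symmetric phantom: axis at the detector center
  phc <- diskPhantom(cx = 0, cy = 0, r = 1.2, mu = 0.5)
  gc <- scanGeometry("parallel", nProj = 180, angleStep = 2 * pi / 180,
                     axisU = (W - 1) / 2, axisV = 0, pixelPitch = 100)
  Lc <- projectScan(phc, gc, c(1L, W))
  expect_equal(estimateAxis(Lc, "pair_correlation", angles = gc@angles),
               (W - 1) / 2, tolerance = 1e-6)
  # pair correlation needs a ~180 degree counterpart
  gHalf <- scanGeometry("parallel", nProj = 40, angleStep = (pi / 2) / 40,
                        axisU = trueAxis, axisV = 0, pixelPitch = 100)
  Lh <- projectScan(ph, gHalf, c(1L, W))
  expect_error(estimateAxis(Lh, "pair_correlation", angles = gHalf@angles),
               "180")
})

test_that("histogram clipping and quantization obey the linear map", {
  v <- array(seq(-1, 3, length.out = 64), c(4, 4, 4))
  q8 <- clipQuantize(v, 0, 2, 8L)
  expect_equal(min(q8[v <= 0]), 0L)
  expect_equal(max(q8), 255L)
  expect_equal(q8[which.min(abs(v - 1))], 128L, tolerance = 1)
  q16 <- clipQuantize(v, 0, 2, 16L)
  # round-trip dequantization error bounded by one quantization step
  back <- q16 / 65535 * 2
  clipped <- pmin(pmax(v, 0), 2)
  expect_lt(max(abs(back - as.numeric(clipped))), 2 / 65535)
  expect_error(clipQuantize(v, 2, 0), "high")
  expect_error(clipQuantize(v, 0, 1, 12L), "bits")
})

test_that("orthogonal slices index the volume mid-planes", {
  v <- array(rnorm(5 * 7 * 9), c(5, 7, 9))
  o <- orthogonalSlices(v)
  expect_equal(o$xy, v[, , 5])
  expect_equal(o$xz, v[3, , ])
  expect_equal(o$yz, v[, 4, ])
  # a marked voxel shows up in all three planes through it
  v2 <- array(0, c(5, 7, 9))
  v2[3, 4, 5] <- 9
  o2 <- orthogonalSlices(v2)
  expect_equal(o2$xy[3, 4], 9)
  expect_equal(o2$xz[4, 5], 9)
  expect_equal(o2$yz[3, 5], 9)
  # symmetric volume gives symmetric slices
  sym <- array(0, c(5, 5, 3))
  sym[, , 2] <- outer(abs(-2:2), abs(-2:2))
  os <- orthogonalSlices(sym)
  expect_equal(os$xy, os$xy[5:1, ])
  expect_equal(os$xy, os$xy[, 5:1])
})
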