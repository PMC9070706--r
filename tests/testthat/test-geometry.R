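test_that("magnification and effective pixel size reproduce textbook arithmetic", {
  expect_equal(signif(magnification(38, 462), 3), 13.2)
  expect_equal(signif(magnification(700, 1000), 2), 2.4)
  expect_equal(effectivePixelSize(200, magnification(700, 1000)), 82.35,
               tolerance = 1e-4)
  expect_equal(signif(effectivePixelSize(200, magnification(85.5, 1629)), 2),
               10)
  # detector at the sample: no magnification
  for (x in c(1, 38, 700)) expect_equal(magnification(x, 0), 1)
  expect_equal(effectivePixelSize(6.5, 1), 6.5)
  expect_error(magnification(0, 100), "ssd")
  expect_error(magnification(-5, 100), "ssd")
  expect_error(effectivePixelSize(200, 0), "magnification")
})

test_that("geometry validity catches inconsistent inputs", {
  expect_error(scanGeometry("parallel", angles = c(0, NA, 1)), "finite")
  expect_error(scanGeometry("parallel", nProj = 4, pixelPitch = -1),
               "pixelPitch")
  expect_error(scanGeometry("parallel", nProj = 4, voxelSize = 0), "voxelSize")
  # cone beam needs positive source-detector separation along the beam
  expect_error(scanGeometry("cone", nProj = 4,
                            sourcePosition = c(0, 100, 0),
                            detectorPosition = c(0, 50, 0)),
               "separation")
  g <- scanGeometry("parallel", nProj = 8)
  expect_s4_class(g, "ScanGeometry")
  expect_equal(nProjections(g), 8L)
  expect_equal(angles(g), (0:7) * pi / 8)
})

test_that("the volume origin projects to the axis point for any projection", {
  g <- scanGeometry("cone", nProj = 7, angleStep = 0.7, axisU = 120.25,
                    axisV = 33.5, laminoTilt = 0.3, axisRoll = 0.1,
                    detectorOrientation = c(0.02, -0.01, 0.05),
                    volumeOrientation = c(0.1, 0.2, -0.3),
                    sourcePosition = c(2, -80, 1),
                    detectorPosition = c(-1, 120, 3), pixelPitch = 50)
  for (i in c(1L, 4L, 7L)) {
    uv <- projectVoxel(g, c(0, 0, 0), i)
    expect_equal(as.numeric(uv), c(120.25, 33.5), tolerance = 1e-9)
  }
})

test_that("aligned parallel projection maps voxels linearly onto the detector", {
  g <- scanGeometry("parallel", nProj = 4, angleStart = 0, angleStep = pi / 4,
                    axisU = 31.5, axisV = 15.5, pixelPitch = 100)
  # theta = 0, voxel (a, 0, b): u = axisU + a, v = axisV + b (voxel = pitch)
  uv <- projectVoxel(g, rbind(c(3, 0, 2), c(-5, 0, 0), c(0, 0, -7)), 1L)
  expect_equal(uv[, "u"], c(34.5, 26.5, 31.5), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(uv[, "v"], c(17.5, 15.5, 8.5), tolerance = 1e-12,
               ignore_attr = TRUE)
  # parallel mapping ignores the source position
  g2 <- scanGeometry("parallel", nProj = 4, angleStep = pi / 4, axisU = 31.5,
                     axisV = 15.5, sourcePosition = c(55, -3, 7),
                     pixelPitch = 100)
  p <- matrix(rnorm(15), 5, 3)
  expect_equal(projectVoxel(g, p, 2L), projectVoxel(g2, p, 2L))
})

test_that("rotating a point along the axis is equivalent to advancing the angle", {
  set.seed(11)
  g <- scanGeometry("parallel", nProj = 32, angleStep = 2 * pi / 32,
                    axisU = 63.5, axisV = 63.5, laminoTilt = 0.25,
                    axisRoll = 0.07, pixelPitch = 80)
  rotY <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0,
                               sin(a), 0, cos(a)), 3, 3)
  rotX <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a),
                               0, -sin(a), cos(a)), 3, 3)
  axisDir <- as.numeric(rotY(0.07) %*% rotX(0.25) %*% c(0, 0, 1))
  rodrigues <- function(a, t) {
    a <- a / sqrt(sum(a^2))
    K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
    diag(3) + sin(t) * K + (1 - cos(t)) * K %*% K
  }
  dtheta <- 2 * pi / 32
  for (rep in 1:5) {
    p <- rnorm(3) * 5
    i <- sample(1:24, 1)
    j <- i + 4L   # theta_j = theta_i + 4 steps
    pRot <- as.numeric(rodrigues(axisDir, -4 * dtheta) %*% p)
    expect_equal(projectVoxel(g, pRot, i), projectVoxel(g, p, j),
                 tolerance = 1e-9)
  }
})

test_that("cone projection matches an independent homogeneous-matrix oracle", {
  set.seed(12)
  g <- scanGeometry("cone", nProj = 12, angleStep = 0.5, axisU = 100.75,
                    axisV = 42.5, laminoTilt = 0.35, axisRoll = -0.12,
                    detectorOrientation = c(0.03, 0.02, -0.04),
                    volumeOrientation = c(-0.1, 0.15, 0.2),
                    sourcePosition = c(1, -90, 2),
                    detectorPosition = c(-2, 110, 1),
                    pixelPitch = 75, voxelSize = 40)
  # oracle: change of basis to put the rotation axis on z, rotate with Rz,
  # then project in the detector's own frame with a perspective divide
  rotXo <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  rotYo <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  rotZo <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  B <- rotYo(-0.12) %*% rotXo(0.35)            # maps z to the tilted axis
  Rdet <- rotXo(0.03) %*% rotYo(0.02) %*% rotZo(-0.04)
  oracle <- function(vox, i) {
    p <- rotXo(-0.1) %*% rotYo(0.15) %*% rotZo(0.2) %*% (vox * 40 / 1000)
    lab <- B %*% rotZo(-g@angles[i]) %*% t(B) %*% p
    toDet <- function(q) as.numeric(t(Rdet) %*% (q - c(-2, 110, 1)))
    sq <- toDet(c(1, -90, 2))
    project <- function(q) {
      qd <- toDet(q)
      tt <- -sq[2] / (qd[2] - sq[2])
      hit <- sq + tt * (qd - sq)
      hit[c(1, 3)]
    }
    ab <- project(as.numeric(lab))
    ab0 <- project(c(0, 0, 0))
    c(100.75, 42.5) + (ab - ab0) / (75 / 1000)
  }
  for (rep in 1:6) {
    vox <- rnorm(3) * 20
    i <- sample(1:12, 1)
    expect_equal(as.numeric(projectVoxel(g, vox, i)), oracle(vox, i),
                 tolerance = 1e-9)
  }
})

test_that("zero tilt cone mapping reduces to the textbook fan formula", {
  g <- scanGeometry("cone", nProj = 4, angleStep = 0.3, axisU = 63.5,
                    axisV = 63.5, sourcePosition = c(0, -100, 0),
                    detectorPosition = c(0, 150, 0), pixelPitch = 100,
                    voxelSize = 100)
  # at theta = 0 a voxel (x', y', z') maps to u-offset M * x'/(1 + y'/ssd)
  M <- magnification(100, 150)
  for (vox in list(c(10, 0, 0), c(10, 20, 0), c(-8, -15, 5))) {
    uv <- projectVoxel(g, vox, 1L)
    xmm <- vox[1] * 0.1; ymm <- vox[2] * 0.1; zmm <- vox[3] * 0.1
    uExp <- 63.5 + M * xmm / (1 + ymm / 100) / 0.1
    vExp <- 63.5 + M * zmm / (1 + ymm / 100) / 0.1
    expect_equal(as.numeric(uv), c(uExp, vExp), tolerance = 1e-9)
  }
})

test_that("cone rays parallel to the detector plane are flagged out of view", {
  g <- scanGeometry("cone", nProj = 1, angles = 0, axisU = 0, axisV = 0,
                    sourcePosition = c(0, -10, 0),
                    detectorPosition = c(0, 10, 0), pixelPitch = 1000,
                    voxelSize = 1000)
  # a voxel level with the source: the ray runs parallel to the plane
  uv <- projectVoxel(g, c(5, -10, 0), 1L)
  expect_true(all(is.na(uv)))
})

test_that("volume regions and sweep specs validate their ranges", {
  expect_error(volumeRegion(c(0, -1, 1), c(0, 1, 1)), "stop")
  expect_error(volumeRegion(c(0, 1, 0), c(0, 1, 1)), "step")
  r <- centeredRegion(8, 2)
  ax <- tomoreco:::regionAxes(r)
  expect_equal(ax$x, seq(-3.5, 3.5))
  expect_equal(ax$z, c(-0.5, 0.5))
  expect_error(sweepSpec("axis_u", numeric()), "non-empty")
  expect_error(sweepSpec("axis_u", c(1, 3, 2)), "monotone")
  expect_error(sweepSpec("zoom", 1:3), "unsupported")
  expect_s4_class(sweepSpec("lamino_tilt", c(0.1, 0.2)), "SweepSpec")
})
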