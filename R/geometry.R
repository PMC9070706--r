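# Reconstruction coordinate system and voxel-to-detector mapping.
#
# Conventions (also documented on the ScanGeometry class): right-handed
# frame, beam along +y, detector u along +x, v along +z, rotation axis +z at
# zero tilt. A volume point p (mm, sample frame) observed at angle theta is
# at lab position R_axis(-theta) %*% p, which makes a parallel projection of
# (x, y, 0) land at column axisU + x*cos(theta) + y*sin(theta).

rotX <- function(a) {
  c0 <- cos(a); s0 <- sin(a)
  matrix(c(1, 0, 0, 0, c0, s0, 0, -s0, c0), 3, 3)
}
rotY <- function(a) {
  c0 <- cos(a); s0 <- sin(a)
  matrix(c(c0, 0, -s0, 0, 1, 0, s0, 0, c0), 3, 3)
}
rotZ <- function(a) {
  c0 <- cos(a); s0 <- sin(a)
  matrix(c(c0, s0, 0, -s0, c0, 0, 0, 0, 1), 3, 3)
}

# Intrinsic rotations about x, then y, then z.
rotationXYZ <- function(abc) rotX(abc[1L]) %*% rotY(abc[2L]) %*% rotZ(abc[3L])

# Rodrigues rotation about unit axis `a` by angle `t`.
rotationAboutAxis <- function(a, t) {
  a <- a / sqrt(sum(a^2))
  K <- matrix(c(0, a[3L], -a[2L], -a[3L], 0, a[1L], a[2L], -a[1L], 0), 3, 3)
  diag(3) + sin(t) * K + (1 - cos(t)) * (K %*% K)
}

# Row i of a per-projection position matrix (recycling a single row).
positionAt <- function(m, i) {
  if (nrow(m) == 1L) as.numeric(m[1L, ]) else as.numeric(m[i, ])
}

# Direction of the rotation axis: +z tilted by the laminographic angle about
# x, then rolled about the beam axis y.
axisDirection <- function(geom) {
  as.numeric(rotY(geom@axisRoll) %*% rotX(geom@laminoTilt) %*% c(0, 0, 1))
}

#' Construct a scan geometry
#'
#' @param beam \code{"parallel"} or \code{"cone"}.
#' @param nProj number of projections; defaults to \code{length(angles)}.
#' @param angles rotation angles in radians. If missing, an evenly spaced set
#'   \code{angleStart + (0:(nProj-1)) * angleStep} is generated.
#' @param angleStart,angleStep evenly-spaced angle constructor, radians;
#'   \code{angleStep} defaults to \code{pi/nProj} (a 180-degree scan).
#' @param axisU,axisV detector coordinates (0-based px) of the rotation-axis
#'   projection.
#' @param laminoTilt,axisRoll axis tilt and in-plane roll, radians.
#' @param detectorOrientation,volumeOrientation rotation triples (radians)
#'   about x, y, z, applied intrinsically in that order.
#' @param sourcePosition,detectorPosition 3-vectors or n-by-3 matrices, mm,
#'   relative to the volume center. Defaults place the detector on the beam
#'   axis at +100 mm and (for cone beam) the source at -100 mm.
#' @param pixelPitch physical detector pixel size, micrometres.
#' @param voxelSize reconstructed voxel edge, micrometres; defaults to the
#'   effective pixel size (pitch divided by magnification for cone beam).
#' @return A validated [ScanGeometry-class] object.
#' @examples
#' g <- scanGeometry("parallel", nProj = 100, axisU = 63.5, axisV = 63.5)
#' g
#' @export
scanGeometry <- function(beam = c("parallel", "cone"), nProj = NULL,
                         angles = NULL, angleStart = 0, angleStep = NULL,
                         axisU = 0, axisV = 0,
                         laminoTilt = 0, axisRoll = 0,
                         detectorOrientation = c(0, 0, 0),
                         volumeOrientation = c(0, 0, 0),
                         sourcePosition = c(0, -100, 0),
                         detectorPosition = c(0, 100, 0),
                         pixelPitch = 1, voxelSize = NULL) {
  beam <- match.arg(beam)
  if (is.null(angles)) {
    if (is.null(nProj)) stop("give either angles or nProj")
    if (is.null(angleStep)) angleStep <- pi / nProj
    angles <- angleStart + (seq_len(nProj) - 1L) * angleStep
  }
  nProj <- length(angles)
  asMat <- function(x) {
    if (is.matrix(x)) x else matrix(as.numeric(x), 1L, 3L)
  }
  src <- asMat(sourcePosition)
  det <- asMat(detectorPosition)
  if (is.null(voxelSize)) {
    voxelSize <- if (beam == "cone") {
      ssd <- meanSourceAxisDistance(src, detectorOrientation)
      sdd <- meanAxisDetectorDistance(det, detectorOrientation)
      effectivePixelSize(pixelPitch, magnification(ssd, sdd))
    } else pixelPitch
  }
  new("ScanGeometry", beam = beam, nProj = as.integer(nProj),
      angles = as.numeric(angles), axisU = axisU, axisV = axisV,
      laminoTilt = laminoTilt, axisRoll = axisRoll,
      detectorOrientation = as.numeric(detectorOrientation),
      sourcePosition = src, detectorPosition = det,
      volumeOrientation = as.numeric(volumeOrientation),
      pixelPitch = pixelPitch, voxelSize = voxelSize)
}

meanSourceAxisDistance <- function(src, detOrient) {
  nrm <- rotationXYZ(detOrient)[, 2L]
  mean(abs(src %*% nrm))
}
meanAxisDetectorDistance <- function(det, detOrient) {
  nrm <- rotationXYZ(detOrient)[, 2L]
  mean(abs(det %*% nrm))
}

#' Geometric magnification of a cone-beam setup
#'
#' @param ssd source-sample distance, mm (> 0).
#' @param sdd sample-detector distance, mm (>= 0).
#' @return \code{(ssd + sdd) / ssd}, unitless.
#' @examples
#' magnification(38, 462)    # microfocus X-ray CT: ~13.2x
#' magnification(700, 1000)  # helical scan: ~2.4x
#' @export
magnification <- function(ssd, sdd) {
  if (any(!is.finite(ssd)) || any(ssd <= 0)) stop("ssd must be > 0")
  if (any(sdd < 0)) stop("sdd must be >= 0")
  (ssd + sdd) / ssd
}

#' Effective (sample-plane) pixel size
#'
#' @param pixelPitch physical detector pixel size, micrometres (> 0).
#' @param magnification geometric magnification (> 0).
#' @return pitch / magnification, micrometres.
#' @examples
#' effectivePixelSize(200, magnification(700, 1000))  # 82.35 um
#' @export
effectivePixelSize <- function(pixelPitch, magnification) {
  if (any(pixelPitch <= 0)) stop("pixelPitch must be > 0")
  if (any(!is.finite(magnification)) || any(magnification <= 0))
    stop("magnification must be > 0")
  pixelPitch / magnification
}

# Detector basis for projection i: unit u/v directions, plane normal, plane
# anchor d0 (mm), and the in-plane coordinates (alpha0, beta0) where the
# volume origin projects (so that the origin maps to (axisU, axisV) px).
detectorBasis <- function(geom, i) {
  Rdet <- rotationXYZ(geom@detectorOrientation)
  uDir <- Rdet[, 1L]
  vDir <- Rdet[, 3L]
  nrm <- Rdet[, 2L]
  d0 <- positionAt(geom@detectorPosition, i)
  if (geom@beam == "cone") {
    s <- positionAt(geom@sourcePosition, i)
    dn <- sum(-s * nrm)                  # source -> origin along normal
    pn <- sum((d0 - s) * nrm)            # source -> plane along normal
    hit <- s + (pn / dn) * (0 - s)       # ray source->origin hits plane
    a0 <- sum((hit - d0) * uDir)
    b0 <- sum((hit - d0) * vDir)
  } else {
    b <- c(0, 1, 0)
    t0 <- sum((d0 - 0) * nrm) / sum(b * nrm)
    hit <- t0 * b
    a0 <- sum((hit - d0) * uDir)
    b0 <- sum((hit - d0) * vDir)
    s <- NULL
  }
  list(uDir = uDir, vDir = vDir, nrm = nrm, d0 = d0,
       alpha0 = a0, beta0 = b0, source = s)
}

#' Map voxels to detector coordinates for one projection
#'
#' Applies, in order: the volume orientation, the rotation by the projection
#' angle about the (possibly tilted and rolled) rotation axis, then either an
#' orthographic projection along the beam (parallel) or a central projection
#' from the source position (cone) onto the detector plane. The result is
#' offset so the rotation axis projects to \code{(axisU, axisV)} and
#' converted to pixels via the pixel pitch.
#'
#' @param geom a [ScanGeometry-class].
#' @param voxel numeric length-3 vector or n-by-3 matrix of voxel-center
#'   coordinates \code{(x, y, z)} in voxel units relative to the volume
#'   center.
#' @param i projection index (1-based).
#' @return n-by-2 matrix of \code{(u, v)} detector pixel coordinates,
#'   0-based. Cone rays parallel to the detector plane (or hitting it from
#'   behind) are flagged out-of-view as \code{NA}, not an error.
#' @export
projectVoxel <- function(geom, voxel, i) {
  stopifnot(is(geom, "ScanGeometry"))
  if (i < 1L || i > geom@nProj) stop("projection index out of range")
  V <- if (is.matrix(voxel)) voxel else matrix(voxel, ncol = 3L)
  voxmm <- geom@voxelSize / 1000
  P <- (V * voxmm) %*% t(rotationXYZ(geom@volumeOrientation))
  Rax <- rotationAboutAxis(axisDirection(geom), -geom@angles[i])
  L <- P %*% t(Rax)                       # lab positions, mm
  db <- detectorBasis(geom, i)
  pitchmm <- geom@pixelPitch / 1000
  if (geom@beam == "cone") {
    s <- db$source
    D <- sweep(L, 2L, s)                  # ray directions source -> voxel
    dn <- as.numeric(D %*% db$nrm)
    pn <- sum((db$d0 - s) * db$nrm)
    tt <- ifelse(dn > 1e-12 * abs(pn) | dn < -1e-12 * abs(pn), pn / dn, NA_real_)
    tt[!is.na(tt) & tt <= 0] <- NA_real_  # behind the source
    hit <- sweep(D * tt, 2L, s, FUN = "+")
  } else {
    b <- c(0, 1, 0)
    tt <- as.numeric((matrix(db$d0, nrow(L), 3L, byrow = TRUE) - L) %*% db$nrm) /
      sum(b * db$nrm)
    hit <- L + outer(tt, b)
  }
  rel <- sweep(hit, 2L, db$d0)
  alpha <- as.numeric(rel %*% db$uDir)
  beta <- as.numeric(rel %*% db$vDir)
  cbind(u = geom@axisU + (alpha - db$alpha0) / pitchmm,
        v = geom@axisV + (beta - db$beta0) / pitchmm)
}

# ---- VolumeRegion / SweepSpec constructors ---------------------------------

#' Construct a volume region
#'
#' @param xRange,yRange,zRange \code{c(start, stop, step)} in voxel units
#'   (inclusive of stop when it falls on the grid), centered at the volume
#'   origin.
#' @return A [VolumeRegion-class].
#' @examples
#' centeredRegion(64)                    # a 64^3 grid
#' volumeRegion(c(-32, 31, 1), c(-32, 31, 1), c(0, 0, 1))   # one slice
#' @export
volumeRegion <- function(xRange, yRange, zRange = c(0, 0, 1)) {
  new("VolumeRegion", xRange = as.numeric(xRange),
      yRange = as.numeric(yRange), zRange = as.numeric(zRange))
}

#' @rdname volumeRegion
#' @param n,nz grid sizes; \code{centeredRegion} builds an n-by-n-by-nz grid
#'   of unit voxel steps centered at the origin.
#' @export
centeredRegion <- function(n, nz = n) {
  half <- (n - 1) / 2
  halfz <- (nz - 1) / 2
  volumeRegion(c(-half, half, 1), c(-half, half, 1), c(-halfz, halfz, 1))
}

regionAxes <- function(region) {
  ax <- function(r) seq(r[1L], r[2L], by = r[3L])
  list(x = ax(region@xRange), y = ax(region@yRange), z = ax(region@zRange))
}

#' Construct a sweep specification
#'
#' @param parameterName \code{"axis_u"}, \code{"lamino_tilt"},
#'   \code{"axis_roll"} or \code{"angle_offset"}.
#' @param values strictly monotone parameter values.
#' @param fixedZ slice height in voxels (default 0, the central slice).
#' @return A [SweepSpec-class].
#' @export
sweepSpec <- function(parameterName, values, fixedZ = 0) {
  new("SweepSpec", parameterName = parameterName,
      values = as.numeric(values), fixedZ = fixedZ)
}

# ---- accessors --------------------------------------------------------------

#' Accessors for geometry and data containers
#'
#' @param x an object of the corresponding class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
nProjections <- function(x) {
  if (is(x, "ScanGeometry")) return(x@nProj)
  if (is(x, "ProjectionStack")) return(dim(x@frames)[3L])
  stop("unsupported type")
}

#' @rdname accessors
#' @export
angles <- function(x) {
  if (is(x, "ScanGeometry")) return(x@angles)
  if (is(x, "Sinogram")) return(x@angles)
  stop("unsupported type")
}

#' @rdname accessors
#' @export
frames <- function(x) {
  stopifnot(is(x, "ProjectionStack"))
  x@frames
}

#' @rdname accessors
#' @export
sinogramValues <- function(x) {
  stopifnot(is(x, "Sinogram"))
  x@values
}

#' @rdname accessors
#' @export
axisU <- function(x) {
  if (is(x, "ScanGeometry") || is(x, "Sinogram")) return(x@axisU)
  stop("unsupported type")
}

#' Construct a projection stack
#'
#' @param frames a 3D array \code{[v, u, frame]}, a matrix (one frame) or a
#'   list of equally sized matrices.
#' @param role \code{"tomo"}, \code{"flats"} or \code{"darks"}.
#' @return A [ProjectionStack-class].
#' @export
projectionStack <- function(frames, role = "tomo") {
  if (is.list(frames)) {
    d <- dim(frames[[1L]])
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(d, length(frames)))
  } else if (is.matrix(frames)) {
    frames <- array(frames, dim = c(dim(frames), 1L))
  }
  storage.mode(frames) <- "double"
  new("ProjectionStack", frames = frames, role = role)
}

#' Construct a sinogram
#'
#' @param values matrix \code{[angle, column]}.
#' @param angles rotation angles, radians.
#' @param axisU rotation-axis column, 0-based fractional px.
#' @return A [Sinogram-class].
#' @export
sinogram <- function(values, angles, axisU = (ncol(values) - 1) / 2) {
  new("Sinogram", values = as.matrix(values), angles = as.numeric(angles),
      axisU = axisU)
}

#' Extract sinograms from a projection stack
#'
#' @param stack a [ProjectionStack-class] or 3D array of absorptivity frames.
#' @param rows detector rows (1-based) to extract.
#' @param geom the [ScanGeometry-class] providing angles and axis position.
#' @return A list of [Sinogram-class] objects, one per requested row.
#' @export
makeSinograms <- function(stack, rows, geom) {
  a <- if (is(stack, "ProjectionStack")) stack@frames else stack
  lapply(rows, function(r) {
    sinogram(t(a[r, , ]), geom@angles, geom@axisU)
  })
}
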