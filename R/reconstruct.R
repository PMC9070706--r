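# Filtered back projection for all supported trajectories: Ram-Lak
# filtering, parallel-beam FBP from sinograms, voxel-driven back projection
# (FDK for cone beam) with per-projection geometry, parameter sweeps, axis
# estimation and output conditioning.

#' Ram-Lak (ramp) filtering of detector rows
#'
#' Rows are padded to at least twice their length -- by default sixteen
#' times, always the next power of two -- to suppress circular-convolution
#' outliers and the broad negative halo the sharp frequency cut of a short
#' ramp would otherwise leave around the object, multiplied by |frequency|
#' in Fourier space, inverse transformed and cropped. The operation is
#' linear and has exactly zero DC gain.
#'
#' @param rows matrix, one detector line per row (a sinogram, or one
#'   projection filtered along u).
#' @param padMode \code{"edge"} (replicate edge values) or \code{"zero"}.
#' @param window \code{"none"} (plain ramp) or \code{"cosine"} apodization.
#' @param padFactor minimum padding ratio (>= 2).
#' @return Filtered matrix of the input size.
#' @export
ramlakFilter <- function(rows, padMode = c("edge", "zero"),
                         window = c("none", "cosine"), padFactor = 16) {
  padMode <- match.arg(padMode)
  window <- match.arg(window)
  if (is.vector(rows)) rows <- matrix(rows, nrow = 1L)
  n <- ncol(rows)
  if (n < 2L) stop("rows must have length >= 2")
  N <- 2^ceiling(log2(max(2, padFactor) * n))
  padL <- (N - n) %/% 2L
  padR <- N - n - padL
  left <- if (padMode == "edge") rows[, rep(1L, padL), drop = FALSE]
          else matrix(0, nrow(rows), padL)
  right <- if (padMode == "edge") rows[, rep(n, padR), drop = FALSE]
           else matrix(0, nrow(rows), padR)
  padded <- cbind(left, rows, right)
  nu <- abs(fftFreq(N))                 # cycles per sample
  if (window == "cosine") nu <- nu * cos(pi * fftFreq(N))
  Ft <- mvfft(t(padded)) * nu
  filt <- t(Re(mvfft(Ft, inverse = TRUE))) / N
  filt[, padL + seq_len(n), drop = FALSE]
}

# angular back projection weight: Delta-theta, halved for full-turn scans
# where every ray is measured twice
angularWeight <- function(angles) {
  n <- length(angles)
  if (n < 2L) return(pi)
  step <- (max(angles) - min(angles)) / (n - 1L)
  span <- step * n
  if (span < pi - 1e-6)
    warning(sprintf("angles span only %.1f degrees (< 180)", span * 180 / pi))
  if (span > 1.5 * pi) step / 2 else step
}

#' Parallel-beam filtered back projection of one sinogram
#'
#' For each output pixel the filtered rows are sampled (linear
#' interpolation) at \code{u = axisU + x*cos(theta) + y*sin(theta)} and
#' summed with the angular weight. Grid coordinates are in detector-pixel
#' units, centered on the rotation axis; for monochromatic absorptivity
#' input the reconstructed values are the unitless \code{dx * mu} with
#' \code{dx} the (effective) detector pixel size.
#'
#' @param sino a [Sinogram-class] (or matrix; then \code{angles} and
#'   \code{axisU} must be given).
#' @param n output grid size (an n-by-n slice); default the detector width.
#' @param region optionally a [VolumeRegion-class]; its x/y ranges replace
#'   \code{n}.
#' @param filter apply the Ram-Lak filter (disable if rows are prefiltered).
#' @param padMode,window passed to [ramlakFilter()].
#' @param angles,axisU used when \code{sino} is a plain matrix.
#' @return Matrix slice \code{[y, x]} (both ascending, origin at the
#'   center).
#' @export
fbpParallel <- function(sino, n = NULL, region = NULL, filter = TRUE,
                        padMode = "edge", window = "none",
                        angles = NULL, axisU = NULL) {
  if (is(sino, "Sinogram")) {
    m <- sino@values
    angles <- sino@angles
    axisU <- sino@axisU
  } else {
    m <- sino
    if (is.null(angles) || is.null(axisU))
      stop("matrix input needs angles and axisU")
  }
  W <- ncol(m)
  if (axisU < 0 || axisU > W - 1)
    warning("rotation axis lies outside the detector")
  if (is.null(region)) {
    if (is.null(n)) n <- W
    half <- (n - 1) / 2
    xs <- seq(-half, half)
    ys <- xs
  } else {
    ax <- regionAxes(region)
    xs <- ax$x
    ys <- ax$y
  }
  q <- if (filter) ramlakFilter(m, padMode = padMode, window = window) else m
  w <- angularWeight(angles)
  acc <- matrix(0, length(ys), length(xs))
  for (i in seq_along(angles)) {
    u <- axisU + outer(ys * sin(angles[i]), xs * cos(angles[i]), "+")
    acc <- acc + matrix(.linearSampleCpp(q[i, ], as.numeric(u)),
                        length(ys), length(xs))
  }
  acc * w
}

# project a matrix of sample-frame positions (mm) for projection i;
# returns u, v (detector px, 0-based) and, for cone beam, the source-to-
# point distance component U along the detector normal
projectPoints <- function(geom, P, i, db = NULL) {
  Rax <- rotationAboutAxis(axisDirection(geom), -geom@angles[i])
  L <- P %*% t(Rax)
  if (is.null(db)) db <- detectorBasis(geom, i)
  pitchmm <- geom@pixelPitch / 1000
  if (geom@beam == "cone") {
    s <- db$source
    D <- sweep(L, 2L, s)
    dn <- as.numeric(D %*% db$nrm)
    pn <- sum((db$d0 - s) * db$nrm)
    bad <- abs(dn) < 1e-12 * abs(pn) | dn * pn <= 0
    tt <- ifelse(bad, NA_real_, pn / dn)
    hit <- sweep(D * tt, 2L, s, FUN = "+")
    U <- dn
  } else {
    b <- c(0, 1, 0)
    tt <- as.numeric(sweep(-L, 2L, db$d0, FUN = "+") %*% db$nrm) / sum(b * db$nrm)
    hit <- L + outer(tt, b)
    U <- NULL
  }
  rel <- sweep(hit, 2L, db$d0)
  list(u = geom@axisU + (as.numeric(rel %*% db$uDir) - db$alpha0) / pitchmm,
       v = geom@axisV + (as.numeric(rel %*% db$vDir) - db$beta0) / pitchmm,
       U = U)
}

#' Voxel-driven filtered back projection for arbitrary geometry
#'
#' Supports parallel and cone beam, tomography and laminography (tilted
#' axis), arbitrary detector/volume orientations and per-projection source
#' and detector positions (helical trajectories). Cone-beam data gets the
#' FDK treatment: rows are pre-weighted by
#' \code{ssd / sqrt(ssd^2 + u'^2 + v'^2)} before Ram-Lak filtering, and each
#' voxel-projection contribution is weighted by \code{(ssd/U)^2}, with
#' \code{U} the component of the source-to-voxel vector along the beam axis.
#' Only the detector rows intersecting the requested region are used.
#'
#' @param projections a [ProjectionStack-class] or 3D array of absorptivity
#'   (or phase) frames, \code{[v, u, projection]}.
#' @param geom the [ScanGeometry-class].
#' @param region a [VolumeRegion-class] (voxel units, origin-centered).
#' @param filter apply Ram-Lak filtering (disable for prefiltered input).
#' @param padMode,window passed to [ramlakFilter()].
#' @return 3D array \code{[y, x, z]}. Out-of-detector samples contribute
#'   zero; a region entirely outside the reconstructable support yields an
#'   all-zero volume with a warning.
#' @export
reconstructVolume <- function(projections, geom, region, filter = TRUE,
                              padMode = "edge", window = "none") {
  a <- if (is(projections, "ProjectionStack")) projections@frames else projections
  stopifnot(is(geom, "ScanGeometry"), is(region, "VolumeRegion"))
  if (dim(a)[3L] != geom@nProj)
    stop("projection count does not match geometry")
  ax <- regionAxes(region)
  nx <- length(ax$x); ny <- length(ax$y); nz <- length(ax$z)
  voxmm <- geom@voxelSize / 1000
  V <- cbind(rep(ax$x, each = ny, times = nz),
             rep(ax$y, times = nx * nz),
             rep(ax$z, each = ny * nx)) * voxmm
  Rvol <- rotationXYZ(geom@volumeOrientation)
  P <- V %*% t(Rvol)
  # region-limited row window: project the region's corner points
  corners <- as.matrix(expand.grid(range(ax$x), range(ax$y), range(ax$z))) *
    voxmm
  cornersP <- corners %*% t(Rvol)
  nr <- dim(a)[1L]; nu <- dim(a)[2L]
  vlo <- nr; vhi <- -1
  for (i in seq_len(geom@nProj)) {
    pv <- projectPoints(geom, cornersP, i)
    vv <- pv$v[is.finite(pv$v)]
    if (length(vv)) {
      vlo <- min(vlo, floor(min(vv)) - 1)
      vhi <- max(vhi, ceiling(max(vv)) + 1)
    }
  }
  vlo <- max(0, vlo); vhi <- min(nr - 1, vhi)
  if (vhi < vlo) {
    warning("requested region projects entirely outside the detector")
    return(array(0, dim = c(ny, nx, nz)))
  }
  rows <- (vlo + 1):(vhi + 1)
  w <- angularWeight(geom@angles)
  pitchmm <- geom@pixelPitch / 1000
  du <- ((0:(nu - 1)) - geom@axisU) * pitchmm
  dv <- ((vlo:vhi) - geom@axisV) * pitchmm
  # Per-projection trajectories (helical): each voxel is inside the cone for
  # only part of the scan, so normalize by the per-voxel count of
  # contributing projections (pi / N_seen reduces to the global angular
  # weight when every voxel sees every projection).
  perVoxel <- nrow(geom@sourcePosition) > 1L || nrow(geom@detectorPosition) > 1L
  acc <- numeric(nx * ny * nz)
  seen <- if (perVoxel) numeric(nx * ny * nz) else NULL
  anyHit <- FALSE
  for (i in seq_len(geom@nProj)) {
    db <- detectorBasis(geom, i)
    fr <- matrix(a[rows, , i], length(rows), nu)
    if (geom@beam == "cone") {
      ssd <- abs(sum(db$source * db$nrm))
      fr <- fr * (ssd / sqrt(ssd^2 + outer(dv^2, du^2, "+")))
    }
    if (filter) fr <- ramlakFilter(fr, padMode = padMode, window = window)
    pv <- projectPoints(geom, P, i, db = db)
    vRel <- pv$v - vlo
    val <- .bilinearSampleCpp(fr, pv$u, vRel)
    if (geom@beam == "cone") {
      ssd <- abs(sum(db$source * db$nrm))
      cw <- (ssd / pv$U)^2
      cw[!is.finite(cw)] <- 0
      val <- val * cw
    }
    if (perVoxel) {
      inside <- !is.na(pv$u) & pv$u >= 0 & pv$u <= nu - 1 &
        !is.na(vRel) & vRel >= 0 & vRel <= length(rows) - 1
      seen <- seen + inside
    }
    if (!anyHit && any(val != 0)) anyHit <- TRUE
    acc <- acc + val
  }
  if (!anyHit)
    warning("no projection data intersected the requested region")
  out <- if (perVoxel) acc * (pi / pmax(seen, 1)) else acc * w
  array(out, dim = c(ny, nx, nz))
}

#' Reconstruct one slice for a range of parameter values
#'
#' The third output dimension walks the sweep parameter instead of z: the
#' slice at height \code{fixedZ} is reconstructed once per parameter value
#' with the geometry overridden accordingly. Apply [sliceMetric()] to locate
#' the best value (e.g. for axis finding).
#'
#' @param projections as in [reconstructVolume()].
#' @param geom the base [ScanGeometry-class].
#' @param sweep a [SweepSpec-class].
#' @param region a [VolumeRegion-class]; its z range is replaced by the
#'   sweep's \code{fixedZ}.
#' @param ... passed to [reconstructVolume()].
#' @return 3D array \code{[y, x, parameter value]}.
#' @export
sweepReconstruct <- function(projections, geom, sweep, region, ...) {
  stopifnot(is(sweep, "SweepSpec"))
  sliceRegion <- volumeRegion(region@xRange, region@yRange,
                              c(sweep@fixedZ, sweep@fixedZ, 1))
  out <- NULL
  for (j in seq_along(sweep@values)) {
    g <- overrideParameter(geom, sweep@parameterName, sweep@values[j])
    sl <- reconstructVolume(projections, g, sliceRegion, ...)[, , 1L]
    if (is.null(out))
      out <- array(0, dim = c(dim(sl), length(sweep@values)))
    out[, , j] <- sl
  }
  out
}

overrideParameter <- function(geom, name, value) {
  switch(name,
    axis_u = { geom@axisU <- value; geom },
    lamino_tilt = { geom@laminoTilt <- value; geom },
    axis_roll = { geom@axisRoll <- value; geom },
    angle_offset = { geom@angles <- geom@angles + value; geom },
    stop("unsupported sweep parameter: ", name))
}

#' Per-slice image metric
#'
#' @param stack 3D array of slices (e.g. a sweep output) or a single matrix.
#' @param metric currently \code{"std"}: the standard deviation.
#' @param circularMask restrict to the inscribed circle (recommended, since
#'   the reconstructable support is circular).
#' @return Numeric vector, one value per slice.
#' @export
sliceMetric <- function(stack, metric = "std", circularMask = TRUE) {
  metric <- match.arg(metric, "std")
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  d <- dim(stack)
  mask <- if (circularMask) {
    cy <- (d[1L] - 1) / 2; cx <- (d[2L] - 1) / 2
    r <- min(cx, cy)
    outer(((seq_len(d[1L]) - 1) - cy)^2, ((seq_len(d[2L]) - 1) - cx)^2,
          "+") <= r^2
  } else matrix(TRUE, d[1L], d[2L])
  vapply(seq_len(d[3L]), function(k) sd(stack[, , k][mask]), numeric(1L))
}

#' Estimate the rotation-axis position
#'
#' \code{"pair_correlation"}: the projection nearest 0 degrees is
#' cross-correlated with the horizontally mirrored projection nearest 180
#' degrees; the correlation peak (with parabolic sub-pixel refinement) gives
#' the axis as \code{(W - 1 + shift) / 2}. \code{"sweep_metric"}: a
#' coarse-to-fine sweep of reconstructions over candidate axis positions,
#' maximizing the slice standard deviation.
#'
#' @param x a [ProjectionStack-class]/3D array of absorptivity projections
#'   (pair_correlation) or a [Sinogram-class] (either method; for
#'   pair_correlation its rows are used as 1-pixel-high projections).
#' @param method \code{"pair_correlation"} or \code{"sweep_metric"}.
#' @param angles projection angles (taken from the sinogram if available).
#' @param searchRange candidate axis range for sweep_metric, px (default
#'   the central half of the detector).
#' @param coarseStep initial sweep step, px.
#' @param refineLevels number of 4-fold refinement passes.
#' @return Estimated axis column, 0-based fractional px.
#' @export
estimateAxis <- function(x, method = c("pair_correlation", "sweep_metric"),
                         angles = NULL, searchRange = NULL, coarseStep = 4,
                         refineLevels = 3L) {
  method <- match.arg(method)
  if (is(x, "Sinogram")) {
    m <- x@values
    angles <- x@angles
  } else {
    a <- if (is(x, "ProjectionStack")) x@frames else x
    if (length(dim(a)) == 3L) {
      if (is.null(angles)) stop("give the projection angles")
      # column profiles, one row per projection
      m <- t(apply(a, 3L, colMeans))
    } else m <- a
  }
  W <- ncol(m)
  if (method == "pair_correlation") {
    i0 <- which.min(abs(wrapAngle(angles)))
    i180 <- which.min(abs(wrapAngle(angles - pi)))
    # tolerate one angular step of mismatch (180-degree scans stop at
    # pi minus one step)
    if (abs(wrapAngle(angles[i180] - angles[i0] - pi)) > 0.1)
      stop("no projection close to 180 degrees from the reference")
    p0 <- m[i0, ] - mean(m[i0, ])
    p180m <- rev(m[i180, ]) - mean(m[i180, ])
    # cross-correlation via FFT, shifts -W+1 .. W-1
    N <- 2^ceiling(log2(2L * W))
    A <- fft(c(p0, numeric(N - W)))
    B <- fft(c(p180m, numeric(N - W)))
    cc <- Re(fft(A * Conj(B), inverse = TRUE)) / N
    shifts <- c(0:(N / 2 - 1), -(N / 2):-1)
    valid <- abs(shifts) <= W - 1
    ccv <- cc[valid]; sv <- shifts[valid]
    k <- which.max(ccv)
    shift <- sv[k]
    # parabolic sub-pixel refinement around the peak
    km <- which(sv == shift - 1); kp <- which(sv == shift + 1)
    if (length(km) && length(kp)) {
      y1 <- ccv[km]; y2 <- ccv[k]; y3 <- ccv[kp]
      denom <- y1 - 2 * y2 + y3
      if (abs(denom) > 0) shift <- shift + 0.5 * (y1 - y3) / denom
    }
    return((W - 1 + shift) / 2)
  }
  # sweep_metric on a sinogram
  if (is.null(angles)) stop("give the projection angles")
  sino <- if (is(x, "Sinogram")) x else sinogram(m, angles)
  if (is.null(searchRange))
    searchRange <- c(W / 4, 3 * W / 4)
  step <- coarseStep
  lo <- searchRange[1L]; hi <- searchRange[2L]
  best <- NA_real_
  nGrid <- min(W, 128L)
  for (lev in seq_len(refineLevels + 1L)) {
    cand <- seq(lo, hi, by = step)
    vals <- vapply(cand, function(a0) {
      s2 <- sinogram(sino@values, sino@angles, a0)
      sl <- fbpParallel(s2, n = nGrid)
      sliceMetric(sl)
    }, numeric(1L))
    best <- cand[which.max(vals)]
    lo <- best - step; hi <- best + step
    step <- step / 4
  }
  best
}

wrapAngle <- function(a) {
  ((a + pi) %% (2 * pi)) - pi
}

#' Clip and quantize a volume to integers
#'
#' Linear map of \code{[low, high]} to \code{[0, 2^bits - 1]} with clipping
#' outside the range.
#'
#' @param volume numeric array.
#' @param low,high histogram clip limits.
#' @param bits 8 or 16.
#' @return Integer-valued array of the same shape.
#' @export
clipQuantize <- function(volume, low, high, bits = c(8L, 16L)) {
  bits <- as.integer(bits)[1L]
  if (!bits %in% c(8L, 16L)) stop("bits must be 8 or 16")
  if (high <= low) stop("high must be > low")
  top <- 2^bits - 1
  v <- pmin(pmax(volume, low), high)
  out <- round((v - low) / (high - low) * top)
  storage.mode(out) <- "integer"
  dim(out) <- dim(volume)
  out
}

#' Mid-plane orthogonal slices of a volume
#'
#' @param volume 3D array \code{[y, x, z]}.
#' @return List with \code{xy} (mid-z slice), \code{xz} (mid-y) and
#'   \code{yz} (mid-x).
#' @export
orthogonalSlices <- function(volume) {
  d <- dim(volume)
  mid <- function(n) (n + 1L) %/% 2L
  list(xy = matrix(volume[, , mid(d[3L])], d[1L], d[2L]),
       xz = matrix(volume[mid(d[1L]), , ], d[2L], d[3L]),
       yz = matrix(volume[, mid(d[2L]), ], d[1L], d[3L]))
}
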