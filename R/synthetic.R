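# Analytic phantoms, exact forward projection and artifact injection, so
# that every processing stage can be validated end-to-end without external
# data. Chord lengths through ellipsoids and (z-capped) cylinders are
# computed by quadratic intersection in the unrotated primitive frame, which
# makes the projections exact up to floating point for any beam geometry.

#' Construct a phantom specification
#'
#' @param primitives data.frame of primitives; see [PhantomSpec-class].
#' @param extent half-width of the support, mm.
#' @return A [PhantomSpec-class].
#' @examples
#' # a centered cylinder, radius 2 mm, mu = 0.5 / mm
#' ph <- phantomSpec(data.frame(shape = "cylinder", cx = 0, cy = 0, cz = 0,
#'                              ax = 2, ay = 2, az = 5, mu = 0.5), extent = 6)
#' @export
phantomSpec <- function(primitives, extent) {
  if (is.null(primitives$delta)) primitives$delta <- 0
  new("PhantomSpec", primitives = primitives, extent = extent)
}

# chord length of ray o + t*d (unit d) through one primitive row
chordLength <- function(prim, o, d) {
  # shift into the primitive frame and scale ellipsoid axes to a unit sphere
  ox <- (o[, 1L] - prim$cx)
  oy <- (o[, 2L] - prim$cy)
  oz <- (o[, 3L] - prim$cz)
  if (prim$shape == "ellipsoid") {
    sx <- ox / prim$ax; sy <- oy / prim$ay; sz <- oz / prim$az
    dx <- d[, 1L] / prim$ax; dy <- d[, 2L] / prim$ay; dz <- d[, 3L] / prim$az
    A <- dx^2 + dy^2 + dz^2
    B <- 2 * (sx * dx + sy * dy + sz * dz)
    C <- sx^2 + sy^2 + sz^2 - 1
    disc <- B^2 - 4 * A * C
    len <- numeric(length(A))
    hit <- disc > 0 & A > 0
    # |t2 - t1| in scaled space times the original parameter scale: the ray
    # parameter t is shared, so the chord is |t2 - t1| with unit lab d
    len[hit] <- sqrt(disc[hit]) / A[hit]
    return(len)
  }
  # cylinder along z, radius (ax, ay), half height az
  sx <- ox / prim$ax; sy <- oy / prim$ay
  dx <- d[, 1L] / prim$ax; dy <- d[, 2L] / prim$ay
  A <- dx^2 + dy^2
  B <- 2 * (sx * dx + sy * dy)
  C <- sx^2 + sy^2 - 1
  disc <- B^2 - 4 * A * C
  n <- length(A)
  t1 <- rep(NA_real_, n); t2 <- rep(NA_real_, n)
  hit <- disc > 0 & A > 1e-300
  sq <- sqrt(pmax(disc[hit], 0))
  t1[hit] <- (-B[hit] - sq) / (2 * A[hit])
  t2[hit] <- (-B[hit] + sq) / (2 * A[hit])
  # rays parallel to the axis: inside the ellipse for all t
  par <- A <= 1e-300
  inside <- par & (C < 0)
  t1[inside] <- -Inf; t2[inside] <- Inf
  # intersect with the z-slab |z - cz| <= az
  dz <- d[, 3L]
  zlo <- rep(-Inf, n); zhi <- rep(Inf, n)
  movez <- abs(dz) > 1e-300
  zA <- (-prim$az - oz[movez]) / dz[movez]
  zB <- (prim$az - oz[movez]) / dz[movez]
  zlo[movez] <- pmin(zA, zB)
  zhi[movez] <- pmax(zA, zB)
  flat <- !movez & abs(oz) > prim$az
  lo <- pmax(t1, zlo); hi <- pmin(t2, zhi)
  len <- pmax(hi - lo, 0)
  len[is.na(len)] <- 0
  len[flat] <- 0
  len
}

#' Exact line-integral projection of a phantom
#'
#' Computes the chord-length integrals of the attenuation coefficient
#' through every primitive along each detector-pixel ray of projection
#' \code{i}. The result \code{sum(mu * chord_mm)} is the unitless
#' absorptivity a monochromatic detector would measure, so flat-field
#' correction plus log of a simulated scan reproduces it exactly, and a
#' parallel-beam FBP of these frames recovers the per-pixel attenuation
#' \code{dx * mu} (dx the effective pixel size in mm).
#'
#' @param spec a [PhantomSpec-class]; \code{mu} in 1/mm, geometry in mm.
#' @param geom a [ScanGeometry-class].
#' @param i projection index (1-based).
#' @param shape detector size \code{c(nrow, ncol)} in px.
#' @param weight \code{"mu"} (attenuation, default) or \code{"delta"}
#'   (projected refractive-index decrement, for phase simulations).
#' @return Matrix \code{[v, u]} of line integrals.
#' @export
analyticProject <- function(spec, geom, i, shape, weight = c("mu", "delta")) {
  weight <- match.arg(weight)
  stopifnot(is(spec, "PhantomSpec"), is(geom, "ScanGeometry"))
  db <- detectorBasis(geom, i)
  nr <- shape[1L]; nc <- shape[2L]
  pitchmm <- geom@pixelPitch / 1000
  # lab-frame position of every detector pixel center
  us <- ((0:(nc - 1)) - geom@axisU) * pitchmm + db$alpha0
  vs <- ((0:(nr - 1)) - geom@axisV) * pitchmm + db$beta0
  U <- rep(us, each = nr)
  Vv <- rep(vs, times = nc)
  pix <- matrix(db$d0, nr * nc, 3L, byrow = TRUE) +
    outer(U, db$uDir) + outer(Vv, db$vDir)
  if (geom@beam == "cone") {
    o <- matrix(db$source, nr * nc, 3L, byrow = TRUE)
    d <- pix - o
    d <- d / sqrt(rowSums(d^2))
  } else {
    o <- pix
    d <- matrix(c(0, 1, 0), nr * nc, 3L, byrow = TRUE)
  }
  # transform rays into the sample frame: sample = Rvol^T R_axis(theta) lab
  Rax <- rotationAboutAxis(axisDirection(geom), geom@angles[i])
  M <- t(rotationXYZ(geom@volumeOrientation)) %*% Rax
  o <- o %*% t(M)
  d <- d %*% t(M)
  acc <- numeric(nr * nc)
  for (r in seq_len(nrow(spec@primitives))) {
    prim <- spec@primitives[r, ]
    wgt <- if (weight == "mu") prim$mu else prim$delta
    if (wgt == 0) next
    acc <- acc + wgt * chordLength(prim, o, d)
  }
  matrix(acc, nr, nc)
}

#' Discrete cross-check projector
#'
#' Numerically integrates the phantom's attenuation along the same rays as
#' [analyticProject()] by equidistant sampling, as an independent
#' cross-validation of the exact chords.
#'
#' @inheritParams analyticProject
#' @param step sampling step along the ray, mm.
#' @return Matrix \code{[v, u]} of approximate line integrals.
#' @export
sampleProject <- function(spec, geom, i, shape, step = NULL) {
  stopifnot(is(spec, "PhantomSpec"))
  if (is.null(step)) step <- spec@extent / 200
  db <- detectorBasis(geom, i)
  nr <- shape[1L]; nc <- shape[2L]
  pitchmm <- geom@pixelPitch / 1000
  us <- ((0:(nc - 1)) - geom@axisU) * pitchmm + db$alpha0
  vs <- ((0:(nr - 1)) - geom@axisV) * pitchmm + db$beta0
  U <- rep(us, each = nr)
  Vv <- rep(vs, times = nc)
  pix <- matrix(db$d0, nr * nc, 3L, byrow = TRUE) +
    outer(U, db$uDir) + outer(Vv, db$vDir)
  if (geom@beam == "cone") {
    o <- matrix(db$source, nr * nc, 3L, byrow = TRUE)
    d <- pix - o
    d <- d / sqrt(rowSums(d^2))
  } else {
    o <- pix
    d <- matrix(c(0, 1, 0), nr * nc, 3L, byrow = TRUE)
  }
  Rax <- rotationAboutAxis(axisDirection(geom), geom@angles[i])
  M <- t(rotationXYZ(geom@volumeOrientation)) %*% Rax
  o <- o %*% t(M)
  d <- d %*% t(M)
  # march from the support entry: center rays at closest approach to origin
  t0 <- -rowSums(o * d)
  span <- 2 * spec@extent * sqrt(3)
  ts <- seq(-span / 2, span / 2, by = step)
  acc <- numeric(nr * nc)
  for (tt in ts) {
    pos <- o + d * (t0 + tt)
    acc <- acc + phantomMu(spec, pos)
  }
  matrix(acc * step, nr, nc)
}

# attenuation value of the phantom at sample-frame positions (n x 3, mm)
phantomMu <- function(spec, pos) {
  out <- numeric(nrow(pos))
  for (r in seq_len(nrow(spec@primitives))) {
    p <- spec@primitives[r, ]
    sx <- (pos[, 1L] - p$cx) / p$ax
    sy <- (pos[, 2L] - p$cy) / p$ay
    sz <- (pos[, 3L] - p$cz) / p$az
    inside <- if (p$shape == "ellipsoid") sx^2 + sy^2 + sz^2 <= 1
              else sx^2 + sy^2 <= 1 & abs(pos[, 3L] - p$cz) <= p$az
    out <- out + p$mu * inside
  }
  out
}

#' Rasterize a phantom onto a voxel grid
#'
#' Ground truth for reconstruction error metrics: attenuation sampled at
#' voxel centers, in the same \code{[y, x, z]} layout as
#' [reconstructVolume()].
#'
#' @param spec a [PhantomSpec-class].
#' @param geom the [ScanGeometry-class] (voxel size).
#' @param region a [VolumeRegion-class].
#' @return 3D array of \code{mu} values (1/mm).
#' @export
rasterizePhantom <- function(spec, geom, region) {
  ax <- regionAxes(region)
  nx <- length(ax$x); ny <- length(ax$y); nz <- length(ax$z)
  voxmm <- geom@voxelSize / 1000
  pos <- cbind(rep(ax$x, each = ny, times = nz),
               rep(ax$y, times = nx * nz),
               rep(ax$z, each = ny * nx)) * voxmm
  array(phantomMu(spec, pos), dim = c(ny, nx, nz))
}

#' Convert line integrals to (optionally noisy) detector counts
#'
#' @param lineIntegrals matrix or 3D array of path integrals \code{L}.
#' @param I0 incident intensity (counts).
#' @param photonCount if \code{TRUE}, draw Poisson counts with mean
#'   \code{I0 * exp(-L)}.
#' @param seed RNG seed used when sampling (local to this call).
#' @return Counts frames, same shape.
#' @export
toTransmission <- function(lineIntegrals, I0, photonCount = FALSE, seed = 0L) {
  mean <- I0 * exp(-lineIntegrals)
  if (!photonCount) return(mean)
  withSeed(seed, {
    out <- rpois(length(mean), lambda = as.numeric(mean))
    dim(out) <- dim(mean)
    out
  })
}

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Inject the classic projection artifacts
#'
#' Adds (i) zingers: isolated salt impulses at a given per-pixel rate,
#' (ii) a scintillator spot: a fixed bright Gaussian blob present in every
#' frame, and (iii) per-column multiplicative gain errors drawn once for the
#' whole stack, which turn into rings after reconstruction. Reproducible by
#' seed.
#'
#' @param stack 3D array or [ProjectionStack-class] of counts frames.
#' @param zingerRate per-pixel probability of a zinger impulse.
#' @param zingerAmplitude impulse height (added), intensity units.
#' @param spotSpec \code{NULL} or a list with \code{u, v} (center, 1-based
#'   px), \code{radius} (px) and \code{amplitude}.
#' @param columnGainStd standard deviation of the per-column gain (around 1).
#' @param seed RNG seed (local to this call).
#' @return Same type as the input, plus an attribute \code{"zingerMask"}
#'   (logical array of injected impulse positions).
#' @export
injectArtifacts <- function(stack, zingerRate = 0, zingerAmplitude = NULL,
                            spotSpec = NULL, columnGainStd = 0, seed = 0L) {
  a <- if (is(stack, "ProjectionStack")) stack@frames else stack
  d <- dim(a)
  withSeed(seed, {
    zmask <- array(FALSE, dim = d)
    if (zingerRate > 0) {
      if (is.null(zingerAmplitude)) zingerAmplitude <- 10 * max(a)
      zmask <- array(runif(prod(d)) < zingerRate, dim = d)
      a[zmask] <- a[zmask] + zingerAmplitude
    }
    if (!is.null(spotSpec)) {
      blob <- spotSpec$amplitude *
        exp(-outer((seq_len(d[1L]) - spotSpec$v)^2,
                   (seq_len(d[2L]) - spotSpec$u)^2, "+") /
              (2 * spotSpec$radius^2))
      for (k in seq_len(d[3L])) a[, , k] <- matrix(a[, , k], d[1L], d[2L]) + blob
    }
    if (columnGainStd > 0) {
      gain <- 1 + rnorm(d[2L], sd = columnGainStd)
      gainM <- matrix(gain, d[1L], d[2L], byrow = TRUE)
      for (k in seq_len(d[3L])) a[, , k] <- matrix(a[, , k], d[1L], d[2L]) * gainM
    }
    out <- if (is(stack, "ProjectionStack")) projectionStack(a, stack@role) else a
    attr(out, "zingerMask") <- zmask
    out
  })
}

#' Simulate flat- and dark-field reference stacks
#'
#' @param shape \code{c(nrow, ncol)} detector size, px.
#' @param I0 flat-field level (counts).
#' @param darkLevel detector background level (counts).
#' @param noise Gaussian noise standard deviation (0 = constant frames).
#' @param n frames per stack.
#' @param seed RNG seed (local to this call).
#' @return List with \code{flats} and \code{darks} (3D arrays).
#' @export
makeFlatsDarks <- function(shape, I0, darkLevel = 0, noise = 0, n = 10L,
                           seed = 0L) {
  withSeed(seed, {
    mk <- function(level) {
      a <- array(level, dim = c(shape, n))
      if (noise > 0) a <- a + array(rnorm(prod(dim(a)), sd = noise), dim(a))
      a
    }
    list(flats = mk(I0), darks = mk(darkLevel))
  })
}

#' Simulate a complete scan of a phantom
#'
#' Convenience wrapper producing the projections of \code{spec} under
#' \code{geom} plus matching flats and darks, optionally with artifacts.
#'
#' @inheritParams analyticProject
#' @param shape detector size \code{c(nrow, ncol)}.
#' @param I0 flat-field level, counts.
#' @param darkLevel dark level, counts.
#' @param photonCount Poisson-sample the counts.
#' @param artifacts \code{NULL} or a list of [injectArtifacts()] arguments.
#' @param seed RNG seed.
#' @return List with \code{tomo}, \code{flats}, \code{darks} (3D arrays) and
#'   \code{lineIntegrals}.
#' @export
simulateScan <- function(spec, geom, shape, I0 = 1e4, darkLevel = 100,
                         photonCount = FALSE, artifacts = NULL, seed = 0L) {
  L <- array(0, dim = c(shape, geom@nProj))
  for (i in seq_len(geom@nProj))
    L[, , i] <- analyticProject(spec, geom, i, shape)
  tomo <- toTransmission(L, I0 - darkLevel, photonCount = photonCount,
                         seed = seed) + darkLevel
  if (!is.null(artifacts))
    tomo <- do.call(injectArtifacts, c(list(stack = tomo), artifacts,
                                       list(seed = seed + 1L)))
  refs <- makeFlatsDarks(shape, I0, darkLevel, noise = 0, n = 3L,
                         seed = seed + 2L)
  list(tomo = tomo, flats = refs$flats, darks = refs$darks,
       lineIntegrals = L)
}
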