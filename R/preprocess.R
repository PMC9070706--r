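# Intensity normalization and projection-space artifact repair: frame
# averaging, flat/dark-field correction, absorptivity, zinger removal,
# scintillator-spot masking + horizontal inpainting, and half-acquisition
# stitching.

#' Average a stack of frames
#'
#' Dark and flat fields are averaged before normalization; the median is
#' robust against zingers in the reference frames.
#'
#' @param stack a [ProjectionStack-class] or 3D array.
#' @param mode \code{"mean"} or \code{"median"}, element-wise.
#' @return A matrix.
#' @export
averageFrames <- function(stack, mode = c("mean", "median")) {
  mode <- match.arg(mode)
  a <- if (is(stack, "ProjectionStack")) stack@frames else stack
  if (is.matrix(a)) return(a)
  if (!length(a) || dim(a)[3L] < 1L) stop("empty stack")
  if (mode == "mean") {
    out <- a[, , 1L]
    if (dim(a)[3L] > 1L) out <- rowMeans(a, dims = 2L)
    out
  } else {
    apply(a, c(1L, 2L), median)
  }
}

#' Flat-field correction
#'
#' Computes the transmission \code{(p - dark) / (flat - dark)} and fixes
#' possible extreme values: any non-finite or non-positive result is replaced
#' by \code{eps}, so the output is strictly positive and safe to take the
#' logarithm of.
#'
#' @param p projection frame.
#' @param dark,flat averaged dark and flat frames (same shape as \code{p}).
#' @param eps replacement for invalid pixels (default \code{1e-6}).
#' @return Transmission frame, all values > 0.
#' @export
flatFieldCorrect <- function(p, dark, flat, eps = 1e-6) {
  if (!identical(dim(p), dim(dark)) || !identical(dim(p), dim(flat)))
    stop("frame shapes must match")
  t <- (p - dark) / (flat - dark)
  t[!is.finite(t) | t <= 0] <- eps
  t
}

#' Absorptivity of a transmission frame
#'
#' @param t transmission frame (values > 0).
#' @return \code{-log(t)}, the line integral of the attenuation coefficient.
#' @export
absorptivity <- function(t) -log(t)

#' Remove outlier pixels (zingers)
#'
#' A pixel is replaced by the median of its \code{(2*radius+1)^2}
#' neighborhood iff it deviates from that median by more than
#' \code{threshold} in the selected direction; all other pixels pass through
#' unchanged. Borders are handled by reflection.
#'
#' @param frame image matrix, or a [ProjectionStack-class]/3D array (each
#'   frame filtered independently).
#' @param radius neighborhood half-size, px (>= 1).
#' @param threshold deviation threshold, intensity units.
#' @param direction \code{"bright"}, \code{"dark"} or \code{"both"}.
#' @return Same shape as the input.
#' @export
removeOutliers <- function(frame, radius = 1L, threshold,
                           direction = c("both", "bright", "dark")) {
  direction <- match.arg(direction)
  if (radius < 1L) stop("radius must be >= 1")
  dirCode <- switch(direction, bright = 1L, dark = -1L, both = 0L)
  one <- function(m) {
    .removeOutliersCpp(reflectPad(m, radius), as.integer(radius),
                       threshold, dirCode)
  }
  applyFrames(frame, one)
}

# reflect-pad a matrix by r pixels on every side (edge row/col not repeated)
reflectPad <- function(m, r) {
  if (r == 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rev(seq_len(min(r, nr - 1L)) + 1L), seq_len(nr),
          nr - seq_len(min(r, nr - 1L)))
  ci <- c(rev(seq_len(min(r, nc - 1L)) + 1L), seq_len(nc),
          nc - seq_len(min(r, nc - 1L)))
  # if the image is smaller than the pad, recycle reflections
  while (length(ri) < nr + 2L * r) ri <- c(ri[1L], ri, ri[length(ri)])
  while (length(ci) < nc + 2L * r) ci <- c(ci[1L], ci, ci[length(ci)])
  m[ri, ci, drop = FALSE]
}

applyFrames <- function(x, f) {
  if (is(x, "ProjectionStack")) {
    a <- x@frames
    d <- dim(a)
    for (k in seq_len(d[3L])) a[, , k] <- f(matrix(a[, , k], d[1L], d[2L]))
    return(projectionStack(a, role = x@role))
  }
  if (is.matrix(x)) return(f(x))
  if (length(dim(x)) == 3L) {
    d <- dim(x)
    for (k in seq_len(d[3L])) x[, , k] <- f(matrix(x[, , k], d[1L], d[2L]))
    return(x)
  }
  stop("unsupported input")
}

#' Find large spots by thresholding and region growing
#'
#' Seeds are pixels deviating from the frame median by more than
#' \code{spotThreshold}; the mask is the union of 8-connected regions grown
#' from the seeds over pixels deviating by more than \code{growThreshold}.
#' Thresholds are relative to the frame median.
#'
#' @param frame image matrix.
#' @param spotThreshold seed threshold (absolute deviation from the median).
#' @param growThreshold growth threshold (<= \code{spotThreshold}).
#' @return Logical matrix, \code{TRUE} = invalid pixel.
#' @export
findLargeSpots <- function(frame, spotThreshold, growThreshold) {
  if (!is.finite(spotThreshold) || !is.finite(growThreshold))
    stop("thresholds must be finite")
  if (growThreshold > spotThreshold)
    stop("growThreshold must be <= spotThreshold")
  dev <- abs(frame - median(frame))
  mask <- dev > spotThreshold
  cand <- dev > growThreshold
  if (!any(mask)) return(mask)
  repeat {
    grown <- dilate8(mask) & cand
    if (identical(grown, mask)) break
    mask <- grown
  }
  mask
}

# one step of 8-connected binary dilation (edge-clamped)
dilate8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  sh <- function(di, dj) {
    ri <- pmin(pmax(seq_len(nr) + di, 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + dj, 1L), nc)
    m[ri, ci, drop = FALSE]
  }
  for (di in -1:1) for (dj in -1:1) {
    if (di || dj) out <- out | sh(di, dj)
  }
  out
}

#' Inpaint masked pixels by horizontal linear interpolation
#'
#' Per row, each masked run is replaced by linear interpolation between the
#' nearest unmasked neighbors; runs touching a row edge take the nearest
#' unmasked value. Fully masked rows borrow the nearest row with valid
#' pixels above/below. Unmasked pixels are unchanged; the operation is
#' idempotent.
#'
#' @param frame image matrix.
#' @param mask logical matrix, \code{TRUE} = replace.
#' @return Repaired frame.
#' @export
inpaintHorizontal <- function(frame, mask) {
  if (!identical(dim(frame), dim(mask))) stop("mask shape must match frame")
  if (!any(mask)) return(frame)
  out <- frame
  nr <- nrow(frame)
  rowsValid <- which(rowSums(!mask) > 0L)
  for (i in seq_len(nr)) {
    mi <- mask[i, ]
    if (!any(mi)) next
    if (all(mi)) next  # handled below from repaired neighbors
    good <- which(!mi)
    out[i, which(mi)] <- approx(good, frame[i, good], xout = which(mi),
                                rule = 2)$y
  }
  fullRows <- which(rowSums(!mask) == 0L)
  for (i in fullRows) {
    if (!length(rowsValid)) break
    j <- rowsValid[which.min(abs(rowsValid - i))]
    out[i, ] <- out[j, ]
  }
  out
}

#' Stitch a 0-360 degree half-acquisition scan
#'
#' With the rotation axis near a detector edge, projection i (angle theta)
#' and projection i + n/2 (theta + 180 degrees) view complementary halves of
#' the sample. The opposed projection is mirrored horizontally and placed so
#' its axis column coincides with the direct one; the overlap is blended
#' linearly. The result is a 0-180 degree stack of roughly doubled width
#' with the axis at the output center.
#'
#' @param stack a [ProjectionStack-class] or 3D array over 0-360 degrees
#'   (even frame count; frame i+n/2 at theta_i + 180 degrees).
#' @param axisU rotation-axis column, 0-based fractional px, in the right
#'   half of the frame (use \code{flip = TRUE} for a left-edge axis).
#' @param flip set when the axis sits in the left half; frames are mirrored
#'   before stitching.
#' @return A list with \code{frames} (stitched stack over 0-180 degrees,
#'   width \code{round(2 * (axisU + 0.5))}) and \code{axisU} (axis position
#'   in output coordinates; the direct frame keeps its columns, so this is
#'   the input value, at the output center up to rounding).
#' @export
stitchHalfAcquisition <- function(stack, axisU, flip = FALSE) {
  a <- if (is(stack, "ProjectionStack")) stack@frames else stack
  n <- dim(a)[3L]
  if (n %% 2L) stop("half-acquisition stitching needs an even frame count")
  W <- dim(a)[2L]
  if (axisU < 0 || axisU > W - 1) stop("axisU must lie within the frame")
  if (flip) {
    a <- a[, W:1, , drop = FALSE]
    axisU <- (W - 1) - axisU
  }
  Wout <- as.integer(round(2 * (axisU + 0.5)))
  half <- n %/% 2L
  # Output column j holds the direct frame at u = j and the mirrored opposed
  # frame at u' = 2*axisU - j (sampled with linear interpolation when the
  # axis is fractional); the overlap is blended linearly.
  jj <- 0:(Wout - 1L)
  sMirror <- 2 * axisU - jj
  dCov <- jj <= W - 1L
  mCov <- sMirror >= 0 & sMirror <= W - 1
  nOver <- sum(dCov & mCov)
  if (nOver > 0.8 * W)
    warning("axis close to the detector center: overlap exceeds 80%")
  wDirect <- as.numeric(dCov)
  wMirror <- as.numeric(mCov)
  ovr <- which(dCov & mCov)
  if (length(ovr)) {
    ramp <- seq(0, 1, length.out = length(ovr) + 2L)[seq_along(ovr) + 1L]
    wDirect[ovr] <- 1 - ramp
    wMirror[ovr] <- ramp
  }
  norm <- wDirect + wMirror
  norm[norm == 0] <- 1
  nr <- dim(a)[1L]
  out <- array(0, dim = c(nr, Wout, half))
  for (k in seq_len(half)) {
    direct <- matrix(a[, , k], nr, W)
    opp <- matrix(a[, , k + half], nr, W)
    dPart <- cbind(direct, matrix(0, nr, Wout - W))
    mPart <- t(apply(opp, 1L, function(row) .linearSampleCpp(row, sMirror)))
    out[, , k] <- (sweep(dPart, 2L, wDirect, "*") +
                   sweep(mPart, 2L, wMirror, "*")) / rep(norm, each = nr)
  }
  list(frames = out, axisU = axisU)
}
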