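# Near-field propagation-based phase retrieval on flat-corrected
# projections: transport-of-intensity (single effective distance, optionally
# anisotropic x/y distances) and weak-object CTF inversion (one or several
# distances, per-frequency least squares with Tikhonov regularization).
#
# Frequency grids use the FFT layout (zero frequency at element 1); frames
# are symmetrically padded by half their size with edge replication before
# filtering and cropped afterwards, to keep the circular convolution from
# wrapping object structure around the frame edges.

#' Construct phase-retrieval parameters
#'
#' @param method \code{"tie"} or \code{"ctf"}.
#' @param wavelength wavelength, m (give this or \code{energyKeV}).
#' @param energyKeV photon energy in keV, converted to wavelength.
#' @param distances propagation distance(s), m. TIE: scalar or (x, y) pair;
#'   CTF: K >= 1 distances.
#' @param delta,beta refractive index decrement / absorption index.
#' @param alpha Tikhonov regularization (>= 0). For TIE, when \code{delta}
#'   or \code{beta} is missing, the kernel uses \code{1/alpha} in place of
#'   \code{delta/beta}.
#' @param pixelSize effective detector pixel size, m.
#' @param output \code{"phase"} or \code{"thickness"}.
#' @return A [PhaseParams-class].
#' @export
phaseParams <- function(method = c("tie", "ctf"), wavelength = NULL,
                        energyKeV = NULL, distances, delta = numeric(),
                        beta = numeric(), alpha = 0, pixelSize,
                        output = c("phase", "thickness")) {
  method <- match.arg(method)
  output <- match.arg(output)
  if (is.null(wavelength)) {
    if (is.null(energyKeV)) stop("give wavelength or energyKeV")
    # lambda[m] = h*c / E; h*c = 1.23984198e-9 keV m
    wavelength <- 1.23984198e-9 / energyKeV
  }
  new("PhaseParams", method = method, wavelength = wavelength,
      distances = as.numeric(distances), delta = as.numeric(delta),
      beta = as.numeric(beta), alpha = alpha, pixelSize = pixelSize,
      output = output)
}

# squared angular spatial frequencies kx^2, ky^2 (rad^2/m^2) on the FFT grid
# of an nr x nc frame with pixel size dx; returns matrices of dim (nr, nc)
angularFreqGrids <- function(nr, nc, dx) {
  fy <- fftFreq(nr) / dx * 2 * pi
  fx <- fftFreq(nc) / dx * 2 * pi
  list(kx2 = matrix(fx^2, nr, nc, byrow = TRUE),
       ky2 = matrix(fy^2, nr, nc))
}

# FFT-layout frequencies in cycles per sample: 0, 1/n, ..., mirrored negative
fftFreq <- function(n) {
  k <- 0:(n - 1L)
  k[k > n / 2] <- k[k > n / 2] - n
  k / n
}

padHalf <- function(m) {
  pr <- floor(nrow(m) / 2)
  pc <- floor(ncol(m) / 2)
  ri <- c(rep(1L, pr), seq_len(nrow(m)), rep(nrow(m), pr))
  ci <- c(rep(1L, pc), seq_len(ncol(m)), rep(ncol(m), pc))
  list(m = m[ri, ci, drop = FALSE], pr = pr, pc = pc,
       nr = nrow(m), nc = ncol(m))
}

cropPad <- function(p, m) {
  m[p$pr + seq_len(p$nr), p$pc + seq_len(p$nc), drop = FALSE]
}

#' Transport-of-intensity phase retrieval
#'
#' Single-material (homogeneous) near-field retrieval: each frame is divided
#' in Fourier space by the low-pass kernel
#' \code{1 + (lambda/(4*pi)) * (delta/beta) * (dx_dist * kx^2 + dy_dist * ky^2)},
#' then \code{output = "thickness"} converts to projected thickness
#' \code{-log(.)/mu} in meters (\code{mu = 4*pi*beta/lambda}), and
#' \code{output = "phase"} additionally scales by \code{-2*pi*delta/lambda}
#' so that a parallel-beam FBP of the result yields the unitless per-voxel
#' phase shift \code{-2*pi*dx*delta/lambda}.
#'
#' @param frames flat-corrected transmission frame(s) (matrix, 3D array or
#'   [ProjectionStack-class]); all values must be > 0.
#' @param params a [PhaseParams-class] with \code{method = "tie"}.
#' @return Same shape as the input.
#' @export
tieRetrieve <- function(frames, params) {
  stopifnot(is(params, "PhaseParams"), params@method == "tie")
  lam <- params@wavelength
  d <- params@distances
  dX <- d[1L]
  dY <- if (length(d) == 2L) d[2L] else d[1L]
  ratio <- if (length(params@delta) && length(params@beta)) {
    params@delta / params@beta
  } else {
    if (params@alpha <= 0)
      stop("give delta and beta, or a regularization alpha > 0")
    1 / params@alpha
  }
  one <- function(m) {
    if (any(m <= 0))
      stop("non-positive transmission values: repair frames upstream")
    p <- padHalf(m)
    k <- angularFreqGrids(nrow(p$m), ncol(p$m), params@pixelSize)
    kern <- 1 + (lam / (4 * pi)) * ratio * (dX * k$kx2 + dY * k$ky2)
    filt <- Re(fft(fft(p$m) / kern, inverse = TRUE)) / length(p$m)
    out <- cropPad(p, filt)
    if (params@output == "thickness" || length(params@beta)) {
      mu <- 4 * pi * params@beta / lam
      thick <- -log(pmax(out, .Machine$double.xmin)) / mu
      if (params@output == "thickness") thick
      else -2 * pi * params@delta / lam * thick
    } else {
      # no material given: return the filtered log-transmission
      -log(pmax(out, .Machine$double.xmin))
    }
  }
  applyFrames(frames, one)
}

#' Weak-object CTF phase retrieval
#'
#' Pure-phase weak-object inversion. The forward model for the intensity
#' contrast at distance d is \code{C_d(k) = 2*sin(lambda*d*|k|^2/(4*pi)) *
#' phi(k)}; the inverse is the per-frequency Tikhonov least squares over the
#' K distances: \code{phi(k) = sum_d s_d C_d(k) / (sum_d s_d^2 + alpha)}
#' with \code{s_d = 2*sin(lambda*d*|k|^2/(4*pi))}. The DC value is set by
#' the regularization (it is zero for \code{alpha > 0}).
#'
#' @param frames one frame per distance: a matrix (K = 1), 3D array or list
#'   of matrices (co-registered, one per distance).
#' @param params a [PhaseParams-class] with \code{method = "ctf"};
#'   \code{distances} must match the number of frames.
#' @return Retrieved phase map (matrix).
#' @export
ctfRetrieve <- function(frames, params) {
  stopifnot(is(params, "PhaseParams"), params@method == "ctf")
  if (is.matrix(frames)) frames <- list(frames)
  if (is(frames, "ProjectionStack")) frames <- frames@frames
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3L]), function(k) frames[, , k])
  K <- length(frames)
  if (K != length(params@distances))
    stop("number of frames must match number of distances")
  lam <- params@wavelength
  pads <- lapply(frames, padHalf)
  k <- angularFreqGrids(nrow(pads[[1L]]$m), ncol(pads[[1L]]$m),
                        params@pixelSize)
  k2 <- k$kx2 + k$ky2
  num <- 0
  den <- 0
  for (j in seq_len(K)) {
    s <- 2 * sin(lam * params@distances[j] * k2 / (4 * pi))
    contrast <- pads[[j]]$m - mean(pads[[j]]$m)
    num <- num + s * fft(contrast) / K
    den <- den + s^2 / K
  }
  # averaging (not summing) over distances keeps alpha comparable across K
  # and makes K identical distances reduce exactly to the K = 1 result
  if (params@alpha <= 0 && any(abs(den) < 1e-12))
    stop("all CTF kernels vanish at some frequency; set alpha > 0")
  phiHat <- num / (den + params@alpha)
  phi <- Re(fft(phiHat, inverse = TRUE)) / length(phiHat)
  cropPad(pads[[1L]], phi)
}
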