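# Narrow ring artifacts come from detector columns whose response is wrong
# by a roughly constant factor: in a sinogram they are vertical stripes. A
# signal that is constant along the angle axis has all its energy on the
# zero-angular-frequency row of the 2D Fourier transform, so suppressing a
# narrow Gaussian notch of angular frequencies (away from the detector-
# frequency DC column, which carries the per-angle mean) removes stripes
# while leaving structure that genuinely moves with angle untouched.

#' Suppress near-vertical sinogram stripes in the Fourier domain
#'
#' The 2D FFT of the sinogram is multiplied by
#' \code{1 - exp(-ja^2 / (2*sigma^2))}, where \code{ja} is the angular
#' frequency index, for every detector-frequency column except DC and
#' restricted to detector frequencies above \code{1/maxWidthPx} (so only
#' stripes up to about \code{maxWidthPx} wide are affected). The overall DC
#' coefficient and the detector-frequency-zero column are preserved, which
#' keeps the sinogram mean; the real part of the inverse transform is
#' returned.
#'
#' @param sino a [Sinogram-class] or matrix \code{[angle, column]} with at
#'   least 8 angles.
#' @param sigma Gaussian notch width in angular-frequency bins (> 0).
#' @param maxWidthPx largest stripe width affected, px (default all widths).
#' @return Same type as the input.
#' @export
suppressStripesFourier <- function(sino, sigma = 2, maxWidthPx = Inf) {
  if (sigma <= 0) stop("sigma must be > 0")
  m <- if (is(sino, "Sinogram")) sino@values else sino
  if (nrow(m) < 8L) stop("need at least 8 angles")
  na <- nrow(m); nd <- ncol(m)
  ja <- pmin(0:(na - 1L), na - (0:(na - 1L)))       # angular frequency index
  jd <- pmin(0:(nd - 1L), nd - (0:(nd - 1L)))       # detector frequency index
  nuD <- jd / nd                                    # cycles per pixel
  atten <- 1 - exp(-ja^2 / (2 * sigma^2))
  A <- matrix(atten, na, nd)
  keep <- jd == 0L | nuD < 1 / maxWidthPx
  A[, keep] <- 1
  out <- Re(fft(fft(m) * A, inverse = TRUE)) / length(m)
  if (is(sino, "Sinogram")) sinogram(out, sino@angles, sino@axisU) else out
}
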