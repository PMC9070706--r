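# Non-local means denoising. Two implementations with identical output: a
# reference one looping over pixels (compiled), and a fast one that, for
# each search-window shift, computes all patch distances at once via
# cumulative sums (integral images) of the shifted squared-difference image.

#' Construct NLM parameters
#'
#' @param searchRadius search window half-size, px.
#' @param patchRadius patch half-size, px.
#' @param h filtering strength, intensity units.
#' @param sigmaNoise noise standard deviation, intensity units.
#' @param fast use the cumulative-sum variant.
#' @return An [NlmParams-class].
#' @export
nlmParams <- function(searchRadius = 5L, patchRadius = 2L, h, sigmaNoise = 0,
                      fast = TRUE) {
  new("NlmParams", searchRadius = as.integer(searchRadius),
      patchRadius = as.integer(patchRadius), h = h, sigmaNoise = sigmaNoise,
      fast = fast)
}

#' Non-local means denoising of a frame or slice
#'
#' Each pixel is replaced by the weight-normalized average of the pixels in
#' its search window; the weight of a neighbor is
#' \code{exp(-max(D2 - 2*sigmaNoise^2, 0) / h^2)}, where \code{D2} is the
#' mean squared difference of the two patches centered on the pixels. The
#' center pixel itself gets the maximum neighbor weight. Borders are
#' reflect-padded. The fast variant is numerically equivalent to the
#' reference one.
#'
#' @param frame image matrix (or 3D array / [ProjectionStack-class]; frames
#'   denoised independently).
#' @param params an [NlmParams-class].
#' @return Same shape as the input. Values are convex combinations of input
#'   values inside the search window.
#' @export
nlmDenoise <- function(frame, params) {
  stopifnot(is(params, "NlmParams"))
  s <- params@searchRadius
  p <- params@patchRadius
  if (s == 0L) return(frame)
  one <- function(m) {
    padded <- reflectPad(m, s + p)
    if (params@fast) {
      nlmFast(padded, s, p, params@h, params@sigmaNoise)
    } else {
      .nlmNaiveCpp(padded, s, p, params@h, params@sigmaNoise)
    }
  }
  applyFrames(frame, one)
}

# Box sum of every (2p+1)^2 window, via an integral image with a zero
# border; input (n x m) -> output (n-2p x m-2p), window fully inside.
boxSum <- function(m, p) {
  w <- 2L * p + 1L
  S <- rbind(0, apply(m, 2L, cumsum))
  S <- cbind(0, t(apply(S, 1L, cumsum)))
  nr <- nrow(m) - w + 1L
  nc <- ncol(m) - w + 1L
  ri <- seq_len(nr)
  ci <- seq_len(nc)
  S[ri + w, ci + w, drop = FALSE] - S[ri, ci + w, drop = FALSE] -
    S[ri + w, ci, drop = FALSE] + S[ri, ci, drop = FALSE]
}

nlmFast <- function(padded, s, p, h, sigma) {
  off <- s + p
  nr <- nrow(padded) - 2L * off
  nc <- ncol(padded) - 2L * off
  npatch <- (2 * p + 1)^2
  h2 <- h * h
  s2 <- 2 * sigma * sigma
  wsum <- matrix(0, nr, nc)
  vsum <- matrix(0, nr, nc)
  wmax <- matrix(0, nr, nc)
  centerIdxR <- off + seq_len(nr)
  centerIdxC <- off + seq_len(nc)
  center <- padded[centerIdxR, centerIdxC, drop = FALSE]
  for (dj in -s:s) {
    for (di in -s:s) {
      if (di == 0L && dj == 0L) next
      shifted <- padded[centerIdxR + di, centerIdxC + dj, drop = FALSE]
      # squared differences on the patch-extended region, then box sums
      extR <- (off - p) + seq_len(nr + 2L * p)
      extC <- (off - p) + seq_len(nc + 2L * p)
      d2 <- (padded[extR, extC, drop = FALSE] -
             padded[extR + di, extC + dj, drop = FALSE])^2
      D2 <- boxSum(d2, p) / npatch
      w <- exp(-pmax(D2 - s2, 0) / h2)
      wmax <- pmax(wmax, w)
      wsum <- wsum + w
      vsum <- vsum + w * shifted
    }
  }
  wmax[wmax <= 0] <- 1
  (vsum + wmax * center) / (wsum + wmax)
}
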