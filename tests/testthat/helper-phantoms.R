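# Shared fixtures and independent oracles used across the suite. Everything
# is generated in code; no data files.

# forward-project a phantom into a [v, u, projection] stack
projectScan <- function(ph, geom, shape) {
  a <- array(0, dim = c(shape, geom@nProj))
  for (i in seq_len(geom@nProj)) a[, , i] <- analyticProject(ph, geom, i, shape)
  a
}

# off-center disk (tall cylinder) used by many reconstruction tests
diskPhantom <- function(cx = 0.3, cy = 0, r = 2, mu = 0.5, extent = 6) {
  phantomSpec(data.frame(shape = "cylinder", cx = cx, cy = cy, cz = 0,
                         ax = r, ay = r, az = extent * 0.8, mu = mu),
              extent = extent)
}

# single-row sinogram of a phantom (detector = one row)
phantomSinogram <- function(ph, geom, W) {
  L <- projectScan(ph, geom, c(1L, W))
  sinogram(t(matrix(L, W, geom@nProj)), geom@angles, geom@axisU)
}

fftfreqR <- function(n) {
  k <- 0:(n - 1L)
  k[k > n / 2] <- k[k > n / 2] - n
  k / n
}

# independent per-pixel median filter (reference for removeOutliers);
# reflect-padded neighborhood, plain loops
naiveRemoveOutliers <- function(m, r, thr, direction = "both") {
  nr <- nrow(m); nc <- ncol(m)
  refl <- function(i, n) {
    i <- abs(i - 1L) + 1L
    i[i > n] <- 2L * n - i[i > n]
    i
  }
  out <- m
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      nb <- m[refl(i + (-r:r), nr), refl(j + (-r:r), nc)]
      med <- median(nb)
      dev <- m[i, j] - med
      rep <- switch(direction,
                    bright = dev > thr,
                    dark = -dev > thr,
                    both = abs(dev) > thr)
      if (rep) out[i, j] <- med
    }
  }
  out
}

# independent BFS flood fill (reference for findLargeSpots)
floodFillSpots <- function(m, spotThr, growThr) {
  med <- median(m)
  dev <- abs(m - med)
  cand <- dev > growThr
  seeds <- which(dev > spotThr)
  nr <- nrow(m); nc <- ncol(m)
  mask <- matrix(FALSE, nr, nc)
  queue <- seeds
  mask[queue] <- TRUE
  while (length(queue)) {
    idx <- queue[1L]
    queue <- queue[-1L]
    i <- (idx - 1L) %% nr + 1L
    j <- (idx - 1L) %/% nr + 1L
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii < 1L || ii > nr || jj < 1L || jj > nc) next
      k <- (jj - 1L) * nr + ii
      if (cand[k] && !mask[k]) {
        mask[k] <- TRUE
        queue <- c(queue, k)
      }
    }
  }
  mask
}

# weak-object CTF forward model with the same pad/crop layout as the
# retrieval (oracle for the round-trip test)
ctfForward <- function(phi, d, lambda, px) {
  pr <- nrow(phi) %/% 2L; pc <- ncol(phi) %/% 2L
  ri <- c(rep(1L, pr), seq_len(nrow(phi)), rep(nrow(phi), pr))
  ci <- c(rep(1L, pc), seq_len(ncol(phi)), rep(ncol(phi), pc))
  P <- phi[ri, ci]
  k2 <- outer((fftfreqR(nrow(P)) / px * 2 * pi)^2,
              (fftfreqR(ncol(P)) / px * 2 * pi)^2, "+")
  s <- 2 * sin(lambda * d * k2 / (4 * pi))
  C <- Re(fft(s * fft(P), inverse = TRUE)) / length(P)
  1 + C[pr + seq_len(nrow(phi)), pc + seq_len(ncol(phi))]
}

# TIE forward model (low-pass multiplication) on a 1-row frame
tieForwardRow <- function(I0row, d, lambda, deltaBeta, px) {
  n <- length(I0row)
  pc <- n %/% 2L
  row <- I0row[c(rep(1L, pc), seq_len(n), rep(n, pc))]
  kern <- 1 + (lambda / (4 * pi)) * deltaBeta * d *
    (fftfreqR(length(row)) / px * 2 * pi)^2
  filt <- Re(fft(fft(row) * kern, inverse = TRUE)) / length(row)
  filt[pc + seq_len(n)]
}

# write a synthetic CT dataset tree (darks/flats/tomo TIFF sequences)
writeCtDataset <- function(root, sim) {
  writeStack(sim$darks, file.path(root, "darks"), "tiff_sequence")
  writeStack(sim$flats, file.path(root, "flats"), "tiff_sequence")
  writeStack(sim$tomo, file.path(root, "tomo"), "tiff_sequence")
  invisible(root)
}

expect_rel_rms <- function(actual, expected, tol) {
  rel <- sqrt(mean((actual - expected)^2)) / sqrt(mean(expected^2))
  expect_lt(rel, tol)
}
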