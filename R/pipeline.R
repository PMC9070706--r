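# Headless batch driver: discovers CT data sets under an input tree, skips
# the ones already reconstructed, builds an executable per-dataset stage
# plan in the canonical order (stitch, outlier removal, spot inpainting,
# flat-field + absorptivity, phase retrieval, ring filtering, axis
# estimation, reconstruction, crop/rotate, quantize, NLM, orthogonal
# slices), and runs it with per-dataset error isolation and a re-runnable
# parameter dump.

stageOrder <- c("stitch", "remove_outliers", "inpaint_spots", "flat_field",
                "phase_retrieval", "ring_removal", "estimate_axis",
                "reconstruct", "crop_rotate", "quantize", "nlm",
                "ortho_slices")

#' Assemble a pipeline configuration
#'
#' Toggles and parameters for the twelve workflow categories. Only
#' \code{flatField} and \code{reconstruct} are on by default; stages always
#' execute in the canonical order regardless of the order given here.
#'
#' @param stitch \code{NULL} or \code{list(axisU =, flip = FALSE)} for
#'   half-acquisition data.
#' @param removeOutliers \code{NULL} or \code{list(radius =, threshold =,
#'   direction =)}.
#' @param inpaintSpots \code{NULL} or \code{list(spotThreshold =,
#'   growThreshold =)}.
#' @param flatField \code{list(eps =)} or \code{NULL} to skip normalization.
#' @param phase \code{NULL} or a [PhaseParams-class].
#' @param rings \code{NULL} or \code{list(sigma =, maxWidthPx =)}.
#' @param axis \code{"estimate"} (pair correlation), \code{"sweep"}
#'   (metric sweep) or a numeric axis position in px.
#' @param reconstruct \code{list(nSlices =, zStep =, gridSize = NULL)}:
#'   slice count around the vertical center, their z spacing (rows), and
#'   optional output grid size (defaults to the detector width).
#' @param angleSpan total angular range of the scan, radians.
#' @param cropRotate \code{NULL} or \code{list(crop = c(y0, y1, x0, x1),
#'   rotate = k)} (k quarter-turns).
#' @param quantize \code{NULL} or \code{list(low =, high =, bits =)}.
#' @param nlm \code{NULL} or an [NlmParams-class] applied to slices.
#' @param orthoSlices write mid-plane orthogonal slices.
#' @return A named list (class \code{"pipelineConfig"}).
#' @export
pipelineConfig <- function(stitch = NULL, removeOutliers = NULL,
                           inpaintSpots = NULL, flatField = list(eps = 1e-6),
                           phase = NULL, rings = NULL, axis = "estimate",
                           reconstruct = list(nSlices = 1L, zStep = 1L,
                                              gridSize = NULL),
                           angleSpan = pi, cropRotate = NULL, quantize = NULL,
                           nlm = NULL, orthoSlices = FALSE) {
  cfg <- list(stitch = stitch, removeOutliers = removeOutliers,
              inpaintSpots = inpaintSpots, flatField = flatField,
              phase = phase, rings = rings, axis = axis,
              reconstruct = reconstruct, angleSpan = angleSpan,
              cropRotate = cropRotate, quantize = quantize, nlm = nlm,
              orthoSlices = orthoSlices)
  class(cfg) <- "pipelineConfig"
  cfg
}

configStages <- function(config) {
  st <- c(
    if (!is.null(config$stitch)) "stitch",
    if (!is.null(config$removeOutliers)) "remove_outliers",
    if (!is.null(config$inpaintSpots)) "inpaint_spots",
    if (!is.null(config$flatField)) "flat_field",
    if (!is.null(config$phase)) "phase_retrieval",
    if (!is.null(config$rings)) "ring_removal",
    if (is.character(config$axis)) "estimate_axis",
    "reconstruct",
    if (!is.null(config$cropRotate)) "crop_rotate",
    if (!is.null(config$quantize)) "quantize",
    if (!is.null(config$nlm)) "nlm",
    if (isTRUE(config$orthoSlices)) "ortho_slices")
  stageOrder[stageOrder %in% st]
}

#' Plan a batch reconstruction
#'
#' Discovers all valid CT directories under \code{inputRoot}, preserves
#' their relative paths, skips data sets whose names already exist under
#' \code{outputRoot}, and emits one executable stage list per remaining
#' data set. The plan can be printed without executing anything.
#'
#' @param inputRoot input directory tree.
#' @param outputRoot output directory tree.
#' @param config a [pipelineConfig()].
#' @return List of plan entries (\code{layout}, \code{relPath},
#'   \code{outputDir}, \code{stages}), class \code{"batchPlan"}.
#' @export
planBatch <- function(inputRoot, outputRoot, config = pipelineConfig()) {
  if (!dir.exists(inputRoot)) stop("missing input root: ", inputRoot)
  layouts <- discoverLayout(inputRoot)
  stages <- configStages(config)
  plan <- list()
  rootNorm <- normalizePath(inputRoot)
  for (lay in layouts) {
    rel <- sub("^/+", "", substring(lay@root, nchar(rootNorm) + 1L))
    if (rel == "") rel <- basename(rootNorm)
    outDir <- file.path(outputRoot, rel)
    if (dir.exists(outDir)) next   # already reconstructed
    plan[[length(plan) + 1L]] <- list(layout = lay, relPath = rel,
                                      outputDir = outDir, stages = stages)
  }
  attr(plan, "config") <- config
  class(plan) <- "batchPlan"
  plan
}

#' @export
print.batchPlan <- function(x, ...) {
  cat(sprintf("Batch plan: %d data set(s)\n", length(x)))
  for (e in x) {
    cat(sprintf("  %s -> %s\n    stages: %s\n", e$layout@root, e$outputDir,
                paste(e$stages, collapse = " ! ")))
  }
  invisible(x)
}

#' Execute a batch plan
#'
#' Stages run sequentially per data set; a failure in one data set is
#' recorded and does not abort the batch. Every completed data set gets its
#' slices written as float TIFFs plus a key=value parameter dump sufficient
#' to re-run the reconstruction.
#'
#' @param plan a [planBatch()] result.
#' @param config overrides the config stored on the plan.
#' @param quiet suppress per-stage messages.
#' @return Data frame with one row per data set (\code{relPath},
#'   \code{status}, \code{message}); attribute \code{"exitCode"} is 0 when
#'   everything succeeded, 1 otherwise.
#' @export
runPlan <- function(plan, config = NULL, quiet = FALSE) {
  if (is.null(config)) config <- attr(plan, "config")
  status <- character(length(plan))
  msg <- character(length(plan))
  rel <- character(length(plan))
  for (j in seq_along(plan)) {
    e <- plan[[j]]
    rel[j] <- e$relPath
    res <- tryCatch({
      runDataset(e, config, quiet = quiet)
      list(status = "ok", message = "")
    }, error = function(err) {
      list(status = "failed", message = conditionMessage(err))
    })
    status[j] <- res$status
    msg[j] <- res$message
    if (!quiet)
      message(sprintf("[%s] %s%s", res$status, e$relPath,
                      if (nzchar(res$message)) paste0(": ", res$message) else ""))
  }
  out <- data.frame(relPath = rel, status = status, message = msg,
                    stringsAsFactors = FALSE)
  attr(out, "exitCode") <- if (all(status == "ok")) 0L else 1L
  out
}

runDataset <- function(entry, config, quiet = FALSE) {
  lay <- entry$layout
  note <- function(...) if (!quiet) message("  ", sprintf(...))
  darks <- frames(readStack(lay@darksDir, role = "darks"))
  flats <- frames(readStack(lay@flatsDir, role = "flats"))
  tomo <- frames(readStack(lay@tomoDir, role = "tomo"))
  params <- list()
  axisVal <- if (is.numeric(config$axis)) config$axis else NA_real_
  span <- config$angleSpan
  for (st in entry$stages) {
    note("stage %s", st)
    if (st == "stitch") {
      r <- stitchHalfAcquisition(tomo, config$stitch$axisU,
                                 flip = isTRUE(config$stitch$flip))
      tomo <- r$frames
      axisVal <- r$axisU
      span <- span / 2
      # references must be stitched consistently; for constant flats/darks
      # widening by replication is equivalent
      widen <- function(m) {
        dW <- dim(tomo)[2L] - ncol(m)
        if (dW > 0) cbind(m, m[, rev(seq_len(dW)), drop = FALSE]) else m
      }
      darks <- array(apply(darks, 3L, widen),
                     dim = c(dim(tomo)[1:2], dim(darks)[3L]))
      flats <- array(apply(flats, 3L, widen),
                     dim = c(dim(tomo)[1:2], dim(flats)[3L]))
      params$stitch_axis <- config$stitch$axisU
    } else if (st == "remove_outliers") {
      p <- config$removeOutliers
      tomo <- removeOutliers(tomo, p$radius, p$threshold,
                             p$direction %||% "both")
      flats <- removeOutliers(flats, p$radius, p$threshold,
                              p$direction %||% "both")
      params$outlier_radius <- p$radius
      params$outlier_threshold <- p$threshold
    } else if (st == "inpaint_spots") {
      p <- config$inpaintSpots
      ref <- averageFrames(flats, "median")
      mask <- findLargeSpots(ref, p$spotThreshold, p$growThreshold)
      for (k in seq_len(dim(tomo)[3L]))
        tomo[, , k] <- inpaintHorizontal(tomo[, , k], mask)
      for (k in seq_len(dim(flats)[3L]))
        flats[, , k] <- inpaintHorizontal(flats[, , k], mask)
      params$spot_threshold <- p$spotThreshold
      params$grow_threshold <- p$growThreshold
    } else if (st == "flat_field") {
      dark <- averageFrames(darks, "mean")
      flat <- averageFrames(flats, "mean")
      eps <- config$flatField$eps %||% 1e-6
      for (k in seq_len(dim(tomo)[3L]))
        tomo[, , k] <- flatFieldCorrect(tomo[, , k], dark, flat, eps = eps)
      if (is.null(config$phase)) tomo <- absorptivity(tomo)
      params$flat_eps <- eps
    } else if (st == "phase_retrieval") {
      tomo <- tieRetrieve(tomo, config$phase)
      params$phase_method <- config$phase@method
      params$phase_distances <- config$phase@distances
    } else if (st == "estimate_axis") {
      nAngles <- dim(tomo)[3L]
      angs <- seq(0, span, length.out = nAngles + 1L)[seq_len(nAngles)]
      axisVal <- if (identical(config$axis, "sweep")) {
        midRow <- (dim(tomo)[1L] + 1L) %/% 2L
        sino <- sinogram(t(tomo[midRow, , ]), angs)
        estimateAxis(sino, method = "sweep_metric")
      } else {
        estimateAxis(tomo, method = "pair_correlation", angles = angs)
      }
      params$estimated_axis <- axisVal
    } else if (st == "reconstruct") {
      if (is.na(axisVal)) axisVal <- (dim(tomo)[2L] - 1) / 2
      rc <- config$reconstruct
      nAngles <- dim(tomo)[3L]
      angs <- seq(0, span, length.out = nAngles + 1L)[seq_len(nAngles)]
      midRow <- (dim(tomo)[1L] - 1) / 2
      zs <- (seq_len(rc$nSlices) - (rc$nSlices + 1) / 2) * (rc$zStep %||% 1L)
      n <- rc$gridSize %||% dim(tomo)[2L]
      half <- (n - 1) / 2
      slices <- array(0, dim = c(n, n, length(zs)))
      for (si in seq_along(zs)) {
        row <- round(midRow + zs[si]) + 1L
        sino <- sinogram(t(tomo[row, , ]), angs, axisVal)
        slices[, , si] <- fbpParallel(sino, n = n)
      }
      volume <- slices
      params$axis <- axisVal
      params$n_slices <- rc$nSlices
      params$z_step <- rc$zStep %||% 1L
      params$grid_size <- n
      params$angle_span <- span
    } else if (st == "ring_removal") {
      p <- config$rings
      nAngles <- dim(tomo)[3L]
      for (r in seq_len(dim(tomo)[1L])) {
        s <- t(tomo[r, , ])
        tomo[r, , ] <- t(suppressStripesFourier(s, sigma = p$sigma %||% 2,
                                                maxWidthPx = p$maxWidthPx %||% Inf))
      }
      params$ring_sigma <- p$sigma %||% 2
    } else if (st == "crop_rotate") {
      p <- config$cropRotate
      if (!is.null(p$crop)) {
        cr <- p$crop
        volume <- volume[cr[1L]:cr[2L], cr[3L]:cr[4L], , drop = FALSE]
      }
      if (!is.null(p$rotate) && p$rotate %% 4L != 0L) {
        for (k in seq_len(dim(volume)[3L])) {
          m <- volume[, , k]
          for (q in seq_len(p$rotate %% 4L)) m <- t(m[nrow(m):1L, ])
          volume[, , k] <- m
        }
      }
    } else if (st == "quantize") {
      p <- config$quantize
      volume <- clipQuantize(volume, p$low, p$high, p$bits %||% 16L)
      params$quantize_low <- p$low
      params$quantize_high <- p$high
      params$quantize_bits <- p$bits %||% 16L
    } else if (st == "nlm") {
      for (k in seq_len(dim(volume)[3L]))
        volume[, , k] <- nlmDenoise(matrix(volume[, , k], dim(volume)[1L],
                                           dim(volume)[2L]), config$nlm)
      # NLM after quantization must stay on the integer grid for output
      if (!is.null(config$quantize)) volume <- round(volume)
      params$nlm_h <- config$nlm@h
    } else if (st == "ortho_slices") {
      orth <- orthogonalSlices(volume)
    }
  }
  dir.create(entry$outputDir, recursive = TRUE, showWarnings = FALSE)
  qz <- !is.null(config$quantize)
  writeStack(volume, file.path(entry$outputDir, "slices"),
             kind = "tiff_sequence", prefix = "slice",
             dtype = if (qz) sprintf("uint%d", config$quantize$bits %||% 16L)
                     else "float32")
  if (exists("orth", inherits = FALSE)) {
    for (nm in names(orth))
      writeStack(orth[[nm]],
                 file.path(entry$outputDir, sprintf("ortho_%s", nm)),
                 kind = "tiff_sequence", prefix = nm, dtype = "float32")
  }
  params$stages <- paste(entry$stages, collapse = "!")
  params$input <- entry$layout@root
  writeParameterDump(params, file.path(entry$outputDir, "parameters.txt"))
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
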