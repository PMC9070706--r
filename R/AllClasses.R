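#' Scan geometry for tomographic and laminographic acquisitions
#'
#' @description
#' \code{ScanGeometry} describes where every projection was taken: beam type
#' (parallel or cone), the rotation angle of each projection, where the
#' rotation axis projects onto the detector, the laminographic tilt and
#' in-plane roll of the axis, the orientation of the detector and of the
#' reconstructed grid, and the physical placement of source and detector.
#' Source and detector positions may be given per projection, which is what
#' makes helical trajectories and drift-compensated scans expressible without
#' touching the projection data.
#'
#' Coordinate conventions (documented, right-handed): at zero tilt the
#' rotation axis is +z, the beam travels along +y, detector columns (u) run
#' along +x and detector rows (v) along +z; the rotation angle is measured so
#' that a parallel-beam projection of a point (x, y, 0) lands at detector
#' column \code{axisU + x*cos(theta) + y*sin(theta)} (in effective-pixel
#' units). Orientation triples are intrinsic rotations applied about x, then
#' y, then z. The volume origin is the center of the reconstructed grid and
#' lies on the rotation axis; voxel and pixel coordinates refer to element
#' centers, 0-based.
#'
#' @slot beam \code{"parallel"} or \code{"cone"}.
#' @slot nProj number of projections.
#' @slot angles rotation angle per projection, radians.
#' @slot axisU,axisV detector-pixel coordinates (0-based, fractional) of the
#'   projection of the center of rotation.
#' @slot laminoTilt angle between the rotation axis and the detector-vertical
#'   axis, radians; 0 is plain tomography.
#' @slot axisRoll in-plane rotation of the axis, radians.
#' @slot detectorOrientation,volumeOrientation length-3 rotation triples
#'   (radians) about x, y, z (intrinsic, in that order).
#' @slot sourcePosition,detectorPosition n-by-3 (or 1-by-3) matrices, mm,
#'   relative to the volume center. Source is only used for cone beam.
#' @slot pixelPitch physical detector pixel size, micrometres.
#' @slot voxelSize reconstructed voxel edge, micrometres.
#'
#' @seealso [scanGeometry()] for the user constructor, [projectVoxel()].
#' @export
setClass("ScanGeometry", representation(
  beam = "character",
  nProj = "integer",
  angles = "numeric",
  axisU = "numeric",
  axisV = "numeric",
  laminoTilt = "numeric",
  axisRoll = "numeric",
  detectorOrientation = "numeric",
  sourcePosition = "matrix",
  detectorPosition = "matrix",
  volumeOrientation = "numeric",
  pixelPitch = "numeric",
  voxelSize = "numeric"
))

setValidity("ScanGeometry", function(object) {
  msg <- character()
  if (!object@beam %in% c("parallel", "cone"))
    msg <- c(msg, "beam must be 'parallel' or 'cone'")
  n <- object@nProj
  if (length(object@angles) != n)
    msg <- c(msg, "length(angles) must equal nProj")
  if (!all(is.finite(object@angles)))
    msg <- c(msg, "angles must be finite")
  for (nm in c("sourcePosition", "detectorPosition")) {
    m <- slot(object, nm)
    if (ncol(m) != 3L || !(nrow(m) %in% c(1L, n)))
      msg <- c(msg, sprintf("%s must be 1x3 or nProj x 3", nm))
  }
  for (nm in c("detectorOrientation", "volumeOrientation")) {
    if (length(slot(object, nm)) != 3L)
      msg <- c(msg, sprintf("%s must have length 3", nm))
  }
  if (!(length(object@pixelPitch) == 1L && is.finite(object@pixelPitch) &&
        object@pixelPitch > 0))
    msg <- c(msg, "pixelPitch must be a positive scalar")
  if (!(length(object@voxelSize) == 1L && is.finite(object@voxelSize) &&
        object@voxelSize > 0))
    msg <- c(msg, "voxelSize must be a positive scalar")
  if (object@beam == "cone") {
    # source-detector separation along the beam axis must be positive
    Rdet <- rotationXYZ(object@detectorOrientation)
    nrm <- Rdet[, 2L]
    for (i in seq_len(n)) {
      s <- positionAt(object@sourcePosition, i)
      d <- positionAt(object@detectorPosition, i)
      if (sum((d - s) * nrm) <= 0) {
        msg <- c(msg, "cone beam requires source-detector separation > 0 along the beam axis for every projection")
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Ordered stack of 2D detector frames
#'
#' Frames are stored as a 3D array \code{[row, column, frame]} (detector row
#' v down the first dimension, column u along the second). The \code{role}
#' records whether the frames are darks, flats or sample projections.
#'
#' @slot frames numeric 3D array \code{[v, u, frame]}.
#' @slot role one of \code{"tomo"}, \code{"flats"}, \code{"darks"}.
#' @export
setClass("ProjectionStack", representation(
  frames = "array",
  role = "character"
))

setValidity("ProjectionStack", function(object) {
  msg <- character()
  if (length(dim(object@frames)) != 3L)
    msg <- c(msg, "frames must be a 3D array [v, u, frame]")
  if (!object@role %in% c("tomo", "flats", "darks"))
    msg <- c(msg, "role must be 'tomo', 'flats' or 'darks'")
  if (length(msg)) msg else TRUE
})

#' Sinogram: one detector row across all projection angles
#'
#' Row i of \code{values} is the chosen detector row of the projection taken
#' at \code{angles[i]}; columns are detector columns. Vertical stripes in
#' this view become rings after reconstruction.
#'
#' @slot values numeric matrix \code{[angle, column]}.
#' @slot angles rotation angles, radians.
#' @slot axisU rotation-axis column (0-based, fractional).
#' @export
setClass("Sinogram", representation(
  values = "matrix",
  angles = "numeric",
  axisU = "numeric"
))

setValidity("Sinogram", function(object) {
  if (nrow(object@values) != length(object@angles))
    return("number of sinogram rows must match the number of angles")
  TRUE
})

#' Output grid for volume reconstruction
#'
#' Each range is \code{c(start, stop, step)} in voxel units, centered at the
#' volume origin; grid points are \code{seq(start, stop, by = step)}
#' (inclusive of stop when it falls on the grid).
#'
#' @slot xRange,yRange,zRange numeric length-3 \code{(start, stop, step)}.
#' @export
setClass("VolumeRegion", representation(
  xRange = "numeric", yRange = "numeric", zRange = "numeric"
))

setValidity("VolumeRegion", function(object) {
  for (nm in c("xRange", "yRange", "zRange")) {
    r <- slot(object, nm)
    if (length(r) != 3L || !all(is.finite(r)))
      return(sprintf("%s must be finite (start, stop, step)", nm))
    if (r[3L] <= 0) return(sprintf("%s: step must be > 0", nm))
    if (r[2L] < r[1L]) return(sprintf("%s: stop must be >= start", nm))
  }
  TRUE
})

#' Parameter sweep replacing the z axis of a reconstruction
#'
#' One horizontal slice at height \code{fixedZ} is reconstructed for every
#' value of the chosen geometry parameter, so the third output dimension
#' walks the parameter instead of z. A slice metric (e.g. the standard
#' deviation) applied to the sweep locates the best parameter value.
#'
#' @slot parameterName one of \code{"axis_u"}, \code{"lamino_tilt"},
#'   \code{"axis_roll"}, \code{"angle_offset"}.
#' @slot values strictly monotone parameter values.
#' @slot fixedZ slice height, voxels.
#' @export
setClass("SweepSpec", representation(
  parameterName = "character", values = "numeric", fixedZ = "numeric"
))

setValidity("SweepSpec", function(object) {
  if (!object@parameterName %in%
      c("axis_u", "lamino_tilt", "axis_roll", "angle_offset"))
    return("unsupported sweep parameter")
  v <- object@values
  if (length(v) < 1L) return("values must be non-empty")
  if (length(v) > 1L) {
    d <- diff(v)
    if (!(all(d > 0) || all(d < 0))) return("values must be strictly monotone")
  }
  TRUE
})

#' Analytic phantom: ellipsoids and cylinders with known attenuation
#'
#' @slot primitives data.frame with columns \code{shape} ("ellipsoid" or
#'   "cylinder", the cylinder axis being z), \code{cx, cy, cz} (center, mm),
#'   \code{ax, ay, az} (semi-axes, mm; for a cylinder \code{az} is the half
#'   height), \code{mu} (linear attenuation, 1/mm) and optionally
#'   \code{delta} (refractive index decrement) for phase simulations.
#' @slot extent half-width of the phantom support, mm.
#' @export
setClass("PhantomSpec", representation(
  primitives = "data.frame", extent = "numeric"
))

setValidity("PhantomSpec", function(object) {
  p <- object@primitives
  need <- c("shape", "cx", "cy", "cz", "ax", "ay", "az", "mu")
  if (!all(need %in% names(p)))
    return(paste("primitives needs columns:", paste(need, collapse = ", ")))
  if (any(!p$shape %in% c("ellipsoid", "cylinder")))
    return("shape must be 'ellipsoid' or 'cylinder'")
  if (any(p$mu < 0)) return("mu must be >= 0")
  reach <- pmax(abs(p$cx) + p$ax, abs(p$cy) + p$ay, abs(p$cz) + p$az)
  if (any(reach > object@extent + 1e-9))
    return("primitives must lie within the phantom extent")
  TRUE
})

#' Parameters for propagation-based phase retrieval
#'
#' @slot method \code{"tie"} (transport-of-intensity, single effective
#'   distance or an anisotropic x/y pair) or \code{"ctf"} (weak-object
#'   contrast transfer function, one or several distances).
#' @slot wavelength X-ray wavelength, m.
#' @slot distances propagation distance(s), m. For TIE a scalar or an
#'   \code{(x, y)} pair; for CTF a vector of K distances.
#' @slot delta,beta refractive index decrement and absorption index.
#' @slot alpha Tikhonov regularization weight (>= 0); for TIE it can replace
#'   \code{delta/beta} when those are unknown.
#' @slot pixelSize effective detector pixel size, m.
#' @slot output \code{"phase"} or \code{"thickness"} (TIE only).
#' @export
setClass("PhaseParams", representation(
  method = "character", wavelength = "numeric", distances = "numeric",
  delta = "numeric", beta = "numeric", alpha = "numeric",
  pixelSize = "numeric", output = "character"
))

setValidity("PhaseParams", function(object) {
  if (!object@method %in% c("tie", "ctf")) return("method must be 'tie' or 'ctf'")
  if (!(object@wavelength > 0)) return("wavelength must be > 0")
  if (any(object@distances < 0)) return("distances must be >= 0")
  if (object@method == "tie" && !length(object@distances) %in% c(1L, 2L))
    return("tie takes one distance or an (x, y) pair")
  if (!(object@pixelSize > 0)) return("pixelSize must be > 0")
  if (object@alpha < 0) return("alpha must be >= 0")
  if (!object@output %in% c("phase", "thickness"))
    return("output must be 'phase' or 'thickness'")
  if (object@output == "thickness" &&
      (!length(object@delta) || !length(object@beta)))
    return("output='thickness' requires delta and beta")
  TRUE
})

#' Parameters for non-local means denoising
#'
#' @slot searchRadius half-size of the search window, px.
#' @slot patchRadius half-size of the comparison patch, px.
#' @slot h filtering strength, intensity units.
#' @slot sigmaNoise noise standard deviation, intensity units; patch
#'   distances are reduced by \code{2*sigmaNoise^2} before weighting.
#' @slot fast use the cumulative-sum implementation (identical results).
#' @export
setClass("NlmParams", representation(
  searchRadius = "integer", patchRadius = "integer",
  h = "numeric", sigmaNoise = "numeric", fast = "logical"
))

setValidity("NlmParams", function(object) {
  if (object@searchRadius < 0L || object@patchRadius < 0L)
    return("radii must be >= 0")
  if (!(object@h > 0)) return("h must be > 0")
  if (object@sigmaNoise < 0) return("sigmaNoise must be >= 0")
  TRUE
})

#' Location of one CT data set on disk
#'
#' A valid CT directory holds the darks/flats/tomo triple as subdirectories
#' of TIFF sequences (or single multipage TIFF files).
#'
#' @slot root dataset directory.
#' @slot darksDir,flatsDir,tomoDir paths to the three roles.
#' @slot kind \code{"tiff_sequence"}, \code{"multipage_tiff"} or \code{"raw"}.
#' @export
setClass("DatasetLayout", representation(
  root = "character", darksDir = "character", flatsDir = "character",
  tomoDir = "character", kind = "character"
))

# ---- show methods -----------------------------------------------------------

setMethod("show", "ScanGeometry", function(object) {
  cat(sprintf("ScanGeometry: %s beam, %d projections\n",
              object@beam, object@nProj))
  cat(sprintf("  angles: %.4f .. %.4f rad, axis (u, v) = (%.2f, %.2f) px\n",
              min(object@angles), max(object@angles),
              object@axisU, object@axisV))
  cat(sprintf("  lamino tilt %.4f rad, axis roll %.4f rad\n",
              object@laminoTilt, object@axisRoll))
  cat(sprintf("  pixel pitch %.3f um, voxel size %.3f um\n",
              object@pixelPitch, object@voxelSize))
  if (nrow(object@sourcePosition) > 1L || nrow(object@detectorPosition) > 1L)
    cat("  per-projection source/detector positions\n")
  invisible(NULL)
})

setMethod("show", "ProjectionStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("ProjectionStack (%s): %d frames of %d x %d px\n",
              object@role, d[3L], d[1L], d[2L]))
  invisible(NULL)
})

setMethod("show", "Sinogram", function(object) {
  cat(sprintf("Sinogram: %d angles x %d columns, axis at %.2f px\n",
              nrow(object@values), ncol(object@values), object@axisU))
  invisible(NULL)
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d primitives within +/- %.2f mm\n",
              nrow(object@primitives), object@extent))
  invisible(NULL)
})

setMethod("show", "DatasetLayout", function(object) {
  cat(sprintf("DatasetLayout (%s): %s\n", object@kind, object@root))
  invisible(NULL)
})
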