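# Reading and writing projection stacks: TIFF sequences, multipage TIFF and
# headerless little-endian raw. Reading goes through tiff::readTIFF, which
# handles integer and IEEE-float sample formats. Writing of float data uses a
# minimal uncompressed 32-bit-float grayscale TIFF writer (tiff::writeTIFF
# only stores [0, 1]-scaled integer samples); integer output (after
# clipQuantize) goes through tiff::writeTIFF.

# ---- minimal float32 TIFF writer -------------------------------------------

# Little-endian baseline TIFF: header, then per page [IFD][strip data], one
# uncompressed strip per page, SampleFormat = IEEE float. tiff::readTIFF
# reads these back exactly.
writeFloatTiff <- function(frames, path) {
  # Assemble in memory offsets first: header(8) then per page [IFD][data].
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  tag <- function(id, type, count, value) {
    w2(id); w2(type); w4(count)
    if (type == 3L) { w2(value); w2(0L) } else w4(value)
  }
  nTags <- 9L
  ifdSize <- 2L + nTags * 12L + 4L
  npage <- length(frames)
  ifdOffsets <- integer(npage)
  pos <- 8L
  for (k in seq_len(npage)) {
    ifdOffsets[k] <- pos
    pos <- pos + ifdSize + 4L * nrow(frames[[k]]) * ncol(frames[[k]])
  }
  writeBin(charToRaw("II"), con); w2(42L); w4(ifdOffsets[1L])
  for (k in seq_len(npage)) {
    fr <- frames[[k]]
    h <- nrow(fr); wd <- ncol(fr)
    stripOffset <- ifdOffsets[k] + ifdSize
    w2(nTags)
    tag(256L, 3L, 1L, wd)
    tag(257L, 3L, 1L, h)
    tag(258L, 3L, 1L, 32L)
    tag(259L, 3L, 1L, 1L)
    tag(262L, 3L, 1L, 1L)
    tag(273L, 4L, 1L, stripOffset)
    tag(278L, 3L, 1L, h)
    tag(279L, 4L, 1L, 4L * h * wd)
    tag(339L, 3L, 1L, 3L)
    w4(if (k < npage) ifdOffsets[k + 1L] else 0L)
    writeBin(as.numeric(t(fr)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

# ---- stack reading ----------------------------------------------------------

# Order file names the way acquisition software numbers them: zero-padded
# names sort lexicographically; unpadded numeric suffixes are sorted
# numerically so frame_2 precedes frame_10.
orderFrameFiles <- function(files) {
  base <- tools::file_path_sans_ext(basename(files))
  num <- suppressWarnings(as.numeric(sub("^.*?(\\d+)$", "\\1", base)))
  hasNum <- grepl("\\d+$", base)
  if (all(hasNum) && !anyNA(num)) {
    prefix <- sub("\\d+$", "", base)
    files[order(prefix, num)]
  } else files[order(base)]
}

rawDtypeInfo <- function(dtype) {
  switch(dtype,
    float32 = list(what = "numeric", size = 4L, signed = TRUE),
    float64 = list(what = "numeric", size = 8L, signed = TRUE),
    uint8 = list(what = "integer", size = 1L, signed = FALSE),
    uint16 = list(what = "integer", size = 2L, signed = FALSE),
    int16 = list(what = "integer", size = 2L, signed = TRUE),
    int32 = list(what = "integer", size = 4L, signed = TRUE),
    stop("unsupported raw dtype: ", dtype))
}

#' Read a projection stack from disk
#'
#' @param path a directory of TIFF files, a single (possibly multipage) TIFF
#'   file, or a raw file.
#' @param kind \code{"auto"} (directory -> tiff_sequence, .tif file ->
#'   multipage_tiff, otherwise raw), or one of \code{"tiff_sequence"},
#'   \code{"multipage_tiff"}, \code{"raw"}.
#' @param rawShape for raw input, \code{c(nrow, ncol, nframes)}.
#' @param rawDtype for raw input, one of \code{"float32"}, \code{"float64"},
#'   \code{"uint8"}, \code{"uint16"}, \code{"int16"}, \code{"int32"}.
#' @param role stored on the returned stack.
#' @return A [ProjectionStack-class]; frames are converted to double. TIFF
#'   sequences are ordered lexicographically (numeric suffixes numerically).
#' @export
readStack <- function(path, kind = "auto", rawShape = NULL, rawDtype = "float32",
                      role = "tomo") {
  if (kind == "auto") {
    kind <- if (dir.exists(path)) "tiff_sequence"
    else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "multipage_tiff"
    else "raw"
  }
  if (kind == "tiff_sequence") {
    files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                        full.names = TRUE)
    if (!length(files)) stop("no TIFF files in ", path)
    files <- orderFrameFiles(files)
    fr <- lapply(files, function(f) {
      pages <- tiff::readTIFF(f, all = TRUE)
      lapply(pages, asGray)
    })
    fr <- unlist(fr, recursive = FALSE)
    names(fr) <- NULL
    d <- dim(fr[[1L]])
    bad <- which(vapply(fr, function(m) !identical(dim(m), d), logical(1L)))
    if (length(bad)) {
      stop("frame shape mismatch in ", path, ": file ",
           basename(files[min(length(files), bad[1L])]),
           " has dimensions ", paste(dim(fr[[bad[1L]]]), collapse = "x"),
           ", expected ", paste(d, collapse = "x"))
    }
    return(projectionStack(fr, role = role))
  }
  if (kind == "multipage_tiff") {
    pages <- tiff::readTIFF(path, all = TRUE)
    pages <- lapply(pages, asGray)
    d <- dim(pages[[1L]])
    if (any(vapply(pages, function(m) !identical(dim(m), d), logical(1L))))
      stop("page shape mismatch in ", path)
    return(projectionStack(pages, role = role))
  }
  if (kind == "raw") {
    if (is.null(rawShape) || length(rawShape) != 3L)
      stop("raw input needs rawShape = c(nrow, ncol, nframes)")
    info <- rawDtypeInfo(rawDtype)
    n <- prod(rawShape)
    v <- readBin(path, what = info$what, n = n, size = info$size,
                 signed = info$signed, endian = "little")
    if (length(v) != n) stop("raw file ", path, " is shorter than declared shape")
    # file stores frames row-major (rows contiguous), like the TIFF strips
    a <- array(NA_real_, dim = rawShape)
    perFrame <- rawShape[1L] * rawShape[2L]
    for (k in seq_len(rawShape[3L])) {
      a[, , k] <- matrix(v[((k - 1L) * perFrame + 1L):(k * perFrame)],
                         rawShape[1L], rawShape[2L], byrow = TRUE)
    }
    return(projectionStack(a, role = role))
  }
  stop("unknown kind: ", kind)
}

asGray <- function(m) {
  if (length(dim(m)) == 3L) m <- m[, , 1L]   # drop extra channels
  storage.mode(m) <- "double"
  m
}

#' Write a projection stack or volume to disk
#'
#' Float data is stored as uncompressed 32-bit IEEE-float TIFF (or raw);
#' integer dtypes require already-quantized integral values in range (see
#' [clipQuantize()]) -- lossy implicit casts are refused.
#'
#' @param stack a [ProjectionStack-class], 3D array or matrix.
#' @param path output directory (tiff_sequence), file (multipage_tiff, raw).
#' @param kind \code{"tiff_sequence"}, \code{"multipage_tiff"} or \code{"raw"}.
#' @param dtype \code{"float32"}, \code{"uint16"} or \code{"uint8"}.
#' @param prefix file-name prefix for sequences.
#' @return Invisibly, the paths written.
#' @export
writeStack <- function(stack, path, kind = c("tiff_sequence", "multipage_tiff",
                                             "raw"),
                       dtype = "float32", prefix = "frame") {
  kind <- match.arg(kind)
  a <- if (is(stack, "ProjectionStack")) stack@frames else stack
  if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1L))
  if (length(dim(a)) != 3L || dim(a)[3L] < 1L || !length(a))
    stop("empty stack")
  nfr <- dim(a)[3L]
  if (dtype %in% c("uint8", "uint16")) {
    top <- if (dtype == "uint8") 255 else 65535
    if (any(a < 0 | a > top) || any(a != round(a)))
      stop("refusing lossy cast: quantize with clipQuantize() before ",
           "writing ", dtype)
  }
  if (kind == "tiff_sequence") {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    files <- file.path(path, sprintf("%s_%05d.tif", prefix, seq_len(nfr) - 1L))
    for (k in seq_len(nfr)) {
      if (dtype == "float32") writeFloatTiff(list(a[, , k]), files[k])
      else tiff::writeTIFF(a[, , k] / ifelse(dtype == "uint8", 255, 65535),
                           files[k],
                           bits.per.sample = if (dtype == "uint8") 8L else 16L,
                           compression = "none")
    }
    return(invisible(files))
  }
  if (kind == "multipage_tiff") {
    fr <- lapply(seq_len(nfr), function(k) a[, , k])
    if (dtype == "float32") writeFloatTiff(fr, path)
    else tiff::writeTIFF(lapply(fr, function(m)
      m / ifelse(dtype == "uint8", 255, 65535)), path,
      bits.per.sample = if (dtype == "uint8") 8L else 16L,
      compression = "none")
    return(invisible(path))
  }
  # raw: row-major, little-endian
  con <- file(path, "wb")
  on.exit(close(con))
  info <- rawDtypeInfo(if (dtype == "float32") "float32" else dtype)
  for (k in seq_len(nfr)) {
    v <- as.numeric(t(a[, , k]))
    if (info$what == "integer") v <- as.integer(v)
    writeBin(v, con, size = info$size, endian = "little")
  }
  invisible(path)
}

# ---- dataset discovery ------------------------------------------------------

#' Discover CT data sets under a directory tree
#'
#' A valid CT directory contains the darks/flats/tomo triple as
#' subdirectories (names configurable). The search is recursive and relative
#' paths are preserved in the returned layouts.
#'
#' @param root directory to search.
#' @param roles named character vector mapping the three roles to directory
#'   names.
#' @return A list of [DatasetLayout-class] objects (possibly empty).
#' @export
discoverLayout <- function(root,
                           roles = c(darks = "darks", flats = "flats",
                                     tomo = "tomo")) {
  if (!dir.exists(root)) return(list())
  dirs <- c(root, list.dirs(root, recursive = TRUE, full.names = TRUE))
  dirs <- unique(normalizePath(dirs))
  out <- list()
  for (d in dirs) {
    sub <- file.path(d, roles)
    if (all(dir.exists(sub))) {
      out[[length(out) + 1L]] <- new("DatasetLayout", root = d,
                                     darksDir = sub[[which(names(roles) == "darks")]],
                                     flatsDir = sub[[which(names(roles) == "flats")]],
                                     tomoDir = sub[[which(names(roles) == "tomo")]],
                                     kind = "tiff_sequence")
    }
  }
  out
}

# ---- parameter dumps --------------------------------------------------------

#' Write / read a plain-text key=value parameter dump
#'
#' Every reconstruction writes the parameters needed to re-run it next to
#' its outputs; the dump is a flat key=value text file (vectors
#' comma-separated).
#'
#' @param params named list of scalars / numeric vectors / strings.
#' @param path file to write.
#' @return \code{writeParameterDump}: invisibly, \code{path};
#'   \code{readParameterDump}: the named list (numbers parsed back).
#' @export
writeParameterDump <- function(params, path) {
  lines <- vapply(names(params), function(k) {
    v <- params[[k]]
    sprintf("%s=%s", k, paste(format(v, digits = 17, trim = TRUE,
                                     scientific = FALSE), collapse = ","))
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeParameterDump
#' @export
readParameterDump <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    k <- substr(ln, 1L, eq - 1L)
    v <- strsplit(substr(ln, eq + 1L, nchar(ln)), ",", fixed = TRUE)[[1L]]
    num <- suppressWarnings(as.numeric(v))
    out[[k]] <- if (anyNA(num)) v else num
  }
  out
}
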