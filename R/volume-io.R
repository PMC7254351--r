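## Volume and angiogram I/O.
##
## On-disk dialects:
##  * multi-page TIFF (one 32-bit float page per z slice) + JSON sidecar.
##    TIFF float pages hold values in [0, 1]; amplitudes are stored
##    divided by data_max, which the sidecar records, and re-scaled on
##    read (lossless at float32 precision).
##  * raw little-endian binary + JSON sidecar (exact float64 dump), for
##    camera-style dumps; selected by a .raw/.bin extension.
## The sidecar states dtype, shape, axis_order, voxel pitch and
## surface_index so cubes stored in any axis permutation normalize to
## (z, x, y) on read.

.sidecarPath <- function(path) paste0(path, ".json")

.isRawPath <- function(path) grepl("\\.(raw|bin)$", path, ignore.case = TRUE)

.writeSidecar <- function(path, meta) {
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(.sidecarPath(path))
}

.readSidecar <- function(metadataPath) {
  if (!file.exists(metadataPath))
    stop("metadata sidecar not found: ", metadataPath, call. = FALSE)
  jsonlite::read_json(metadataPath, simplifyVector = TRUE)
}

.checkVoxels <- function(data, path) {
  bad <- is.na(data) | is.nan(data)
  if (any(bad)) {
    idx <- arrayInd(which(bad)[1L], dim(data))
    stop(sprintf("NaN voxel at (z=%d, x=%d, y=%d) in %s",
                 idx[1L], idx[2L], idx[3L], path), call. = FALSE)
  }
  neg <- data < 0
  if (any(neg)) {
    idx <- arrayInd(which(neg)[1L], dim(data))
    stop(sprintf("negative voxel at (z=%d, x=%d, y=%d) in %s",
                 idx[1L], idx[2L], idx[3L], path), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read an OCTA volume from disk
#'
#' Reads a multi-page TIFF stack (one page per z slice) or a raw binary
#' dump, together with its JSON metadata sidecar, and returns an
#' [OctaVolume-class] with axes normalized to (z, x, y) regardless of the
#' on-disk layout. Negative or NaN stored voxels are an error naming the
#' first offending index, never silently clipped.
#'
#' @param path file written by [writeVolume()] (or compatible).
#' @param metadataPath JSON sidecar; defaults to `paste0(path, ".json")`.
#' @return an [OctaVolume-class].
#' @examples
#' vol <- OctaVolume(array(runif(24), c(4, 3, 2)), 4, 16, 16)
#' f <- tempfile(fileext = ".raw")
#' writeVolume(vol, f)
#' identical(volData(readVolume(f)), volData(vol))
#' @seealso [writeVolume()]
#' @export
readVolume <- function(path, metadataPath = NULL) {
  if (!file.exists(path))
    stop("volume file not found: ", path, call. = FALSE)
  if (is.null(metadataPath)) metadataPath <- .sidecarPath(path)
  meta <- .readSidecar(metadataPath)
  shape <- as.integer(meta$shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("sidecar must declare a positive integer shape of length 3",
         call. = FALSE)
  axisOrder <- if (is.null(meta$axis_order)) "zxy" else meta$axis_order
  perm <- match(c("z", "x", "y"), strsplit(axisOrder, "")[[1L]])
  if (any(is.na(perm)))
    stop("sidecar axis_order must be a permutation of \"zxy\": got ",
         axisOrder, call. = FALSE)

  if (.isRawPath(path)) {
    n <- prod(shape)
    sz <- if (identical(meta$dtype, "float32")) 4L else 8L
    have <- file.info(path)$size / sz
    if (have != n)
      stop(sprintf(
        "sidecar declares shape %s (%d voxels) but %s holds %g values",
        paste(shape, collapse = "x"), n, path, have), call. = FALSE)
    raw <- readBin(path, "double", n = n, size = sz, endian = "little")
    stored <- array(raw, dim = shape)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pg <- dim(pages[[1L]])
    onDisk <- c(length(pages), pg[1L], pg[2L])
    if (!identical(onDisk, shape))
      stop(sprintf(
        "sidecar declares shape %s but TIFF stack is %s (pages x rows x cols)",
        paste(shape, collapse = "x"), paste(onDisk, collapse = "x")),
        call. = FALSE)
    stored <- array(0, dim = shape)
    for (j in seq_along(pages)) stored[j, , ] <- pages[[j]]
    dataMax <- if (is.null(meta$data_max)) 1 else as.numeric(meta$data_max)
    stored <- stored * dataMax
  }

  data <- aperm(stored, perm)
  .checkVoxels(data, path)
  pitch <- vapply(c("dz_um", "dx_um", "dy_um"), function(k) {
    v <- meta[[k]]
    if (is.null(v)) stop("sidecar missing ", k, call. = FALSE)
    as.numeric(v)
  }, numeric(1))
  si <- if (is.null(meta$surface_index)) 0L else as.integer(meta$surface_index)
  OctaVolume(data, pitch[1L], pitch[2L], pitch[3L], si)
}

#' Write an OCTA volume to disk
#'
#' Emits either a multi-page TIFF (32-bit float, one page per z slice,
#' amplitudes stored divided by the recorded `data_max`) or, for a
#' `.raw`/`.bin` path, an exact little-endian float64 dump. A JSON
#' sidecar at `paste0(path, ".json")` records dtype, shape, axis order,
#' voxel pitch and surface index, so [readVolume()] round-trips the
#' volume at the stored precision.
#'
#' @param vol an [OctaVolume-class].
#' @param path destination; extension selects the dialect.
#' @return `path`, invisibly.
#' @seealso [readVolume()]
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "OctaVolume"))
  validObject(vol)
  d <- dim(vol@data)
  meta <- list(shape = d, axis_order = "zxy", dz_um = vol@dzUm,
               dx_um = vol@dxUm, dy_um = vol@dyUm,
               surface_index = vol@surfaceIndex)
  ok <- try({
    if (.isRawPath(path)) {
      meta$dtype <- "float64"
      writeBin(as.vector(vol@data), path, size = 8L, endian = "little")
    } else {
      meta$dtype <- "float32"
      mx <- max(vol@data)
      meta$data_max <- if (mx > 0) mx else 1
      scaled <- vol@data / meta$data_max
      pages <- lapply(seq_len(d[1L]), function(j) scaled[j, , ])
      tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    }
    .writeSidecar(path, meta)
  }, silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed writing volume to ", path, ": ",
         attr(ok, "condition")$message, call. = FALSE)
  invisible(path)
}

#' Write an en face angiogram as a 16-bit grayscale image
#'
#' Linearly rescales pixel values from `[min, max]` to the full 16-bit
#' range and writes a single-page grayscale TIFF, with a JSON sidecar
#' recording the depth range and intensity scale. A constant image maps
#' to all zeros with a warning (not an error).
#'
#' @param img an [Angiogram-class].
#' @param path destination TIFF path.
#' @return `path`, invisibly.
#' @export
writeAngiogram <- function(img, path) {
  stopifnot(is(img, "Angiogram"))
  validObject(img)
  d <- img@data
  rng <- range(d)
  if (rng[1L] == rng[2L]) {
    warning("constant angiogram: all pixels map to 0 in ", path)
    scaled <- matrix(0, nrow(d), ncol(d))
  } else {
    scaled <- (d - rng[1L]) / (rng[2L] - rng[1L])
  }
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  .writeSidecar(path, list(
    depth_range_um = img@depthRangeUm, scale = img@scale,
    value_range = rng, bits = 16L))
  invisible(path)
}
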