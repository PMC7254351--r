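## Slab extraction and en face angiogram generation.

#' Extract a depth slab from a volume
#'
#' Converts a half-open depth interval `[zTopUm, zBottomUm)` in
#' micrometres below the tissue surface into a half-open 0-based voxel
#' index interval, using the volume's axial pitch and surface index:
#' `idx = surfaceIndex + floor(um / dzUm)`. `floor` assigns a boundary
#' falling mid-voxel to the deeper-starting slab, so tiled slabs never
#' double-count a slice.
#'
#' @param vol an [OctaVolume-class].
#' @param zTopUm,zBottomUm slab bounds in um below the surface,
#'   `zTopUm < zBottomUm`.
#' @return a [Slab-class].
#' @examples
#' vol <- OctaVolume(array(0, c(256, 8, 8)), dzUm = 2, dxUm = 16, dyUm = 16)
#' extractSlab(vol, 400, 420)  # z indices [200, 210)
#' @seealso [maxAmplitudeProjection()]
#' @export
extractSlab <- function(vol, zTopUm, zBottomUm) {
  stopifnot(is(vol, "OctaVolume"))
  if (!is.finite(zTopUm) || !is.finite(zBottomUm) || zTopUm >= zBottomUm)
    stop("slab bounds must satisfy zTopUm < zBottomUm", call. = FALSE)
  nz <- dim(vol@data)[1L]
  top <- vol@surfaceIndex + as.integer(floor(zTopUm / vol@dzUm))
  bot <- vol@surfaceIndex + as.integer(floor(zBottomUm / vol@dzUm))
  if (top < 0L || bot > nz || top >= bot)
    stop(sprintf(
      paste0("slab [%g, %g) um converts to empty/out-of-range z indices ",
             "[%d, %d) (dz = %g um, surface index %d, nz = %d)"),
      zTopUm, zBottomUm, top, bot, vol@dzUm, vol@surfaceIndex, nz),
      call. = FALSE)
  new("Slab", parent = vol, zTopUm = as.numeric(zTopUm),
      zBottomUm = as.numeric(zBottomUm), zTopIdx = top, zBottomIdx = bot)
}

#' En face angiogram by maximum amplitude projection
#'
#' Collapses a slab into a 2-D view: each (x, y) pixel is the maximum
#' amplitude over the slab's z index interval. The result is on the
#' linear amplitude scale; apply [logScale()] for display.
#'
#' @param slab a [Slab-class] from [extractSlab()].
#' @return an [Angiogram-class] with the slab's depth range recorded.
#' @export
maxAmplitudeProjection <- function(slab) {
  stopifnot(is(slab, "Slab"))
  validObject(slab)
  rows <- (slab@zTopIdx + 1L):slab@zBottomIdx
  sub <- slab@parent@data[rows, , , drop = FALSE]
  proj <- apply(sub, c(2L, 3L), max)
  Angiogram(proj, c(slab@zTopUm, slab@zBottomUm), scale = "linear")
}

#' Logarithmic display scaling of an angiogram
#'
#' Maps linear amplitudes to `20 * log10(pixel / max)` decibels, clamps
#' below at `floorDb`, then affinely rescales `[floorDb, 0]` dB to
#' `[0, 1]`. Pixel ordering is preserved; the brightest pixel maps to 1
#' and anything at or below `max * 10^(floorDb / 20)` maps to 0.
#'
#' @param img a linear-scale [Angiogram-class].
#' @param floorDb negative dB floor (default -40).
#' @return a log-scale [Angiogram-class]; an all-zero image passes
#'   through as zeros with a warning.
#' @export
logScale <- function(img, floorDb = -40) {
  stopifnot(is(img, "Angiogram"))
  if (img@scale != "linear")
    stop("logScale expects a linear-scale angiogram", call. = FALSE)
  if (!is.finite(floorDb) || floorDb >= 0)
    stop("floorDb must be a negative number", call. = FALSE)
  mx <- max(img@data)
  if (mx <= 0) {
    warning("all-zero angiogram: log scaling is a no-op")
    return(Angiogram(img@data, img@depthRangeUm, scale = "log"))
  }
  db <- ifelse(img@data > 0, 20 * log10(img@data / mx), -Inf)
  db <- pmax(db, floorDb)
  Angiogram((db - floorDb) / (-floorDb), img@depthRangeUm, scale = "log")
}
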