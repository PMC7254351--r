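## Phantom-based evaluation: per-capillary visibility bookkeeping and
## the capillary SNR sweep over the mean-subtraction weight.

## (x, y) columns containing any vessel voxel, as an nx x ny matrix.
.vesselColumns <- function(truth) {
  nz <- dim(truth@vesselMask)[1L]
  d <- dim(truth@vesselMask)
  matrix(colSums(matrix(truth@vesselMask, nrow = nz)) > 0L,
         d[2L], d[3L])
}

#' Per-capillary visibility report
#'
#' For every capillary of a phantom spec, reports whether it is
#' shadowed (shares an (x, y) column with a vessel), its peak amplitude
#' in the supplied volume, and the mean of the surrounding local
#' background (a lateral/axial neighbourhood excluding vessel and
#' capillary voxels). Run on a de-shadowed volume, `peak >
#' backgroundMean` means the capillary survived processing and stands
#' out of its local background.
#'
#' @param vol the [OctaVolume-class] to measure (original or processed;
#'   must match the phantom's geometry).
#' @param spec the [PhantomSpec-class] that generated the phantom.
#' @param truth the matching [PhantomTruth-class].
#' @param lateralMarginVox,zMarginVox half-width of the local
#'   background neighbourhood, in voxels.
#' @return data.frame with columns `id`, `shadowed`, `peak`,
#'   `backgroundMean`.
#' @seealso [generatePhantom()]
#' @export
capillaryVisibility <- function(vol, spec, truth, lateralMarginVox = 6L,
                                zMarginVox = 6L) {
  stopifnot(is(vol, "OctaVolume"), is(spec, "PhantomSpec"),
            is(truth, "PhantomTruth"))
  if (!identical(dim(vol@data), spec@shape))
    stop("volume does not match the phantom geometry", call. = FALSE)
  grid <- .gridUm(spec)
  vcols <- .vesselColumns(truth)
  structure <- truth@vesselMask | truth@capillaryMask
  nCap <- nrow(spec@capillaries)
  out <- data.frame(id = seq_len(nCap), shadowed = logical(nCap),
                    peak = numeric(nCap), backgroundMean = numeric(nCap))
  d <- spec@shape
  for (i in seq_len(nCap)) {
    idx <- .capillaryVoxels(spec, i, grid)
    out$shadowed[i] <- any(vcols[idx[, 2:3, drop = FALSE]])
    out$peak[i] <- max(vol@data[.linIndex(idx, d)])
    zr <- max(1L, min(idx[, 1L]) - zMarginVox):
          min(d[1L], max(idx[, 1L]) + zMarginVox)
    xr <- max(1L, min(idx[, 2L]) - lateralMarginVox):
          min(d[2L], max(idx[, 2L]) + lateralMarginVox)
    yr <- max(1L, min(idx[, 3L]) - lateralMarginVox):
          min(d[3L], max(idx[, 3L]) + lateralMarginVox)
    nb <- vol@data[zr, xr, yr]
    keep <- !structure[zr, xr, yr]
    out$backgroundMean[i] <- mean(nb[keep])
  }
  out
}

## Split a sorted integer vector into maximal contiguous runs, returned
## as a list of c(lo, hi) intervals.
.contiguousRuns <- function(v) {
  if (!length(v)) return(list())
  brk <- c(0L, which(diff(v) > 1L), length(v))
  lapply(seq_len(length(brk) - 1L), function(k)
    c(v[brk[k] + 1L], v[brk[k + 1L]]))
}

## Choose the sweep target: a shadowed capillary scored on a transverse
## profile along x, with background windows in a +/- halfWidth column
## neighbourhood spanning the vessel shadow and its edge (other
## capillary columns excluded). Returns NULL if no shadowed capillary
## offers enough background pixels.
.selectSweepRoi <- function(vol, spec, truth, slabHalfUm,
                            halfWidth = 8L) {
  grid <- .gridUm(spec)
  vcols <- .vesselColumns(truth)
  nx <- spec@shape[2L]
  best <- NULL
  for (i in seq_len(nrow(spec@capillaries))) {
    cp <- spec@capillaries[i, ]
    xi <- which.min(abs(grid$x - cp$x_um))
    yi <- which.min(abs(grid$y - cp$y_um))
    zi <- which.min(abs(grid$z - cp$z_um))
    if (!vcols[xi, yi]) next
    rows <- which(abs(grid$z - cp$z_um) <= slabHalfUm)
    cand <- max(1L, xi - halfWidth):min(nx, xi + halfWidth)
    capCols <- vapply(cand, function(x)
      any(truth@capillaryMask[rows, x, yi]), logical(1))
    ok <- setdiff(cand[!capCols], (xi - 1L):(xi + 1L))
    if (length(ok) < 6L) next
    bgw <- Filter(function(w) w[2L] > w[1L], .contiguousRuns(ok))
    if (!length(bgw)) next
    nShadow <- sum(vcols[unlist(lapply(bgw, function(w) w[1L]:w[2L])),
                         yi])
    score <- nShadow * 100L + length(ok)
    if (is.null(best) || score > best$score)
      best <- list(cap = i, xi = xi, yi = yi, zi = zi, rows = rows,
                   peakWindow = c(max(1L, xi - 1L), min(nx, xi + 1L)),
                   backgroundWindows = bgw, score = score)
  }
  best
}

#' Capillary SNR under a mean-subtraction weight sweep
#'
#' Reproduces the weight-optimisation experiment on a phantom: a
#' shadowed deep capillary is selected from the ground truth, a
#' transverse intensity profile through it is computed (maximum
#' projection over a thin depth window) after mean subtraction at each
#' weight of `wGrid`, and [profileSnr()] is scored against background
#' windows inside the overlying vessel's shadow. The subtraction is
#' evaluated unclipped here: clipping zeroes whole background windows at
#' large weights, which turns the SNR into a `+Inf` censoring sentinel
#' rather than a measure of residual artifact texture.
#'
#' @param vol the original phantom [OctaVolume-class].
#' @param spec,truth the phantom's [PhantomSpec-class] /
#'   [PhantomTruth-class].
#' @param wGrid non-negative, strictly increasing weights.
#' @param slabHalfUm half-thickness (um) of the depth window projected
#'   around the capillary centre.
#' @return data.frame with columns `w`, `snr`; attributes `roi` (the
#'   selected capillary and windows) and `wOpt` (the grid argmax).
#' @seealso [cmdSweepW()], [profileSnr()]
#' @export
capillarySnrSweep <- function(vol, spec, truth, wGrid = seq(0, 3.5, 0.5),
                              slabHalfUm = 10) {
  stopifnot(is(vol, "OctaVolume"))
  if (any(wGrid < 0) || any(diff(wGrid) <= 0))
    stop("wGrid must be non-negative and strictly increasing",
         call. = FALSE)
  roi <- .selectSweepRoi(vol, spec, truth, slabHalfUm)
  if (is.null(roi))
    stop("no shadowed capillary with a usable background window found",
         call. = FALSE)
  plane <- vol@data[, , roi$yi]            # nz x nx
  mu <- colMeans(plane)                    # per-A-line mean, all N pixels
  sub <- plane[roi$rows, , drop = FALSE]
  snr <- vapply(wGrid, function(w) {
    resid <- sub - matrix(w * mu, nrow = length(roi$rows),
                          ncol = ncol(sub), byrow = TRUE)
    prof <- apply(resid, 2L, max)
    profileSnr(prof, roi$peakWindow, roi$backgroundWindows)
  }, numeric(1))
  out <- data.frame(w = wGrid, snr = snr)
  attr(out, "roi") <- roi[c("cap", "xi", "yi", "zi", "peakWindow",
                            "backgroundWindows")]
  attr(out, "wOpt") <- wGrid[which.max(snr)]
  out
}
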