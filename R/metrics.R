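## Quantitative evaluation: line-profile RMS contrast, capillary SNR,
## and cross-correlation similarity between adjacent en face slabs.

.popSd <- function(v) sqrt(mean((v - mean(v))^2))

#' Extract a 1-D line profile
#'
#' Pulls a single intensity profile out of an angiogram or volume.
#' For an [Angiogram-class], `axis = "x"` returns the profile running
#' along x at column `location` (one of the ny "horizontal" lines);
#' `axis = "y"` the converse. For an [OctaVolume-class], `axis = "z"`
#' returns the A-line at `location = c(x, y)`, and `axis = "x"`/`"y"`
#' a transverse profile at `location = c(z, y)` / `c(z, x)` (1-based).
#'
#' @param x an [Angiogram-class] or [OctaVolume-class].
#' @param axis axis the profile runs along.
#' @param location fixed indices of the other axes (1-based).
#' @return numeric vector of intensities.
#' @export
profileAlong <- function(x, axis = c("x", "y", "z"), location) {
  axis <- match.arg(axis)
  if (is(x, "Angiogram")) {
    if (axis == "z") stop("an angiogram has no z axis", call. = FALSE)
    if (axis == "x") x@data[, location[1L]] else x@data[location[1L], ]
  } else if (is(x, "OctaVolume")) {
    switch(axis,
      z = x@data[, location[1L], location[2L]],
      x = x@data[location[1L], , location[2L]],
      y = x@data[location[1L], location[2L], ])
  } else {
    stop("x must be an Angiogram or OctaVolume", call. = FALSE)
  }
}

#' RMS contrast of a line profile
#'
#' The root-mean-square contrast of an intensity profile, defined as the
#' population standard deviation of its pixel values (no mean
#' normalization): the magnitude of vessel signal excursions relative to
#' the local background.
#'
#' @param profile numeric vector of length >= 2.
#' @return non-negative scalar.
#' @examples
#' rmsContrast(c(0, 1, 0, 1))  # 0.5
#' @seealso [meanRmsContrast()]
#' @export
rmsContrast <- function(profile) {
  if (!is.numeric(profile) || length(profile) < 2L)
    stop("profile must be numeric with length >= 2", call. = FALSE)
  if (any(!is.finite(profile)))
    stop("profile contains non-finite values", call. = FALSE)
  .popSd(profile)
}

#' Average RMS contrast over all lines of an angiogram
#'
#' Applies [rmsContrast()] to every line profile along the chosen axis
#' (`axis = "x"`: the ny horizontal lines) and summarises them.
#'
#' @param img an [Angiogram-class].
#' @param axis axis the profiles run along.
#' @return list with `mean`, `sd` (population SD across lines) and
#'   `perLine` (the full vector of per-line contrasts).
#' @export
meanRmsContrast <- function(img, axis = c("x", "y")) {
  stopifnot(is(img, "Angiogram"))
  axis <- match.arg(axis)
  lines <- if (axis == "x") {
    lapply(seq_len(ncol(img@data)), function(j) img@data[, j])
  } else {
    lapply(seq_len(nrow(img@data)), function(i) img@data[i, ])
  }
  per <- vapply(lines, rmsContrast, numeric(1))
  list(mean = mean(per), sd = .popSd(per), perLine = per)
}

.windowIndices <- function(w, n, what) {
  if (length(w) != 2L || any(!is.finite(w)) || w[1L] > w[2L] ||
      w[1L] < 1 || w[2L] > n)
    stop(what, " window must be c(lo, hi) inside the profile",
         call. = FALSE)
  seq.int(w[1L], w[2L])
}

#' Peak signal-to-noise ratio of a profile
#'
#' Scores a vessel cross-section against its local background:
#' `(max over the peak window - mean over the background windows) /
#' (population SD over the background windows)`. Used to score a
#' capillary under a de-shadowing parameter sweep; invariant to adding
#' a constant to the whole profile.
#'
#' @param profile numeric vector.
#' @param peakWindow `c(lo, hi)` 1-based inclusive index interval
#'   containing the peak.
#' @param backgroundWindows list of `c(lo, hi)` intervals, disjoint from
#'   the peak window and from each other.
#' @return the SNR; `+Inf` with a warning when the background is exactly
#'   constant.
#' @examples
#' profileSnr(c(1, 1, 10, 1.5, 0.5), peakWindow = c(3, 3),
#'            backgroundWindows = list(c(1, 2), c(4, 5)))
#' @export
profileSnr <- function(profile, peakWindow, backgroundWindows) {
  if (!is.numeric(profile) || length(profile) < 2L)
    stop("profile must be numeric with length >= 2", call. = FALSE)
  n <- length(profile)
  pk <- .windowIndices(peakWindow, n, "peak")
  if (!is.list(backgroundWindows) || length(backgroundWindows) == 0L)
    stop("backgroundWindows must be a non-empty list of intervals",
         call. = FALSE)
  bg <- unlist(lapply(backgroundWindows, .windowIndices, n = n,
                      what = "background"))
  if (anyDuplicated(bg) || length(intersect(pk, bg)))
    stop("peak and background windows must be disjoint", call. = FALSE)
  s <- .popSd(profile[bg])
  if (s == 0) {
    warning("background window is constant: SNR is +Inf")
    return(Inf)
  }
  (max(profile[pk]) - mean(profile[bg])) / s
}

#' Cross-correlation similarity of two angiograms
#'
#' Zero-normalized cross-correlation at zero lag: the Pearson
#' correlation of the flattened pixel vectors. Values near 1 indicate
#' that adjacent slabs show the same structures; low values indicate
#' depth heterogeneity of the vascular network.
#'
#' @param a,b [Angiogram-class] objects of identical shape and scale.
#' @return correlation in \[-1, 1\].
#' @seealso [similarityVsDepth()]
#' @export
slabSimilarity <- function(a, b) {
  stopifnot(is(a, "Angiogram"), is(b, "Angiogram"))
  if (!identical(dim(a@data), dim(b@data)))
    stop("angiograms must have identical shape", call. = FALSE)
  if (a@scale != b@scale)
    stop("angiograms must be on the same intensity scale", call. = FALSE)
  va <- as.vector(a@data); vb <- as.vector(b@data)
  if (.popSd(va) == 0)
    stop("first angiogram is constant: correlation undefined",
         call. = FALSE)
  if (.popSd(vb) == 0)
    stop("second angiogram is constant: correlation undefined",
         call. = FALSE)
  stats::cor(va, vb)
}

#' Similarity between adjacent en face slabs as depth increases
#'
#' Projects consecutive slabs of thickness `slabThicknessUm`, stepped by
#' `stepUm` through `[zStartUm, zEndUm]`, and returns the
#' [slabSimilarity()] between each adjacent pair, indexed by the
#' shallower slab's top depth. A declining curve indicates vascular
#' structure changing with depth. Defaults follow an adjacent-slab gap
#' of 5 um between 20-um slabs.
#'
#' @param vol an [OctaVolume-class].
#' @param slabThicknessUm slab thickness in um.
#' @param stepUm step between consecutive slab tops in um.
#' @param zStartUm,zEndUm depth range swept, in um below the surface.
#' @return data.frame with columns `depth_um`, `similarity`; one row per
#'   adjacent pair, i.e. `floor((zEndUm - zStartUm - slabThicknessUm) /
#'   stepUm)` rows.
#' @export
similarityVsDepth <- function(vol, slabThicknessUm = 20, stepUm = 5,
                              zStartUm, zEndUm) {
  stopifnot(is(vol, "OctaVolume"))
  if (slabThicknessUm <= 0 || stepUm <= 0)
    stop("slabThicknessUm and stepUm must be positive", call. = FALSE)
  nPairs <- floor((zEndUm - zStartUm - slabThicknessUm) / stepUm)
  if (nPairs < 1)
    stop("fewer than two slabs fit in [zStartUm, zEndUm]", call. = FALSE)
  tops <- zStartUm + stepUm * (0:nPairs)
  projs <- lapply(tops, function(t)
    maxAmplitudeProjection(extractSlab(vol, t, t + slabThicknessUm)))
  sim <- vapply(seq_len(nPairs), function(k)
    slabSimilarity(projs[[k]], projs[[k + 1L]]), numeric(1))
  data.frame(depth_um = tops[seq_len(nPairs)], similarity = sim)
}
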