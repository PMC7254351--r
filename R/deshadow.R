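## Per-A-line tail-artifact removal.
##
## Both operators act on one depth profile (A-line) at a time:
##  * mean subtraction: out = in - w * mean(in), the mean taken over ALL
##    N depth pixels of the A-line. Because the subtracted offset grows
##    with the total intensity of the line, the correction is
##    automatically more aggressive for A-lines carrying longer tails.
##  * step-down exponential filtering: proceeding top to bottom,
##    out[z] = in[z] * exp(-(1/gamma) * sum(out[1..z-1])), so each pixel
##    is attenuated by the accumulated de-shadowed signal above it.

.validAline <- function(aline) {
  if (!is.numeric(aline) || length(aline) < 1L)
    stop("A-line must be a numeric vector of length >= 1", call. = FALSE)
  if (any(!is.finite(aline)))
    stop("A-line contains NaN/non-finite entries", call. = FALSE)
  invisible(TRUE)
}

#' Mean-subtraction de-shadowing of one A-line
#'
#' Subtracts `w` times the mean of the whole depth profile from every
#' pixel of the profile. With `clipNegative = TRUE` (the default, since
#' OCTA magnitudes are non-negative) results below zero are set to zero.
#'
#' @param aline numeric depth profile, finite and non-negative.
#' @param w non-negative weight on the mean; `w = 0` is the identity.
#'   The package default elsewhere is 2.0, the weight that maximises
#'   capillary signal-to-noise.
#' @param clipNegative clip negative results to zero.
#' @return de-shadowed profile of the same length.
#' @examples
#' meanSubtractAline(c(8, 4, 0, 0), w = 1)   # mean 3 -> c(5, 1, 0, 0)
#' @seealso [stepDownAline()], [deshadowVolume()]
#' @export
meanSubtractAline <- function(aline, w, clipNegative = TRUE) {
  .validAline(aline)
  if (!is.numeric(w) || length(w) != 1L || !is.finite(w) || w < 0)
    stop("w must be a single finite non-negative number", call. = FALSE)
  out <- aline - w * mean(aline)
  if (clipNegative) out <- pmax(out, 0)
  out
}

## Step-down recursion on an (nz x ncol) matrix of A-lines, vectorized
## across columns; the z loop is inherent (out[z] depends on out[1..z-1]).
.stepDownMatrix <- function(mat, gamma) {
  out <- mat
  acc <- numeric(ncol(mat))
  for (z in seq_len(nrow(mat))) {
    row <- mat[z, ] * exp(-acc / gamma)
    out[z, ] <- row
    acc <- acc + row
  }
  out
}

#' Step-down exponential filtering of one A-line
#'
#' Sequential top-to-bottom recursion: each pixel is multiplied by
#' `exp(-(1/gamma) * S)` where `S` is the sum of the already de-shadowed
#' pixels above it. The topmost pixel passes through unchanged; output
#' obeys `0 <= out[z] <= in[z]`. Small `gamma` attenuates strongly; as
#' `gamma` grows the filter tends to the identity.
#'
#' @param aline numeric depth profile, finite and non-negative.
#' @param gamma positive attenuation constant, in units of cumulative
#'   amplitude (scale-dependent; see [matchGamma()]).
#' @return filtered profile of the same length.
#' @examples
#' stepDownAline(c(1, 1, 1), gamma = 1)  # c(1, exp(-1), exp(-1 - exp(-1)))
#' @seealso [meanSubtractAline()], [matchGamma()]
#' @export
stepDownAline <- function(aline, gamma) {
  .validAline(aline)
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma <= 0)
    stop("gamma must be a single finite positive number", call. = FALSE)
  as.numeric(.stepDownMatrix(matrix(aline, ncol = 1L), gamma))
}

#' De-shadow a whole OCTA volume
#'
#' Applies the operator selected in `params` independently to every
#' (x, y) column of the volume. Pixels above the volume's
#' `surfaceIndex` pass through unmodified (and are excluded from the
#' step-down attenuation sum); the mean-subtraction offset is still
#' computed over all N depth pixels of each A-line. With
#' `normalizeOutput` the processed volume is divided by its global
#' maximum — a pure rescale with no contrast adjustment.
#'
#' @param vol an [OctaVolume-class].
#' @param params a [DeshadowParams-class].
#' @return a new [OctaVolume-class] with metadata copied through.
#' @examples
#' vol <- generatePhantom(defaultCortexSpec(1))$volume
#' ds <- deshadowVolume(vol, deshadowParams("mean_subtraction", w = 2))
#' @export
deshadowVolume <- function(vol, params = deshadowParams()) {
  stopifnot(is(vol, "OctaVolume"), is(params, "DeshadowParams"))
  validObject(vol); validObject(params)
  d <- dim(vol@data)
  nz <- d[1L]
  m <- matrix(vol@data, nrow = nz)
  tissue <- (vol@surfaceIndex + 1L):nz

  if (params@method == "mean_subtraction") {
    offset <- params@w * colMeans(m)
    sub <- m[tissue, , drop = FALSE] -
      matrix(offset, nrow = length(tissue), ncol = ncol(m), byrow = TRUE)
    if (params@clipNegative) sub <- pmax(sub, 0)
    m[tissue, ] <- sub
  } else {
    m[tissue, ] <- .stepDownMatrix(m[tissue, , drop = FALSE],
                                   params@gamma)
  }
  out <- array(m, dim = d)

  if (params@equalize) {
    tmp <- OctaVolume(out, vol@dzUm, vol@dxUm, vol@dyUm,
                      vol@surfaceIndex)
    out <- equalizeVolume(tmp)@data
  }
  if (params@normalizeOutput) {
    mx <- max(out)
    if (mx > 0) out <- out / mx
    else warning("all-zero volume: normalization skipped")
  }
  OctaVolume(out, vol@dzUm, vol@dxUm, vol@dyUm, vol@surfaceIndex)
}

## Mean residual amplitude inside a region-of-interest mask after
## de-shadowing (no output normalization, so residuals of the two
## methods are compared on a common amplitude scale).
.roiResidual <- function(vol, params, roi) {
  p <- params
  p@normalizeOutput <- FALSE
  mean(deshadowVolume(vol, p)@data[roi])
}

#' Match the step-down constant to a mean-subtraction weight
#'
#' Finds the step-down attenuation constant `gamma` whose mean residual
#' amplitude inside a tail-artifact region equals that of
#' mean-subtraction with weight `w` on the same volume — the two methods
#' are "matched to have nearly equal attenuation of tail artifacts" so
#' their side effects elsewhere can be compared fairly. The residual of
#' the step-down filter is strictly increasing in `gamma`, so the match
#' is found by bracketed 1-D root finding on `log10(gamma)`.
#'
#' @param vol an [OctaVolume-class].
#' @param w mean-subtraction weight to match against.
#' @param tailRoi logical (z, x, y) array marking tail-artifact voxels,
#'   e.g. the `tailMask` of a phantom's [PhantomTruth-class]; must
#'   contain signal in the original volume.
#' @param searchRange numeric(2) bracket for `gamma`. If the target
#'   residual is unreachable inside the bracket the nearer boundary is
#'   returned with a warning.
#' @param clipNegative passed to the mean-subtraction reference.
#' @return the matched `gamma` (inside `searchRange`).
#' @seealso [deshadowVolume()]
#' @export
matchGamma <- function(vol, w, tailRoi, searchRange = c(1e-2, 1e3),
                       clipNegative = TRUE) {
  stopifnot(is(vol, "OctaVolume"))
  if (!is.logical(tailRoi) || !identical(dim(tailRoi), dim(vol@data)))
    stop("tailRoi must be a logical array with the volume's dimensions",
         call. = FALSE)
  if (!any(tailRoi))
    stop("tailRoi is empty", call. = FALSE)
  if (mean(vol@data[tailRoi]) <= 0)
    stop("tailRoi has no signal in the original volume", call. = FALSE)
  if (length(searchRange) != 2L || any(searchRange <= 0) ||
      searchRange[1L] >= searchRange[2L])
    stop("searchRange must be positive and increasing", call. = FALSE)

  target <- .roiResidual(
    vol, deshadowParams("mean_subtraction", w = w,
                        clipNegative = clipNegative,
                        normalizeOutput = FALSE), tailRoi)
  resid <- function(g)
    .roiResidual(vol, deshadowParams("step_down", gamma = g,
                                     normalizeOutput = FALSE), tailRoi)

  hi <- resid(searchRange[2L])
  if (target >= hi) {
    warning(sprintf(
      "mean-subtraction residual (%.4g) not reachable by step-down in ",
      target), "the search range; returning the upper bound gamma")
    return(searchRange[2L])
  }
  lo <- resid(searchRange[1L])
  if (target <= lo) {
    warning(sprintf(
      "mean-subtraction residual (%.4g) below any step-down residual in ",
      target), "the search range; returning the lower bound gamma")
    return(searchRange[1L])
  }
  root <- stats::uniroot(function(lg) resid(10^lg) - target,
                         interval = log10(searchRange), tol = 1e-7)
  10^root$root
}

#' Volume-global histogram equalization
#'
#' Classical global histogram equalization of the voxel intensity
#' distribution: intensities are binned into `nBins` equal-width bins
#' over the observed range and mapped through the empirical CDF, giving
#' outputs in (0, 1] with the rank order of distinct intensity levels
#' preserved. An optional post-step after de-shadowing when capillaries
#' in poorly illuminated deep regions should be prominent.
#'
#' @param vol an [OctaVolume-class].
#' @param nBins number of histogram bins (default 256).
#' @return an equalized [OctaVolume-class]; a constant volume is
#'   returned unchanged with a warning.
#' @export
equalizeVolume <- function(vol, nBins = 256L) {
  stopifnot(is(vol, "OctaVolume"))
  nBins <- as.integer(nBins)
  if (nBins < 1L) stop("nBins must be a positive integer", call. = FALSE)
  v <- vol@data
  rng <- range(v)
  if (rng[1L] == rng[2L]) {
    warning("constant volume: histogram equalization is a no-op")
    return(vol)
  }
  breaks <- seq(rng[1L], rng[2L], length.out = nBins + 1L)
  bin <- findInterval(v, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  cdf <- cumsum(tabulate(bin, nbins = nBins)) / length(v)
  out <- array(cdf[bin], dim = dim(v))
  OctaVolume(out, vol@dzUm, vol@dxUm, vol@dyUm, vol@surfaceIndex)
}
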