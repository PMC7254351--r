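#' @import methods
NULL

## Central containers. Axis convention throughout: (z = depth, x = fast
## scan, y = slow scan), i.e. dim(data) == c(nz, nx, ny). Depth below the
## tissue surface (in micrometres) of 0-based depth index j is
## (j - surfaceIndex) * dzUm.

#' OctaVolume: a volumetric OCT angiography amplitude cube
#'
#' Holds a 3-D array of OCTA amplitudes in (z, x, y) axis order together
#' with the physical voxel pitch and the depth index of the tissue
#' surface. Amplitudes from acquisition or the phantom generator are
#' non-negative and on a linear scale; volumes produced by
#' [deshadowVolume()] with `clipNegative = FALSE` may carry signed
#' residuals, so the class itself only requires finite values.
#'
#' @slot data 3-D numeric array, axes (z, x, y), all values finite.
#' @slot dzUm,dxUm,dyUm voxel pitch per axis in micrometres (> 0).
#' @slot surfaceIndex 0-based depth index of the tissue surface; depth
#'   conversions and de-shadowing start here. Default 0 (cube cropped to
#'   the cortical surface).
#'
#' @examples
#' vol <- OctaVolume(array(runif(4 * 3 * 2), c(4, 3, 2)),
#'                   dzUm = 4, dxUm = 16, dyUm = 16)
#' dim(vol)
#' voxelPitch(vol)
#' @seealso [readVolume()], [generatePhantom()], [deshadowVolume()]
#' @export
setClass("OctaVolume",
  representation(
    data = "array",
    dzUm = "numeric",
    dxUm = "numeric",
    dyUm = "numeric",
    surfaceIndex = "integer"
  )
)

setValidity("OctaVolume", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L)
    return("data must be a 3-D array with axes (z, x, y)")
  bad <- !is.finite(d)
  if (any(bad)) {
    idx <- arrayInd(which(bad)[1L], dim(d))
    return(sprintf("non-finite voxel at (z=%d, x=%d, y=%d)",
                   idx[1L], idx[2L], idx[3L]))
  }
  for (p in c("dzUm", "dxUm", "dyUm")) {
    v <- slot(object, p)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      return(sprintf("%s must be a single positive number", p))
  }
  s <- object@surfaceIndex
  if (length(s) != 1L || is.na(s) || s < 0L || s >= dim(d)[1L])
    return("surfaceIndex must satisfy 0 <= surfaceIndex < nz")
  TRUE
})

#' @param data 3-D numeric array in (z, x, y) order.
#' @param dzUm,dxUm,dyUm voxel pitch in micrometres.
#' @param surfaceIndex 0-based depth index of the tissue surface.
#' @rdname OctaVolume-class
#' @export
OctaVolume <- function(data, dzUm, dxUm, dyUm, surfaceIndex = 0L) {
  new("OctaVolume", data = data, dzUm = as.numeric(dzUm),
      dxUm = as.numeric(dxUm), dyUm = as.numeric(dyUm),
      surfaceIndex = as.integer(surfaceIndex))
}

#' Angiogram: a 2-D en face image
#'
#' Result of projecting a depth slab of an [OctaVolume-class] onto the
#' (x, y) plane, typically by [maxAmplitudeProjection()]. Carries the
#' depth range it summarises (half-open, in micrometres below the
#' surface) and whether the pixel values are on a linear amplitude scale
#' or a display-mapped logarithmic (dB) scale.
#'
#' @slot data numeric matrix, axes (x, y), finite values.
#' @slot depthRangeUm numeric(2), half-open `[top, bottom)` in um below
#'   the tissue surface, `top < bottom`.
#' @slot scale `"linear"` or `"log"`.
#' @seealso [maxAmplitudeProjection()], [logScale()], [writeAngiogram()]
#' @export
setClass("Angiogram",
  representation(
    data = "matrix",
    depthRangeUm = "numeric",
    scale = "character"
  )
)

setValidity("Angiogram", function(object) {
  if (!is.numeric(object@data))
    return("data must be a numeric matrix")
  if (any(!is.finite(object@data)))
    return("angiogram pixels must all be finite")
  dr <- object@depthRangeUm
  if (length(dr) != 2L || !all(is.finite(dr)) || dr[1L] >= dr[2L])
    return("depthRangeUm must be c(top, bottom) with top < bottom")
  if (length(object@scale) != 1L ||
      !object@scale %in% c("linear", "log"))
    return("scale must be \"linear\" or \"log\"")
  TRUE
})

#' @param data numeric matrix, axes (x, y).
#' @param depthRangeUm numeric(2) half-open depth interval in um.
#' @param scale `"linear"` or `"log"`.
#' @rdname Angiogram-class
#' @export
Angiogram <- function(data, depthRangeUm, scale = "linear") {
  new("Angiogram", data = data, depthRangeUm = as.numeric(depthRangeUm),
      scale = scale)
}

#' DeshadowParams: tail-removal algorithm selection and tuning
#'
#' @slot method `"mean_subtraction"` (per-A-line mean subtraction, weight
#'   `w`) or `"step_down"` (step-down exponential filtering, attenuation
#'   constant `gamma`).
#' @slot w non-negative weight multiplying the A-line mean. The default
#'   2.0 is the weight at which capillary signal-to-noise is maximised.
#' @slot gamma positive attenuation constant of the step-down filter, in
#'   units of cumulative amplitude; see [matchGamma()].
#' @slot clipNegative set mean-subtraction results below zero to zero
#'   (default `TRUE`); OCTA magnitudes are non-negative.
#' @slot normalizeOutput divide the processed volume by its global
#'   maximum (a pure rescale, no contrast adjustment; default `TRUE`).
#' @slot equalize apply volume-global histogram equalization after
#'   de-shadowing to make poorly illuminated deep capillaries prominent
#'   (default `FALSE`).
#' @seealso [deshadowVolume()]
#' @export
setClass("DeshadowParams",
  representation(
    method = "character",
    w = "numeric",
    gamma = "numeric",
    clipNegative = "logical",
    normalizeOutput = "logical",
    equalize = "logical"
  )
)

setValidity("DeshadowParams", function(object) {
  if (length(object@method) != 1L ||
      !object@method %in% c("mean_subtraction", "step_down"))
    return("method must be \"mean_subtraction\" or \"step_down\"")
  if (object@method == "mean_subtraction" &&
      (length(object@w) != 1L || !is.finite(object@w) || object@w < 0))
    return("mean_subtraction requires a finite non-negative w")
  if (object@method == "step_down" &&
      (length(object@gamma) != 1L || !is.finite(object@gamma) ||
       object@gamma <= 0))
    return("step_down requires a finite positive gamma")
  for (p in c("clipNegative", "normalizeOutput", "equalize"))
    if (length(slot(object, p)) != 1L || is.na(slot(object, p)))
      return(sprintf("%s must be TRUE or FALSE", p))
  TRUE
})

#' @param method,w,gamma,clipNegative,normalizeOutput,equalize see slots.
#' @rdname DeshadowParams-class
#' @export
deshadowParams <- function(method = c("mean_subtraction", "step_down"),
                           w = 2.0, gamma = 10, clipNegative = TRUE,
                           normalizeOutput = TRUE, equalize = FALSE) {
  new("DeshadowParams", method = match.arg(method), w = as.numeric(w),
      gamma = as.numeric(gamma), clipNegative = clipNegative,
      normalizeOutput = normalizeOutput, equalize = equalize)
}

#' Slab: a contiguous depth range of a volume
#'
#' A half-open depth interval `[zTopUm, zBottomUm)` below the tissue
#' surface together with the 0-based voxel index interval it converts to
#' (`zTopIdx` inclusive, `zBottomIdx` exclusive). Construct with
#' [extractSlab()].
#'
#' @slot parent the [OctaVolume-class] the slab indexes into.
#' @slot zTopUm,zBottomUm depth bounds in um below the surface.
#' @slot zTopIdx,zBottomIdx derived 0-based half-open index interval.
#' @seealso [extractSlab()], [maxAmplitudeProjection()]
#' @export
setClass("Slab",
  representation(
    parent = "OctaVolume",
    zTopUm = "numeric",
    zBottomUm = "numeric",
    zTopIdx = "integer",
    zBottomIdx = "integer"
  )
)

setValidity("Slab", function(object) {
  if (object@zTopUm >= object@zBottomUm)
    return("zTopUm must be < zBottomUm")
  nz <- dim(object@parent@data)[1L]
  if (object@zTopIdx < 0L || object@zBottomIdx > nz ||
      object@zTopIdx >= object@zBottomIdx)
    return("slab index interval must be non-empty and inside [0, nz]")
  TRUE
})

#' PhantomSpec: parameterization of a synthetic OCTA volume
#'
#' Full description of a synthetic cerebral-vasculature phantom: cube
#' geometry, superficial vessels with tail artifacts beneath them,
#' depth-dependent signal attenuation, deep capillaries, and a speckle
#' noise floor. [generatePhantom()] turns it into an [OctaVolume-class]
#' plus ground-truth masks; [defaultCortexSpec()] builds a realistic
#' mouse-cortex default.
#'
#' @slot shape integer(3) extents (nz, nx, ny).
#' @slot dzUm,dxUm,dyUm voxel pitch in um.
#' @slot vessels data.frame with columns `x_um`, `y_um` (lateral centre),
#'   `radius_um`, `depth_um` (centre depth below surface), `amplitude`.
#'   Vessels are rendered as balls so their cross-section is circular.
#' @slot tailDecayUm exponential decay length of the tail artifact below
#'   each vessel, in um.
#' @slot tailStrength tail amplitude as a fraction (0..1) of the casting
#'   vessel's attenuated amplitude.
#' @slot capillaries data.frame with columns `x_um`, `y_um`, `z_um`,
#'   `radius_um`, `amplitude`; rendered as small spheres (never smaller
#'   than one voxel).
#' @slot attenuationLengthUm 1/e depth of the signal attenuation
#'   multiplier applied to vessels and capillaries.
#' @slot noiseDistribution `"rayleigh"` (amplitude speckle) or
#'   `"gaussian_folded"`.
#' @slot noiseScale scale parameter of the noise floor (0 disables it).
#' @slot seed integer seed; generation is deterministic given the spec.
#' @seealso [generatePhantom()], [defaultCortexSpec()]
#' @export
setClass("PhantomSpec",
  representation(
    shape = "integer",
    dzUm = "numeric",
    dxUm = "numeric",
    dyUm = "numeric",
    vessels = "data.frame",
    tailDecayUm = "numeric",
    tailStrength = "numeric",
    capillaries = "data.frame",
    attenuationLengthUm = "numeric",
    noiseDistribution = "character",
    noiseScale = "numeric",
    seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  if (length(object@shape) != 3L || any(object@shape < 1L))
    return("shape must be positive integer (nz, nx, ny)")
  ext <- c(object@shape[2L] * object@dxUm, object@shape[3L] * object@dyUm)
  zExt <- object@shape[1L] * object@dzUm
  v <- object@vessels
  need <- c("x_um", "y_um", "radius_um", "depth_um", "amplitude")
  if (nrow(v) > 0) {
    if (!all(need %in% names(v)))
      return(paste("vessels needs columns", paste(need, collapse = ", ")))
    if (any(v$amplitude <= 0) || any(v$radius_um <= 0))
      return("vessel amplitudes and radii must be positive")
    inside <- v$x_um >= v$radius_um & v$x_um <= ext[1L] - v$radius_um &
      v$y_um >= v$radius_um & v$y_um <= ext[2L] - v$radius_um &
      v$depth_um >= 0 & v$depth_um < zExt
    if (!all(inside))
      return("every vessel must lie laterally inside the volume")
  }
  cp <- object@capillaries
  needc <- c("x_um", "y_um", "z_um", "radius_um", "amplitude")
  if (nrow(cp) > 0) {
    if (!all(needc %in% names(cp)))
      return(paste("capillaries needs columns",
                   paste(needc, collapse = ", ")))
    if (any(cp$amplitude <= 0) || any(cp$radius_um <= 0))
      return("capillary amplitudes and radii must be positive")
    inside <- cp$x_um >= 0 & cp$x_um <= ext[1L] & cp$y_um >= 0 &
      cp$y_um <= ext[2L] & cp$z_um >= 0 & cp$z_um < zExt
    if (!all(inside))
      return("every capillary centre must lie inside the volume")
  }
  if (object@tailStrength < 0 || object@tailStrength > 1)
    return("tailStrength must be in [0, 1]")
  if (object@tailDecayUm <= 0 || object@attenuationLengthUm <= 0)
    return("tailDecayUm and attenuationLengthUm must be positive")
  if (!object@noiseDistribution %in% c("rayleigh", "gaussian_folded"))
    return("noiseDistribution must be \"rayleigh\" or \"gaussian_folded\"")
  if (object@noiseScale < 0)
    return("noiseScale must be >= 0")
  TRUE
})

#' @param shape,dzUm,dxUm,dyUm,vessels,tailDecayUm,tailStrength,capillaries,attenuationLengthUm,noiseDistribution,noiseScale,seed see slots.
#' @rdname PhantomSpec-class
#' @export
phantomSpec <- function(shape, dzUm, dxUm, dyUm,
                        vessels = data.frame(), tailDecayUm = 300,
                        tailStrength = 0.5, capillaries = data.frame(),
                        attenuationLengthUm = 700,
                        noiseDistribution = c("rayleigh", "gaussian_folded"),
                        noiseScale = 0.02, seed = 1L) {
  new("PhantomSpec", shape = as.integer(shape), dzUm = as.numeric(dzUm),
      dxUm = as.numeric(dxUm), dyUm = as.numeric(dyUm), vessels = vessels,
      tailDecayUm = as.numeric(tailDecayUm),
      tailStrength = as.numeric(tailStrength), capillaries = capillaries,
      attenuationLengthUm = as.numeric(attenuationLengthUm),
      noiseDistribution = match.arg(noiseDistribution),
      noiseScale = as.numeric(noiseScale), seed = as.integer(seed))
}

#' PhantomTruth: ground-truth masks of a generated phantom
#'
#' Mutually disjoint boolean masks recorded before noise addition:
#' voxels belonging to superficial vessels, to capillaries (capillaries
#' win where structures overlap), and tail voxels whose signal is purely
#' artifact. Every tail voxel lies strictly below some vessel voxel of
#' the same (x, y) column.
#'
#' @slot vesselMask,capillaryMask,tailMask 3-D logical arrays, (z, x, y).
#' @seealso [generatePhantom()]
#' @export
setClass("PhantomTruth",
  representation(
    vesselMask = "array",
    capillaryMask = "array",
    tailMask = "array"
  )
)

setValidity("PhantomTruth", function(object) {
  dims <- lapply(c("vesselMask", "capillaryMask", "tailMask"),
                 function(s) dim(slot(object, s)))
  if (!all(vapply(dims, function(d) identical(d, dims[[1L]]), logical(1))))
    return("masks must share one (z, x, y) shape")
  if (any(object@vesselMask & object@capillaryMask) ||
      any(object@vesselMask & object@tailMask) ||
      any(object@capillaryMask & object@tailMask))
    return("masks must be mutually disjoint")
  TRUE
})

PhantomTruth <- function(vesselMask, capillaryMask, tailMask) {
  new("PhantomTruth", vesselMask = vesselMask,
      capillaryMask = capillaryMask, tailMask = tailMask)
}

#' RunConfig: one reproducible processing run
#'
#' Bundles the input source (a volume on disk or a seeded phantom), the
#' de-shadowing parameters, the en face slab ranges, an optional weight
#' sweep grid and the output directory, for the [cmdDeshadow()] /
#' [cmdSweepW()] / [cmdCompare()] entry points.
#'
#' @slot input character(0) or path to a stored volume.
#' @slot phantomSeed integer(0) or seed for [defaultCortexSpec()].
#'   Exactly one of `input` / `phantomSeed` must be present.
#' @slot params a [DeshadowParams-class].
#' @slot slabs list of numeric(2) depth ranges in um (half-open).
#' @slot wGrid optional strictly increasing non-negative weights.
#' @slot outDir output directory (created if missing).
#' @slot logLevel `"info"` or `"quiet"`.
#' @seealso [runConfig()]
#' @export
setClass("RunConfig",
  representation(
    input = "character",
    phantomSeed = "integer",
    params = "DeshadowParams",
    slabs = "list",
    wGrid = "numeric",
    outDir = "character",
    logLevel = "character"
  )
)

setValidity("RunConfig", function(object) {
  if (length(object@input) + length(object@phantomSeed) != 1L)
    return("exactly one of input / phantomSeed must be given")
  for (s in object@slabs) {
    if (length(s) != 2L || !all(is.finite(s)) || s[1L] >= s[2L])
      return("each slab must be c(top_um, bottom_um) with top < bottom")
  }
  g <- object@wGrid
  if (length(g)) {
    if (any(g < 0) || any(diff(g) <= 0))
      return("wGrid must be non-negative and strictly increasing")
  }
  if (length(object@outDir) != 1L)
    return("outDir must be a single path")
  if (!object@logLevel %in% c("info", "quiet"))
    return("logLevel must be \"info\" or \"quiet\"")
  TRUE
})

#' Build a RunConfig
#'
#' @param input path to a stored volume (TIFF or raw + sidecar), or NULL.
#' @param phantomSeed seed for the built-in phantom, or NULL.
#' @param params a [DeshadowParams-class].
#' @param slabs list of `c(top_um, bottom_um)` en face depth ranges.
#' @param wGrid optional weight grid for [cmdSweepW()].
#' @param outDir output directory.
#' @param logLevel `"info"` or `"quiet"`.
#' @return a validated [RunConfig-class].
#' @export
runConfig <- function(input = NULL, phantomSeed = NULL,
                      params = deshadowParams(),
                      slabs = list(c(400, 420), c(440, 460), c(480, 500)),
                      wGrid = NULL, outDir = tempfile("octads-run-"),
                      logLevel = "info") {
  new("RunConfig",
      input = if (is.null(input)) character(0) else as.character(input),
      phantomSeed = if (is.null(phantomSeed)) integer(0)
                    else as.integer(phantomSeed),
      params = params, slabs = slabs,
      wGrid = if (is.null(wGrid)) numeric(0) else as.numeric(wGrid),
      outDir = outDir, logLevel = logLevel)
}
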