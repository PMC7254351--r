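#' Accessors for octads classes
#'
#' `volData()` returns the raw (z, x, y) array of a volume, `angioData()`
#' the (x, y) matrix of an angiogram, `voxelPitch()` the named pitch
#' vector in micrometres, `surfaceIndex()` the 0-based surface depth
#' index, `depthRange()` an angiogram's or slab's depth interval in um,
#' and `intensityScale()` whether angiogram pixels are linear or log.
#'
#' @param x an [OctaVolume-class], [Angiogram-class] or [Slab-class].
#' @return see the individual descriptions.
#' @name accessors
#' @examples
#' vol <- OctaVolume(array(1, c(4, 2, 2)), 4, 16, 16)
#' voxelPitch(vol)
NULL

#' @rdname accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @rdname accessors
#' @export
setGeneric("angioData", function(x) standardGeneric("angioData"))
#' @rdname accessors
#' @export
setGeneric("voxelPitch", function(x) standardGeneric("voxelPitch"))
#' @rdname accessors
#' @export
setGeneric("surfaceIndex", function(x) standardGeneric("surfaceIndex"))
#' @rdname accessors
#' @export
setGeneric("depthRange", function(x) standardGeneric("depthRange"))
#' @rdname accessors
#' @export
setGeneric("intensityScale", function(x) standardGeneric("intensityScale"))

#' @rdname accessors
#' @export
setMethod("volData", "OctaVolume", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("angioData", "Angiogram", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("voxelPitch", "OctaVolume", function(x)
  c(dz_um = x@dzUm, dx_um = x@dxUm, dy_um = x@dyUm))

#' @rdname accessors
#' @export
setMethod("surfaceIndex", "OctaVolume", function(x) x@surfaceIndex)

#' @rdname accessors
#' @export
setMethod("depthRange", "Angiogram", function(x) x@depthRangeUm)

#' @rdname accessors
#' @export
setMethod("depthRange", "Slab", function(x) c(x@zTopUm, x@zBottomUm))

#' @rdname accessors
#' @export
setMethod("intensityScale", "Angiogram", function(x) x@scale)

#' @param x an OctaVolume
#' @rdname OctaVolume-class
#' @export
setMethod("dim", "OctaVolume", function(x) dim(x@data))

#' @rdname Angiogram-class
#' @export
setMethod("dim", "Angiogram", function(x) dim(x@data))

setMethod("show", "OctaVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("OctaVolume: %d x %d x %d (z-x-y) voxels\n",
              d[1L], d[2L], d[3L]))
  cat(sprintf("  pitch (um): dz=%g dx=%g dy=%g | surface index %d\n",
              object@dzUm, object@dxUm, object@dyUm,
              object@surfaceIndex))
  cat(sprintf("  amplitude range: [%g, %g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "Angiogram", function(object) {
  d <- dim(object@data)
  cat(sprintf("Angiogram: %d x %d (x-y), %s scale, depth [%g, %g) um\n",
              d[1L], d[2L], object@scale, object@depthRangeUm[1L],
              object@depthRangeUm[2L]))
})

setMethod("show", "Slab", function(object) {
  cat(sprintf("Slab: depth [%g, %g) um -> z indices [%d, %d) of %d\n",
              object@zTopUm, object@zBottomUm, object@zTopIdx,
              object@zBottomIdx, dim(object@parent@data)[1L]))
})

setMethod("show", "DeshadowParams", function(object) {
  cat(sprintf("DeshadowParams: %s (%s)\n", object@method,
              if (object@method == "mean_subtraction")
                sprintf("w = %g", object@w)
              else sprintf("gamma = %g", object@gamma)))
  cat(sprintf("  clipNegative=%s normalizeOutput=%s equalize=%s\n",
              object@clipNegative, object@normalizeOutput,
              object@equalize))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %d x %d x %d voxels, %d vessels, %d capillaries, seed %d\n",
    object@shape[1L], object@shape[2L], object@shape[3L],
    nrow(object@vessels), nrow(object@capillaries), object@seed))
})
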