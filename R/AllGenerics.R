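#' Accessors for image and volume containers
#'
#' `pixels()` returns the raster matrix of a [SEMImage-class] or
#' [BinaryImage-class]; `pixelSize()` its physical pixel size (um/pixel).
#' `labels()` returns the 3D label array of a [LabelVolume-class],
#' `voxelSize()` its per-axis spacing and `boxVolume()` the physical volume
#' of the grid in cubic micrometres. `clPoints()` and `arcLength()` access a
#' [Centerline-class]; `tubes()` and `achievedStats()` an [AxonRVE-class].
#'
#' @param x the object.
#' @return the corresponding slot or derived value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("labels3d", function(x) standardGeneric("labels3d"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("boxVolume", function(x) standardGeneric("boxVolume"))
#' @rdname accessors
#' @export
setGeneric("clPoints", function(x) standardGeneric("clPoints"))
#' @rdname accessors
#' @export
setGeneric("arcLength", function(x) standardGeneric("arcLength"))
#' @rdname accessors
#' @export
setGeneric("tubes", function(x) standardGeneric("tubes"))
#' @rdname accessors
#' @export
setGeneric("achievedStats", function(x) standardGeneric("achievedStats"))

#' @rdname accessors
setMethod("pixels", "SEMImage", function(x) x@pixels)
#' @rdname accessors
setMethod("pixels", "BinaryImage", function(x) x@pixels)
#' @rdname accessors
setMethod("pixelSize", "SEMImage", function(x) x@pixelSize)
#' @rdname accessors
setMethod("pixelSize", "BinaryImage", function(x) x@pixelSize)
#' @rdname accessors
setMethod("labels3d", "LabelVolume", function(x) x@labels)
#' @rdname accessors
setMethod("voxelSize", "LabelVolume", function(x) x@voxelSize)
#' @rdname accessors
setMethod("boxVolume", "LabelVolume",
          function(x) prod(dim(x@labels) * x@voxelSize))
#' @rdname accessors
setMethod("clPoints", "Centerline", function(x) x@points)
#' @rdname accessors
setMethod("arcLength", "Centerline", function(x) {
  p <- x@points
  sum(sqrt(rowSums((p[-1L, , drop = FALSE] -
                    p[-nrow(p), , drop = FALSE])^2)))
})
#' @rdname accessors
setMethod("tubes", "AxonRVE", function(x) x@tubes)
#' @rdname accessors
setMethod("achievedStats", "AxonRVE", function(x) x@achievedStats)

setMethod("show", "SEMImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("SEMImage: %d x %d px, %.4g um/px (%.1f x %.1f um)\n",
              d[1], d[2], object@pixelSize,
              d[1] * object@pixelSize, d[2] * object@pixelSize))
  cat(sprintf("  intensity range [%.4f, %.4f]\n",
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "BinaryImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("BinaryImage: %d x %d px, %.4g um/px, white fraction %.4f\n",
              d[1], d[2], object@pixelSize, mean(object@pixels)))
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@labels)
  nl <- length(setdiff(unique(as.vector(object@labels)), 0L))
  cat(sprintf(
    "LabelVolume: %d x %d x %d voxels @ (%.3g, %.3g, %.3g) um, %d axon(s)\n",
    d[1], d[2], d[3], object@voxelSize[1], object@voxelSize[2],
    object@voxelSize[3], nl))
})

setMethod("show", "Centerline", function(object) {
  cat(sprintf("Centerline: %d points, arc length %.4f um\n",
              nrow(object@points), arcLength(object)))
})

setMethod("show", "LognormalFit", function(object) {
  cat(sprintf(
    "LognormalFit (n = %d): mu = %.4f, sigma = %.4f\n", object@n,
    object@mu, object@sigma))
  cat(sprintf("  mode %.4f | median %.4f | arith mean %.4f | arith sd %.4f\n",
              object@mode, object@median, object@arithMean, object@arithSd))
})

setMethod("show", "TractStats", function(object) {
  cat(sprintf("TractStats [%s]\n", object@tract))
  cat(sprintf("  area lognormal: mu %.4f sigma %.4f (mode %.3f, median %.3f um^2)\n",
              object@areaMu, object@areaSigma,
              exp(object@areaMu - object@areaSigma^2), exp(object@areaMu)))
  cat(sprintf("  diameter lognormal: mu %.4f sigma %.4f\n",
              object@diameterMu, object@diameterSigma))
  cat(sprintf("  ellipticity [%.2f, %.2f]; tortuosity %.3f +/- %.3f\n",
              object@ellipticityMin, object@ellipticityMax,
              object@tortuosityMean, object@tortuositySd))
  cat(sprintf("  density %.3g axons/mm^3; volume fraction %.3f +/- %.3f\n",
              object@axonalDensity, object@volumeFraction,
              object@volumeFractionSd))
})

setMethod("show", "AxonRVE", function(object) {
  cat(sprintf(
    "AxonRVE: %d axon tubes in %.1f x %.1f x %.1f um box (seed %d)\n",
    length(object@tubes), object@box[1], object@box[2], object@box[3],
    object@seed))
  cat(sprintf("  achieved volume fraction %.3f, mean tortuosity %.3f\n",
              object@achievedStats@volumeFraction,
              object@achievedStats@tortuosityMean))
})
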