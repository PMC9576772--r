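#' @import methods
NULL

#' SEMImage: a 2D greyscale electron-microscopy image
#'
#' A rectangular 16-bit-range greyscale raster with a physical pixel size,
#' the input unit of the 2D myelin-content pipeline. Pixel values are stored
#' as doubles on \[0, 1\] (1 corresponds to the top of the 16-bit dynamic
#' range); integer 16-bit data are rescaled on construction.
#'
#' @slot pixels numeric matrix of intensities on \[0, 1\].
#' @slot pixelSize physical pixel size in micrometres per pixel.
#' @export
setClass("SEMImage",
  representation(pixels = "matrix", pixelSize = "numeric"),
  validity = function(object) {
    if (!is.numeric(object@pixels)) return("pixels must be numeric")
    if (nrow(object@pixels) < 1L || ncol(object@pixels) < 1L)
      return("image must be non-empty")
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
      return("pixelSize must be a single positive number")
    TRUE
  }
)

#' BinaryImage: a binarised 2D raster
#'
#' Boolean raster produced by the adaptive binarisation stage; same shape as
#' the source image.
#'
#' @slot pixels logical matrix.
#' @slot pixelSize physical pixel size in micrometres per pixel.
#' @export
setClass("BinaryImage",
  representation(pixels = "matrix", pixelSize = "numeric"),
  validity = function(object) {
    if (!is.logical(object@pixels)) return("pixels must be logical")
    if (nrow(object@pixels) < 1L || ncol(object@pixels) < 1L)
      return("image must be non-empty")
    if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
      return("pixelSize must be a single positive number")
    TRUE
  }
)

#' LabelVolume: a 3D integer-labelled voxel grid
#'
#' One label per axon (k > 0), 0 for the extra-cellular matrix. Voxel
#' spacing may be anisotropic (FIB-SEM stacks have fine in-plane pixels and
#' coarse slice spacing). `origin` is the physical coordinate (micrometres)
#' of the corner of voxel (1,1,1), so sub-volumes keep their position in the
#' parent frame.
#'
#' @slot labels 3D integer array, dimensions (x, y, z).
#' @slot voxelSize numeric length-3, micrometres per voxel along (x, y, z).
#' @slot origin numeric length-3, physical position of the grid corner (um).
#' @export
setClass("LabelVolume",
  representation(labels = "array", voxelSize = "numeric", origin = "numeric"),
  prototype(origin = c(0, 0, 0)),
  validity = function(object) {
    if (length(dim(object@labels)) != 3L) return("labels must be a 3D array")
    if (any(object@labels < 0)) return("labels must be non-negative")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      return("voxelSize must be three positive numbers (x, y, z)")
    if (length(object@origin) != 3L) return("origin must have length 3")
    TRUE
  }
)

#' Centerline: an axon's fitted centre path
#'
#' Ordered polyline in physical micrometre coordinates; the measuring plane
#' at any station is perpendicular to this path.
#'
#' @slot points numeric matrix (n x 3) of (x, y, z) in micrometres, n >= 2.
#' @export
setClass("Centerline",
  representation(points = "matrix"),
  validity = function(object) {
    p <- object@points
    if (!is.numeric(p) || ncol(p) != 3L) return("points must be an n x 3 matrix")
    if (nrow(p) < 2L) return("a centerline needs at least 2 points")
    if (any(!is.finite(p))) return("points must be finite")
    TRUE
  }
)

#' LognormalFit: maximum-likelihood lognormal fit of a morphometric sample
#'
#' Holds the log-scale parameters and the derived descriptive values used
#' for tract characterisation: mode \eqn{v_0 = e^{\mu - \sigma^2}}, median
#' \eqn{\tilde x = e^{\mu}}, arithmetic mean \eqn{e^{\mu + \sigma^2/2}} and
#' arithmetic SD \eqn{mean \cdot \sqrt{e^{\sigma^2} - 1}}.
#'
#' @slot mu log-scale location.
#' @slot sigma log-scale scale, > 0.
#' @slot n sample count.
#' @slot mode,median,arithMean,arithSd derived descriptive values (data units).
#' @export
setClass("LognormalFit",
  representation(mu = "numeric", sigma = "numeric", n = "integer",
                 mode = "numeric", median = "numeric",
                 arithMean = "numeric", arithSd = "numeric"),
  validity = function(object) {
    if (object@sigma <= 0) return("sigma must be > 0")
    if (object@n < 2L) return("n must be >= 2")
    ok <- all.equal(object@mode, exp(object@mu - object@sigma^2)) == TRUE &&
      all.equal(object@median, exp(object@mu)) == TRUE &&
      all.equal(object@arithMean, exp(object@mu + object@sigma^2 / 2)) == TRUE
    if (!isTRUE(ok)) return("derived fields inconsistent with (mu, sigma)")
    TRUE
  }
)

#' TractStats: tract-level summary statistics of a white-matter fibre tract
#'
#' The parameter set that characterises one tract (corpus callosum, corona
#' radiata or fornix) and drives the in silico volume generator: lognormal
#' parameters of cross-sectional area and best-fit diameter, the ellipticity
#' range, mean and SD of tortuosity, axonal density, volume fraction with its
#' SD, and the interlayer (slice-to-slice) variability terms.
#'
#' @slot tract tract code, one of "CC", "CR", "FO" (or a free label).
#' @slot areaMu,areaSigma lognormal parameters of cross-sectional area
#'   (log um^2 scale).
#' @slot diameterMu,diameterSigma lognormal parameters of best-fit diameter
#'   (log um scale).
#' @slot ellipticityMin,ellipticityMax range of ellipticity E = a/b - 1.
#' @slot tortuosityMean,tortuositySd per-axon tortuosity statistics.
#' @slot axonalDensity axons per cubic millimetre.
#' @slot volumeFraction,volumeFractionSd axonal volume fraction and SD.
#' @slot interlayerAreaCv coefficient of variation of the per-station area
#'   about the axon mean.
#' @slot interlayerSemiaxisDelta maximum slice-to-slice change of the major
#'   semi-axis, micrometres.
#' @export
setClass("TractStats",
  representation(tract = "character",
                 areaMu = "numeric", areaSigma = "numeric",
                 diameterMu = "numeric", diameterSigma = "numeric",
                 ellipticityMin = "numeric", ellipticityMax = "numeric",
                 tortuosityMean = "numeric", tortuositySd = "numeric",
                 axonalDensity = "numeric",
                 volumeFraction = "numeric", volumeFractionSd = "numeric",
                 interlayerAreaCv = "numeric",
                 interlayerSemiaxisDelta = "numeric"),
  validity = function(object) {
    if (object@areaSigma <= 0 || object@diameterSigma <= 0)
      return("lognormal sigmas must be > 0")
    if (object@volumeFraction <= 0 || object@volumeFraction >= 1)
      return("volumeFraction must lie in (0, 1)")
    if (object@axonalDensity <= 0) return("axonalDensity must be > 0")
    if (object@ellipticityMin < 0 ||
        object@ellipticityMax < object@ellipticityMin)
      return("ellipticity range invalid")
    if (object@tortuosityMean < 0 || object@tortuosityMean >= 1)
      return("tortuosityMean must lie in [0, 1)")
    TRUE
  }
)

#' AxonRVE: a periodic in silico volume of non-overlapping axon tubes
#'
#' A box (micrometres) filled with tubular axons of elliptical, per-station
#' cross-section, periodic in x-y, all spanning the full z extent. Each tube
#' is a list with per-station geometry (see [generateRVE()]).
#'
#' @slot tubes list of axon tubes; each holds station centres, perpendicular
#'   semi-axes, in-plane orientation and tangents.
#' @slot box numeric length-3 box edge lengths (um).
#' @slot periodicXY logical, always TRUE for generated volumes.
#' @slot achievedStats [TractStats-class] realised by the generated volume.
#' @slot stationSpacing station spacing along z (um).
#' @slot minGap minimum inter-surface clearance (um).
#' @slot seed integer seed the volume was generated from.
#' @export
setClass("AxonRVE",
  representation(tubes = "list", box = "numeric", periodicXY = "logical",
                 achievedStats = "TractStats", stationSpacing = "numeric",
                 minGap = "numeric", seed = "integer"),
  validity = function(object) {
    if (length(object@box) != 3L || any(object@box <= 0))
      return("box must be three positive lengths")
    if (length(object@tubes) < 1L) return("an RVE holds at least one tube")
    TRUE
  }
)
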