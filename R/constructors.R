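#' Construct a SEMImage
#'
#' Wraps a greyscale matrix as a [SEMImage-class]. Integer-valued input on a
#' 16-bit (or 8-bit) range is rescaled to \[0, 1\]; doubles already on
#' \[0, 1\] are taken as-is.
#'
#' @param pixels numeric matrix. Either intensities on \[0, 1\] or integer
#'   counts on \[0, 255\] / \[0, 65535\].
#' @param pixelSize physical pixel size, micrometres per pixel.
#' @return a [SEMImage-class].
#' @examples
#' img <- SEMImage(matrix(runif(64), 8, 8), pixelSize = 0.02)
#' pixelSize(img)
#' @export
SEMImage <- function(pixels, pixelSize = 0.020) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  mx <- suppressWarnings(max(pixels))
  if (is.finite(mx) && mx > 1) {
    bits <- if (mx > 255) 65535 else 255
    pixels <- pixels / bits
  }
  new("SEMImage", pixels = pmin(pmax(pixels, 0), 1),
      pixelSize = as.numeric(pixelSize))
}

#' Construct a BinaryImage
#'
#' @param pixels logical matrix (or 0/1 numeric, coerced).
#' @param pixelSize physical pixel size, micrometres per pixel.
#' @return a [BinaryImage-class].
#' @export
BinaryImage <- function(pixels, pixelSize = 0.020) {
  if (!is.logical(pixels)) {
    stopifnot(all(pixels %in% c(0, 1)))
    storage.mode(pixels) <- "logical"
  }
  new("BinaryImage", pixels = pixels, pixelSize = as.numeric(pixelSize))
}

#' Construct a LabelVolume
#'
#' @param labels 3D integer array (x, y, z); 0 is background (extra-cellular
#'   matrix), positive integers label individual axons.
#' @param voxelSize numeric length-3 spacing (um) along (x, y, z);
#'   anisotropy (coarser z) is the FIB-SEM norm.
#' @param origin physical coordinate of the corner of voxel (1,1,1), um.
#' @return a [LabelVolume-class].
#' @export
LabelVolume <- function(labels, voxelSize = c(0.020, 0.020, 0.150),
                        origin = c(0, 0, 0)) {
  storage.mode(labels) <- "integer"
  new("LabelVolume", labels = labels, voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin))
}

#' Construct a Centerline
#'
#' @param points n x 3 numeric matrix of (x, y, z) in micrometres, ordered
#'   along the axon.
#' @return a [Centerline-class].
#' @export
Centerline <- function(points) {
  new("Centerline", points = as.matrix(points))
}

#' Tract-level statistics container
#'
#' Builds a [TractStats-class] from its component statistics. Lognormal
#' parameters can be supplied directly (`areaMu`/`areaSigma`, ...) or derived
#' from printed mode/median pairs with [modeMedianToParams()].
#'
#' @param tract tract label ("CC", "CR", "FO", or free text).
#' @param areaMu,areaSigma lognormal parameters of cross-sectional area.
#' @param diameterMu,diameterSigma lognormal parameters of best-fit diameter.
#' @param ellipticityMin,ellipticityMax ellipticity range (E = a/b - 1).
#' @param tortuosityMean,tortuositySd per-axon tortuosity mean and SD.
#' @param axonalDensity axons per cubic millimetre.
#' @param volumeFraction,volumeFractionSd axonal volume fraction and its SD.
#' @param interlayerAreaCv slice-to-slice coefficient of variation of area.
#' @param interlayerSemiaxisDelta max slice-to-slice semi-axis change (um).
#' @return a [TractStats-class].
#' @seealso [tractPreset()] for the bundled CC/CR/FO parameter sets.
#' @export
TractStats <- function(tract, areaMu, areaSigma, diameterMu, diameterSigma,
                       ellipticityMin, ellipticityMax,
                       tortuosityMean, tortuositySd,
                       axonalDensity, volumeFraction, volumeFractionSd,
                       interlayerAreaCv = 0.10,
                       interlayerSemiaxisDelta = 0.05) {
  new("TractStats", tract = tract,
      areaMu = areaMu, areaSigma = areaSigma,
      diameterMu = diameterMu, diameterSigma = diameterSigma,
      ellipticityMin = ellipticityMin, ellipticityMax = ellipticityMax,
      tortuosityMean = tortuosityMean, tortuositySd = tortuositySd,
      axonalDensity = axonalDensity,
      volumeFraction = volumeFraction, volumeFractionSd = volumeFractionSd,
      interlayerAreaCv = interlayerAreaCv,
      interlayerSemiaxisDelta = interlayerSemiaxisDelta)
}
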