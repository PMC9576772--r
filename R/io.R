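#' Read a TIFF image or image stack
#'
#' Reads single- or multi-page greyscale TIFF. The physical pixel size is
#' taken from a JSON sidecar (`<file>.json` with a `pixel_size` field) or
#' from the `pixelSize` argument; without either, reading fails so that no
#' measurement silently runs on unknown scale. RGB input is rejected.
#'
#' @param path TIFF file.
#' @param pixelSize um per pixel; overrides the sidecar.
#' @return a [SEMImage-class], or a list of them for multi-page files.
#' @export
readImageStack <- function(path, pixelSize = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.null(pixelSize)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      pixelSize <- meta$pixel_size
    }
  }
  if (is.null(pixelSize))
    stop("no pixel size: provide `pixelSize` or a JSON sidecar with a ",
         "`pixel_size` field")
  toImg <- function(m) {
    if (length(dim(m)) == 3L)
      stop("RGB/multi-channel TIFF not supported; greyscale expected")
    # tiff returns row-major (y, x); transpose to our (x, y) convention
    SEMImage(t(m), pixelSize = pixelSize)
  }
  imgs <- lapply(pages, toImg)
  if (length(imgs) == 1L) imgs[[1L]] else imgs
}

#' Write an image (or image list) to 16-bit TIFF with a JSON sidecar
#'
#' @param img a [SEMImage-class] or list of them (multi-page output).
#' @param path output TIFF file.
#' @return invisibly, `path`.
#' @export
writeImageStack <- function(img, path) {
  if (is(img, "SEMImage")) img <- list(img)
  stopifnot(all(vapply(img, is, TRUE, "SEMImage")))
  pages <- lapply(img, function(im) t(im@pixels))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(pixel_size = img[[1L]]@pixelSize),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a labelled volume from multi-page TIFF plus JSON sidecar
#'
#' The sidecar (`<file>.json`) must hold `voxel_size` (3 numbers, um); it
#' may also carry an `origin`. Alternatively pass `voxelSize` explicitly.
#'
#' @param path multi-page TIFF of integer labels (one page per slice).
#' @param voxelSize spacing (um) along (x, y, z); overrides the sidecar.
#' @return a [LabelVolume-class].
#' @export
readLabelVolume <- function(path, voxelSize = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  origin <- c(0, 0, 0)
  if (is.null(voxelSize)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
      voxelSize <- meta$voxel_size
      if (!is.null(meta$origin)) origin <- meta$origin
    }
  }
  if (is.null(voxelSize))
    stop("no voxel spacing: provide `voxelSize` or a JSON sidecar with a ",
         "`voxel_size` field")
  if (any(vapply(pages, function(m) length(dim(m)) == 3L, TRUE)))
    stop("RGB/multi-channel TIFF cannot be a label volume")
  slices <- lapply(pages, t)
  lab <- array(0L, c(dim(slices[[1L]]), length(slices)))
  for (k in seq_along(slices)) lab[, , k] <- as.integer(slices[[k]])
  LabelVolume(lab, voxelSize = as.numeric(voxelSize), origin = origin)
}

#' Write a labelled volume to multi-page TIFF plus JSON sidecar
#'
#' Labels are stored as 16-bit integer pages; spacing, origin and
#' (optionally) per-axon ground truth go to `<file>.json`.
#'
#' @param vol a [LabelVolume-class].
#' @param path output TIFF file.
#' @param truth optional ground-truth list stored in the sidecar.
#' @return invisibly, `path`.
#' @export
writeLabelVolume <- function(vol, path, truth = NULL) {
  stopifnot(is(vol, "LabelVolume"))
  mx <- max(vol@labels)
  if (mx > 65535L) stop("more than 65535 labels; 16-bit TIFF overflow")
  pages <- lapply(seq_len(dim(vol@labels)[3L]), function(k)
    t(vol@labels[, , k]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(voxel_size = vol@voxelSize, origin = vol@origin)
  if (!is.null(truth)) meta$truth <- truth
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write per-station and per-axon measurement tables
#'
#' CSV with header, full double precision, deterministic row order
#' (axon id, then station arc length); fits as JSON.
#'
#' @param measurement output of [measureVolume()] (or a compatible list
#'   with `axons` and `stations` data frames).
#' @param dir output directory.
#' @param fits optional named list of [LognormalFit-class] objects
#'   serialised to `fits.json`.
#' @return invisibly, the written file paths.
#' @export
writeTables <- function(measurement, dir, fits = NULL) {
  stopifnot(is.list(measurement),
            is.data.frame(measurement$axons),
            nrow(measurement$axons) >= 1L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ax <- measurement$axons[order(measurement$axons$axon_id), , drop = FALSE]
  st <- measurement$stations[order(measurement$stations$axon_id,
                                   measurement$stations$station_arclength),
                             , drop = FALSE]
  fmt <- function(df) {
    for (cn in names(df))
      if (is.numeric(df[[cn]])) df[[cn]] <- sprintf("%.17g", df[[cn]])
    df
  }
  axPath <- file.path(dir, "axons.csv")
  stPath <- file.path(dir, "stations.csv")
  utils::write.csv(fmt(ax), axPath, row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt(st), stPath, row.names = FALSE, quote = FALSE)
  out <- c(axPath, stPath)
  if (!is.null(fits)) {
    fj <- lapply(fits, function(f) list(
      mu = f@mu, sigma = f@sigma, n = f@n, mode = f@mode,
      median = f@median, arith_mean = f@arithMean, arith_sd = f@arithSd))
    fitPath <- file.path(dir, "fits.json")
    jsonlite::write_json(fj, fitPath, auto_unbox = TRUE, digits = NA)
    out <- c(out, fitPath)
  }
  invisible(out)
}

#' Run the full in silico workflow
#'
#' Stage `"all"` chains phantom-volume generation, morphometry,
#' lognormal fitting, in silico volume generation and round-trip
#' validation for one tract, writing tables, STL meshes and a summary
#' JSON that (together with the config) reproduces every output
#' bit-identically. Individual stages are available through the package
#' functions directly; this wrapper is what the command-line entry point
#' calls.
#'
#' @param tract tract preset name ("CC", "CR", "FO").
#' @param outDir output directory.
#' @param seed integer seed used for every stochastic stage.
#' @param box box size (um) for generation stages.
#' @param voxelSize voxel spacing (um).
#' @param stationStride station stride for the validation measurement.
#' @param stl write STL meshes.
#' @return invisibly, the summary list (also written to `summary.json`).
#' @export
runPipeline <- function(tract = "CC", outDir = "axoncyto_out", seed = 1L,
                        box = c(15, 15, 15),
                        voxelSize = c(0.02, 0.02, 0.15),
                        stationStride = 3L, stl = TRUE) {
  t0 <- proc.time()[3L]
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  tp <- tractPreset(tract)
  rve <- generateRVE(rveConfig(tp, box = box, seed = seed))
  val <- validateRVE(rve, voxelSize = voxelSize,
                     stationStride = stationStride)
  fits <- NULL
  if (nrow(val$axons) >= 10L)
    fits <- list(area = fitLognormal(val$axons$mean_area),
                 diameter = fitLognormal(val$axons$mean_diameter))
  writeTables(list(axons = val$axons, stations = val$stations),
              outDir, fits = fits)
  stlInfo <- NULL
  if (stl) stlInfo <- exportSTL(rve, file.path(outDir, "stl"))
  summary <- list(
    tract = tract, seed = seed, box = box, voxel_size = voxelSize,
    axon_count = val$axonCount,
    axonal_density_mm3 = val$density,
    volume_fraction = val$volumeFraction,
    mean_tortuosity = mean(val$axons$tortuosity),
    mean_ellipticity = mean(val$axons$mean_ellipticity),
    area_fit = if (!is.null(fits)) list(
      mu = fits$area@mu, sigma = fits$area@sigma,
      mode = fits$area@mode, median = fits$area@median),
    diameter_fit = if (!is.null(fits)) list(
      mu = fits$diameter@mu, sigma = fits$diameter@sigma,
      mode = fits$diameter@mode, median = fits$diameter@median),
    elapsed_s = unname(proc.time()[3L] - t0))
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
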