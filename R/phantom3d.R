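#' Voxelise an in silico axon volume onto a full periodic grid
#'
#' Rasterises every tube of an [AxonRVE-class] into an integer label grid
#' with the given (typically anisotropic) voxel spacing. A voxel belongs to
#' an axon iff its centre lies inside (or exactly on) the tube surface; the
#' surface at each z-slice is the tube's tilted-ellipse footprint on that
#' plane. x-y coordinates wrap periodically.
#'
#' @param rve an [AxonRVE-class].
#' @param voxelSize spacing (um) along (x, y, z); the z spacing should
#'   match the station spacing (slices are stations).
#' @return a [LabelVolume-class].
#' @export
voxeliseRVE <- function(rve, voxelSize = c(0.02, 0.02, 0.15)) {
  stopifnot(is(rve, "AxonRVE"))
  box <- rve@box
  nx <- round(box[1L] / voxelSize[1L])
  ny <- round(box[2L] / voxelSize[2L])
  nz <- round(box[3L] / voxelSize[3L])
  lab <- array(0L, c(nx, ny, nz))
  for (i in seq_along(rve@tubes))
    lab <- .paintTube(lab, rve@tubes[[i]], i, voxelSize,
                      origin = c(0, 0, 0), wrap = TRUE)
  LabelVolume(lab, voxelSize = voxelSize)
}

#' Voxelise a single tube on its own local grid
#'
#' Rasterises one axon into a tight non-periodic grid around its own
#' extent (the tube is unwrapped even if it crosses the periodic
#' boundary), which keeps per-axon morphometry cheap. The grid origin is
#' recorded so measurements stay in the parent frame.
#'
#' @param rve an [AxonRVE-class].
#' @param axonId tube index.
#' @param voxelSize spacing (um).
#' @param margin lateral margin around the tube extent, um.
#' @return a [LabelVolume-class] containing only that axon's label.
#' @export
voxeliseTube <- function(rve, axonId, voxelSize = c(0.02, 0.02, 0.15),
                         margin = 0.12) {
  stopifnot(is(rve, "AxonRVE"))
  tb <- rve@tubes[[axonId]]
  hx <- vapply(seq_along(tb$z), function(k)
    sqrt(sum(tb$F[1L, , k]^2)), 1)
  hy <- vapply(seq_along(tb$z), function(k)
    sqrt(sum(tb$F[2L, , k]^2)), 1)
  x0 <- min(tb$cx - hx) - margin; x1 <- max(tb$cx + hx) + margin
  y0 <- min(tb$cy - hy) - margin; y1 <- max(tb$cy + hy) + margin
  nx <- ceiling((x1 - x0) / voxelSize[1L])
  ny <- ceiling((y1 - y0) / voxelSize[2L])
  nz <- length(tb$z)
  lab <- array(0L, c(nx, ny, nz))
  lab <- .paintTube(lab, tb, axonId, voxelSize,
                    origin = c(x0, y0, 0), wrap = FALSE)
  LabelVolume(lab, voxelSize = voxelSize, origin = c(x0, y0, 0))
}

# Rasterise one tube into `lab`. Slice k of the grid is assumed to sit at
# the tube's station z (z spacing == station spacing).
.paintTube <- function(lab, tb, id, vox, origin, wrap) {
  d <- dim(lab)
  for (k in seq_along(tb$z)) {
    kz <- round((tb$z[k] - origin[3L]) / vox[3L] + 0.5)
    if (kz < 1L || kz > d[3L]) next
    F <- tb$F[, , k]
    Fi <- solve(F)
    hx <- sqrt(sum(F[1L, ]^2)); hy <- sqrt(sum(F[2L, ]^2))
    cx <- tb$cx[k]; cy <- tb$cy[k]
    i0 <- floor((cx - hx - origin[1L]) / vox[1L] - 0.5)
    i1 <- ceiling((cx + hx - origin[1L]) / vox[1L] + 0.5)
    j0 <- floor((cy - hy - origin[2L]) / vox[2L] - 0.5)
    j1 <- ceiling((cy + hy - origin[2L]) / vox[2L] + 0.5)
    if (!wrap) {
      i0 <- max(i0, 0L); i1 <- min(i1, d[1L] - 1L)
      j0 <- max(j0, 0L); j1 <- min(j1, d[2L] - 1L)
      if (i0 > i1 || j0 > j1) next
    }
    ii <- i0:i1; jj <- j0:j1
    px <- origin[1L] + (ii + 0.5) * vox[1L] - cx
    py <- origin[2L] + (jj + 0.5) * vox[2L] - cy
    PX <- matrix(px, length(px), length(py))
    PY <- matrix(rep(py, each = length(px)), length(px), length(py))
    Q1 <- Fi[1L, 1L] * PX + Fi[1L, 2L] * PY
    Q2 <- Fi[2L, 1L] * PX + Fi[2L, 2L] * PY
    inside <- Q1 * Q1 + Q2 * Q2 <= 1
    if (!any(inside)) next
    iw <- if (wrap) (ii %% d[1L]) + 1L else ii + 1L
    jw <- if (wrap) (jj %% d[2L]) + 1L else jj + 1L
    sel <- which(inside, arr.ind = TRUE)
    idx <- cbind(iw[sel[, 1L]], jw[sel[, 2L]], kz)
    cur <- lab[idx]
    idx <- idx[cur == 0L, , drop = FALSE]
    if (nrow(idx)) lab[idx] <- as.integer(id)
  }
  lab
}

#' Configuration for 3D labelled phantom volumes
#'
#' @param tractParams a [TractStats-class] describing the geometry targets
#'   (see [tractPreset()]).
#' @param box box size, um (default ~15 um cube like the imaged volumes).
#' @param voxelSize anisotropic voxel spacing, um; the default couples
#'   0.020 um pixels with 0.150 um slices.
#' @param stationSpacing station spacing, um.
#' @param seed integer seed.
#' @param ... further arguments passed to [rveConfig()].
#' @return a list of class `phantom3DConfig`.
#' @export
phantom3DConfig <- function(tractParams, box = c(15, 15, 15),
                            voxelSize = c(0.020, 0.020, 0.150),
                            stationSpacing = 0.150, seed = 1L, ...) {
  stopifnot(is(tractParams, "TractStats"), stationSpacing > 0)
  cfg <- list(tractParams = tractParams, box = as.numeric(box),
              voxelSize = as.numeric(voxelSize),
              stationSpacing = stationSpacing, seed = as.integer(seed),
              extra = list(...))
  class(cfg) <- "phantom3DConfig"
  cfg
}

#' Generate a 3D labelled phantom volume with known ground truth
#'
#' Builds tubular axons with the same geometric kernel as the in silico
#' volume generator (delegates to [generateRVE()]) and voxelises them onto
#' an anisotropic grid, returning both the label volume and the exact
#' per-axon ground truth (centreline, per-station semi-axes and areas) so
#' downstream measurements can be checked against known values.
#'
#' @param config a [phantom3DConfig()].
#' @return a list with `volume` ([LabelVolume-class]), `truth` (list per
#'   axon: `centerline` n x 3 matrix, `a`, `b`, `area`, `theta`), and
#'   `rve` (the underlying [AxonRVE-class]).
#' @export
generatePhantomVolume <- function(config) {
  stopifnot(inherits(config, "phantom3DConfig"))
  args <- c(list(tractParams = config$tractParams, box = config$box,
                 stationSpacing = config$stationSpacing,
                 seed = config$seed), config$extra)
  rve <- generateRVE(do.call(rveConfig, args))
  vol <- voxeliseRVE(rve, voxelSize = config$voxelSize)
  truth <- lapply(tubes(rve), function(tb) {
    list(centerline = cbind(x = tb$cx, y = tb$cy, z = tb$z),
         a = tb$a, b = tb$b, area = pi * tb$a * tb$b, theta = tb$theta)
  })
  list(volume = vol, truth = truth, rve = rve)
}
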