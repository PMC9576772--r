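#' Extract an axon's centerline from a labelled volume
#'
#' Chains the per-slice centroids of the axon's voxels (ordered by z) and
#' smooths the lateral coordinates with a centred moving average. All
#' computation is in physical micrometre coordinates, so anisotropic voxels
#' are handled without resampling. For x-y--periodic volumes the per-slice
#' centroids are computed as circular means and unwrapped across slices, so
#' axons crossing the periodic boundary yield a contiguous path.
#'
#' @param vol a [LabelVolume-class].
#' @param axonId positive integer label present in `vol`.
#' @param smoothWindow moving-average window in slices (default 5).
#' @param periodic treat x-y as periodic (generated RVE volumes are).
#' @return a [Centerline-class].
#' @export
extractCenterline <- function(vol, axonId, smoothWindow = 5L,
                              periodic = FALSE) {
  stopifnot(is(vol, "LabelVolume"), axonId >= 1L)
  idx <- which(vol@labels == as.integer(axonId))
  if (length(idx) == 0L)
    stop(sprintf("axon %d not present in volume", axonId))
  d <- dim(vol@labels)
  ai <- arrayInd(idx, d)
  vx <- vol@voxelSize
  zs <- sort(unique(ai[, 3L]))
  if (length(zs) < 2L)
    stop(sprintf("axon %d spans a single slice; no direction defined",
                 axonId))
  Lx <- d[1L] * vx[1L]; Ly <- d[2L] * vx[2L]
  xphys <- (ai[, 1L] - 0.5) * vx[1L]
  yphys <- (ai[, 2L] - 0.5) * vx[2L]
  centroid1 <- function(v, L, per) {
    if (!per) return(mean(v))
    th <- v / L * 2 * pi
    ang <- atan2(mean(sin(th)), mean(cos(th)))
    (ang %% (2 * pi)) / (2 * pi) * L
  }
  cx <- vapply(zs, function(z) {
    centroid1(xphys[ai[, 3L] == z], Lx, periodic)
  }, 1)
  cy <- vapply(zs, function(z) {
    centroid1(yphys[ai[, 3L] == z], Ly, periodic)
  }, 1)
  if (periodic) {
    unwrap <- function(v, L) {
      dv <- diff(v)
      dv <- dv - round(dv / L) * L
      cumsum(c(v[1L], dv))
    }
    cx <- unwrap(cx, Lx)
    cy <- unwrap(cy, Ly)
  }
  cz <- (zs - 0.5) * vx[3L]
  sm <- as.integer(smoothWindow)
  pts <- cbind(x = runMean(cx, sm), y = runMean(cy, sm), z = cz) +
    rep(vol@origin, each = length(zs)) * c(1, 1, 1)
  Centerline(pts)
}

#' Sample measuring stations along a centerline
#'
#' Stations are placed at arc-length multiples of `spacing` (the slice
#' spacing, 0.150 um by default). The first and last half-spacing of the
#' path are trimmed because the tangent there is one-sided. Tangents are
#' taken by central differencing of the interpolated path.
#'
#' @param centerline a [Centerline-class].
#' @param spacing station spacing along the arc, um.
#' @return a list with `points` (n x 3), `tangents` (n x 3, unit rows) and
#'   `arclengths` (station positions along the path).
#' @export
sampleStations <- function(centerline, spacing = 0.150) {
  stopifnot(is(centerline, "Centerline"), spacing > 0)
  p <- centerline@points
  seg <- sqrt(rowSums((p[-1L, , drop = FALSE] -
                       p[-nrow(p), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L < 2 * spacing)
    stop("centerline arc length shorter than two station spacings")
  tpos <- seq(spacing, L, by = spacing)
  tpos <- tpos[tpos >= spacing / 2 & tpos <= L - spacing / 2]
  interp <- function(tt) {
    i <- findInterval(tt, s, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), nrow(p) - 1L)
    w <- (tt - s[i]) / pmax(seg[i], .Machine$double.eps)
    p[i, , drop = FALSE] * (1 - w) + p[i + 1L, , drop = FALSE] * w
  }
  pts <- interp(tpos)
  h <- spacing / 2
  tg <- interp(pmin(tpos + h, L)) - interp(pmax(tpos - h, 0))
  tg <- tg / sqrt(rowSums(tg^2))
  list(points = pts, tangents = tg, arclengths = tpos)
}

#' Cross-section of an axon on an arbitrary measuring plane
#'
#' Intersects the axon's surface (the 0.5 iso-level of its trilinearly
#' interpolated binary mask, in physical micrometre coordinates honouring
#' the anisotropic spacing) with the plane through `point` whose normal is
#' `tangent`. Measuring on the plane perpendicular to the centerline is
#' what removes the slice-angle distortion: a tilted circular tube still
#' yields its true circular section here, whereas the imaging plane
#' (`tangent = c(0,0,1)`) yields an area inflated by 1/cos(alpha).
#'
#' Returns the intersection contour as a closed polygon in in-plane
#' coordinates (um). If the plane cuts several disjoint contours (touching
#' axons after voxelisation), the one containing the centerline point is
#' kept and the station is flagged.
#'
#' @param vol a [LabelVolume-class].
#' @param axonId axon label.
#' @param point centre of the measuring plane (um, length 3).
#' @param tangent plane normal (centerline tangent), length 3.
#' @param halfWidth half-extent of the sampled plane window, um. Default:
#'   derived from the axon's largest slice footprint.
#' @param gridStep in-plane sampling step, um; default the in-plane voxel
#'   size.
#' @param periodic x-y periodic volume.
#' @return a list with `polygon` (n x 2 matrix, um, closed ring without
#'   repeated endpoint), `flagged` (TRUE if multiple contours were seen).
#' @export
crossSection <- function(vol, axonId, point, tangent, halfWidth = NULL,
                         gridStep = NULL, periodic = FALSE) {
  stopifnot(is(vol, "LabelVolume"), length(point) == 3L,
            length(tangent) == 3L)
  mask <- vol@labels == as.integer(axonId)
  if (!any(mask)) stop(sprintf("axon %d not present in volume", axonId))
  storage.mode(mask) <- "double"
  if (is.null(gridStep)) gridStep <- min(vol@voxelSize[1:2])
  if (is.null(halfWidth)) {
    counts <- apply(vol@labels == as.integer(axonId), 3L, sum)
    amax <- sqrt(max(counts) * vol@voxelSize[1L] * vol@voxelSize[2L] / pi)
    halfWidth <- 2 * amax + 4 * gridStep
  }
  .sectionPolygon(mask, vol@voxelSize, vol@origin, point, tangent,
                  halfWidth, gridStep, periodic)
}

# Core plane-sampling + contouring routine, shared with measureVolume()
# which pre-extracts the mask once per axon.
.sectionPolygon <- function(mask, vox, origin, point, tangent, halfWidth,
                            gridStep, periodic, maxGrow = 2L) {
  t <- tangent / sqrt(sum(tangent^2))
  bas <- perpBasis(t)
  for (grow in 0:maxGrow) {
    hw <- halfWidth * 2^grow
    u <- seq(-hw, hw, by = gridStep)
    v <- u
    nu <- length(u)
    uu <- rep(u, times = nu); vv <- rep(v, each = nu)
    pts <- cbind(point[1L] + uu * bas$e1[1L] + vv * bas$e2[1L],
                 point[2L] + uu * bas$e1[2L] + vv * bas$e2[2L],
                 point[3L] + uu * bas$e1[3L] + vv * bas$e2[3L])
    f <- trilinear(mask, pts, vox, origin, outside = 0,
                   periodicXY = periodic)
    fm <- matrix(f, nu, nu)
    cl <- grDevices::contourLines(u, v, fm, levels = 0.5)
    if (length(cl) == 0L) {
      if (grow < maxGrow) next
      stop("empty intersection: plane does not cut the axon")
    }
    closed <- vapply(cl, function(cc) {
      abs(cc$x[1L] - cc$x[length(cc$x)]) < 1e-12 &&
        abs(cc$y[1L] - cc$y[length(cc$y)]) < 1e-12
    }, TRUE)
    if (!any(closed)) {
      if (grow < maxGrow) next   # window clipped the contour: enlarge
      stop("cross-section contour not closed within sampling window")
    }
    cl <- cl[closed]
    polys <- lapply(cl, function(cc) {
      n <- length(cc$x)
      cbind(cc$x[-n], cc$y[-n])
    })
    flagged <- length(polys) > 1L
    if (flagged) {
      contains <- vapply(polys, function(pp)
        pointInPolygon(c(0, 0), pp), TRUE)
      pick <- if (any(contains)) which(contains)[1L] else {
        cent <- vapply(polys, function(pp)
          sum(colMeans(pp)^2), 1)
        which.min(cent)
      }
      poly <- polys[[pick]]
    } else poly <- polys[[1L]]
    return(list(polygon = poly, flagged = flagged))
  }
}

#' Area of a planar cross-section polygon
#'
#' Shoelace area of a simple closed polygon (um^2).
#'
#' @param polygon n x 2 matrix of vertices (closed ring, no repeated end).
#' @param check verify the polygon is simple (non-self-intersecting);
#'   quadratic cost, on by default, disabled internally for contour output
#'   which is simple by construction.
#' @return positive area.
#' @export
sectionArea <- function(polygon, check = TRUE) {
  polygon <- as.matrix(polygon)
  stopifnot(ncol(polygon) == 2L, nrow(polygon) >= 3L)
  A <- abs(signedArea(polygon))
  if (A < .Machine$double.eps * 100)
    stop("degenerate (collinear) polygon")
  if (check && .selfIntersects(polygon))
    stop("self-intersecting polygon")
  A
}

# Segment-pair intersection scan over non-adjacent edges.
.selfIntersects <- function(p) {
  n <- nrow(p)
  if (n < 4L) return(FALSE)
  a <- p
  b <- p[c(2:n, 1L), , drop = FALSE]
  seg <- function(i, j) {
    d1 <- b[i, ] - a[i, ]; d2 <- b[j, ] - a[j, ]
    den <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
    if (abs(den) < 1e-14) return(FALSE)
    w <- a[j, ] - a[i, ]
    t1 <- (w[1L] * d2[2L] - w[2L] * d2[1L]) / den
    t2 <- (w[1L] * d1[2L] - w[2L] * d1[1L]) / den
    t1 > 1e-10 && t1 < 1 - 1e-10 && t2 > 1e-10 && t2 < 1 - 1e-10
  }
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (j > n) break
      if (seg(i, j)) return(TRUE)
    }
  }
  FALSE
}

#' Best-fit (equivalent-area) diameter
#'
#' Diameter of the circle with the same area as the cross-section:
#' `d = 2 * sqrt(area / pi)`.
#'
#' @param area cross-sectional area, um^2, > 0.
#' @return diameter in um.
#' @examples
#' bestFitDiameter(pi)    # 2
#' bestFitDiameter(0.63)  # 0.8957
#' @export
bestFitDiameter <- function(area) {
  if (any(area <= 0)) stop("area must be positive")
  2 * sqrt(area / pi)
}

#' Moment-based best-fit ellipse of a cross-section polygon
#'
#' Fits an ellipse by matching the second central moments of the polygon
#' interior: the semi-axes are twice the square roots of the eigenvalues of
#' the interior covariance. Rotation invariant by construction.
#'
#' @param polygon n x 2 matrix, >= 5 vertices.
#' @return named numeric `c(a = major, b = minor)` semi-axes in um.
#' @export
fitEllipse <- function(polygon) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 5L)
    stop("need at least 5 vertices to fit an ellipse")
  mom <- polygonMoments(polygon)
  ev <- eigen(mom$cov, symmetric = TRUE)$values
  if (any(ev <= 0)) stop("degenerate polygon: non-positive moment matrix")
  c(a = 2 * sqrt(ev[1L]), b = 2 * sqrt(ev[2L]))
}

#' Ellipticity of a fitted cross-section ellipse
#'
#' `E = a/b - 1`: 0 for a perfect circle, 1 when the major axis is double
#' the minor axis.
#'
#' @param a,b semi-axes with `a >= b > 0`.
#' @return dimensionless ellipticity >= 0.
#' @export
ellipticity <- function(a, b) {
  if (any(b <= 0)) stop("minor semi-axis must be positive")
  if (any(a < b)) stop("major semi-axis must not be smaller than minor")
  a / b - 1
}

#' Tortuosity of a centerline
#'
#' `tau = 1 - (end-to-end Euclidean distance) / (arc length)`: 0 for a
#' straight path, approaching 1 for strongly folded paths. Invariant under
#' rigid motions and uniform scaling.
#'
#' @param centerline a [Centerline-class].
#' @return tortuosity in \[0, 1).
#' @export
tortuosity <- function(centerline) {
  stopifnot(is(centerline, "Centerline"))
  p <- centerline@points
  arc <- arcLength(centerline)
  if (arc <= 0) stop("zero arc length")
  chord <- sqrt(sum((p[nrow(p), ] - p[1L, ])^2))
  1 - chord / arc
}

#' Axonal density
#'
#' Number of axons divided by the scanned volume, reported in axons/mm^3
#' (the factor 1e9 converts from um^-3).
#'
#' @param nAxons number of axons counted (every axon with any voxels in the
#'   box counts once; no edge correction).
#' @param boxVolumeUm3 scanned volume in um^3.
#' @return axons per mm^3.
#' @examples
#' axonalDensity(67, 15^3)  # 1.985e7
#' @export
axonalDensity <- function(nAxons, boxVolumeUm3) {
  stopifnot(boxVolumeUm3 > 0)
  nAxons / boxVolumeUm3 * 1e9
}

#' Axonal volume fraction of a labelled volume
#'
#' Fraction between the summed axon volume and the total scanned volume:
#' the share of non-background voxels.
#'
#' @param vol a [LabelVolume-class].
#' @return a number in \[0, 1\].
#' @export
volumeFraction <- function(vol) {
  stopifnot(is(vol, "LabelVolume"))
  mean(vol@labels != 0L)
}

#' Measure every axon of a labelled volume
#'
#' The per-axon measurement loop: centerline extraction, station sampling
#' every `spacing` um, perpendicular-plane cross-sections, per-station area
#' / best-fit diameter / fitted-ellipse semi-axes / ellipticity, per-axon
#' tortuosity, volume (sum of station areas times spacing), plus tract
#' aggregates (axonal density and volume fraction). Stations whose
#' measuring plane would leave the z extent of the volume, or whose section
#' is smaller than the resolvable minimum, are skipped. Axons that fail
#' outright (e.g. single-slice fragments) are recorded in `failures` and
#' skipped, never silently dropped.
#'
#' @param vol a [LabelVolume-class].
#' @param spacing station spacing, um (default 0.150, the slice spacing).
#' @param smoothWindow centerline smoothing window, slices.
#' @param periodic x-y periodic volume (generated RVEs).
#' @param minArea smallest measurable section, um^2; default pi * 0.1^2
#'   (outer diameter 0.2 um, the resolution floor).
#' @param stationStride measure cross-sections at every `stationStride`-th
#'   station (tortuosity and the centerline always use all slices); 1
#'   measures every station.
#' @return a list with `axons` (per-axon data.frame), `stations`
#'   (per-station data.frame), `density` (axons/mm^3), `volumeFraction`,
#'   and `failures` (named character vector of skipped axons).
#' @export
measureVolume <- function(vol, spacing = 0.150, smoothWindow = 5L,
                          periodic = FALSE, minArea = pi * 0.01,
                          stationStride = 1L) {
  stopifnot(is(vol, "LabelVolume"))
  ids <- sort(setdiff(unique(as.vector(vol@labels)), 0L))
  if (length(ids) == 0L) stop("volume contains no labelled axons")
  vx <- vol@voxelSize
  d <- dim(vol@labels)
  zmin <- vol@origin[3L]; zmax <- vol@origin[3L] + d[3L] * vx[3L]
  axRows <- list(); stRows <- list(); failures <- character(0)
  for (id in ids) {
    res <- tryCatch({
      cl <- extractCenterline(vol, id, smoothWindow = smoothWindow,
                              periodic = periodic)
      st <- sampleStations(cl, spacing = spacing)
      mask <- vol@labels == id
      storage.mode(mask) <- "double"
      counts <- apply(mask, 3L, sum)
      amax <- sqrt(max(counts) * vx[1L] * vx[2L] / pi)
      hw <- 1.6 * amax + 6 * min(vx[1:2])
      keep <- seq(1L, nrow(st$points), by = as.integer(stationStride))
      secA <- secD <- secMa <- secMb <- secE <- rep(NA_real_, length(keep))
      secS <- st$arclengths[keep]
      flags <- logical(length(keep))
      for (k in seq_along(keep)) {
        i <- keep[k]
        pt <- st$points[i, ]; tg <- st$tangents[i, ]
        # skip stations whose tilted plane would poke out of the stack
        zreach <- hw * sqrt(max(0, 1 - tg[3L]^2))
        if (pt[3L] - zreach < zmin + 1e-9 ||
            pt[3L] + zreach > zmax - 1e-9) next
        sec <- tryCatch(
          .sectionPolygon(mask, vx, vol@origin, pt, tg, hw,
                          min(vx[1:2]), periodic),
          error = function(e) NULL)
        if (is.null(sec) || nrow(sec$polygon) < 5L) next
        A <- abs(signedArea(sec$polygon))
        if (A < minArea) next
        ab <- tryCatch(fitEllipse(sec$polygon), error = function(e) NULL)
        if (is.null(ab)) next
        secA[k] <- A
        secD[k] <- bestFitDiameter(A)
        secMa[k] <- ab[["a"]]; secMb[k] <- ab[["b"]]
        secE[k] <- ellipticity(ab[["a"]], ab[["b"]])
        flags[k] <- sec$flagged
      }
      ok <- !is.na(secA)
      if (!any(ok)) stop("no measurable stations")
      stat <- data.frame(axon_id = id, station_arclength = secS[ok],
                         area = secA[ok], diameter = secD[ok],
                         a = secMa[ok], b = secMb[ok], E = secE[ok],
                         flagged = flags[ok])
      tau <- tortuosity(cl)
      axn <- data.frame(
        axon_id = id, n_stations = sum(ok), tortuosity = tau,
        mean_area = mean(secA[ok]), mean_diameter = mean(secD[ok]),
        mean_ellipticity = mean(secE[ok]),
        volume = sum(secA[ok]) * spacing * stationStride,
        arc_length = arcLength(cl))
      list(stations = stat, axon = axn)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[as.character(id)] <- conditionMessage(res)
    } else {
      axRows[[length(axRows) + 1L]] <- res$axon
      stRows[[length(stRows) + 1L]] <- res$stations
    }
  }
  if (length(axRows) == 0L)
    stop("no axon could be measured")
  axons <- do.call(rbind, axRows)
  stations <- do.call(rbind, stRows)
  list(axons = axons, stations = stations,
       density = axonalDensity(length(ids), boxVolume(vol)),
       volumeFraction = volumeFraction(vol),
       failures = failures)
}
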