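#' Bundled tract parameter presets
#'
#' Tract-level statistics for the three sampled white-matter tracts,
#' rebuilt exclusively from the published summary values: lognormal
#' parameters derived from the printed mode/median pairs of cross-sectional
#' area and best-fit diameter via [modeMedianToParams()], the printed
#' ellipticity ranges, tortuosity means and SDs, axonal densities and
#' volume fractions. Interlayer variability terms (slice-to-slice area CV
#' 0.10, semi-axis step cap 0.05 um) are package conventions where no
#' printed value exists.
#'
#' @param tract "CC" (corpus callosum), "CR" (corona radiata) or "FO"
#'   (fornix); case-insensitive.
#' @return a [TractStats-class].
#' @examples
#' tractPreset("CC")
#' @export
tractPreset <- function(tract = c("CC", "CR", "FO")) {
  tract <- toupper(tract[1L])
  tract <- match.arg(tract, c("CC", "CR", "FO"))
  p <- switch(tract,
    CC = list(area = c(0.63, 1.42), diam = c(1.07, 1.35),
              ell = c(0.6, 0.9), tau = c(0.113, 0.109),
              dens = 2.0e7, vf = c(0.45, 0.12)),
    CR = list(area = c(0.50, 1.35), diam = c(1.00, 1.30),
              ell = c(0.6, 0.9), tau = c(0.091, 0.070),
              dens = 1.5e7, vf = c(0.37, 0.21)),
    FO = list(area = c(0.98, 2.32), diam = c(1.41, 1.81),
              ell = c(0.7, 0.9), tau = c(0.130, 0.088),
              dens = 1.1e7, vf = c(0.51, 0.05)))
  ap <- modeMedianToParams(p$area[1L], p$area[2L])
  dp <- modeMedianToParams(p$diam[1L], p$diam[2L])
  TractStats(tract = tract,
             areaMu = ap[["mu"]], areaSigma = ap[["sigma"]],
             diameterMu = dp[["mu"]], diameterSigma = dp[["sigma"]],
             ellipticityMin = p$ell[1L], ellipticityMax = p$ell[2L],
             tortuosityMean = p$tau[1L], tortuositySd = p$tau[2L],
             axonalDensity = p$dens,
             volumeFraction = p$vf[1L], volumeFractionSd = p$vf[2L])
}

#' Configuration of the in silico volume generator
#'
#' @param tractParams a [TractStats-class] (generation targets).
#' @param box box edge lengths in um, default `c(15, 15, 15)`.
#' @param stationSpacing station spacing along z, um (default 0.150, the
#'   slice spacing of the source stacks).
#' @param seed integer seed; generation is a pure function of
#'   (config, seed).
#' @param maxOuterIterations volume-fraction rescale iterations.
#' @param minGap minimum inter-axon surface clearance, um (one in-plane
#'   voxel by default; extra-cellular gaps measure tens of nanometres).
#' @param axonJitterMax peak amplitude of the small per-axon lateral
#'   jitter, um.
#' @param maxPlaceAttempts random-sequential-addition attempts per axon.
#' @return a list of class `rveConfig`.
#' @export
rveConfig <- function(tractParams, box = c(15, 15, 15),
                      stationSpacing = 0.150, seed = 1L,
                      maxOuterIterations = 10L, minGap = 0.02,
                      axonJitterMax = 0.05, maxPlaceAttempts = 20000L) {
  stopifnot(is(tractParams, "TractStats"), length(box) == 3L,
            all(box > 0), stationSpacing > 0, minGap >= 0)
  cfg <- list(tractParams = tractParams, box = as.numeric(box),
              stationSpacing = stationSpacing, seed = as.integer(seed),
              maxOuterIterations = as.integer(maxOuterIterations),
              minGap = minGap, axonJitterMax = axonJitterMax,
              maxPlaceAttempts = as.integer(maxPlaceAttempts))
  class(cfg) <- "rveConfig"
  cfg
}

# ---- internal geometry helpers ------------------------------------------

# Shared boundary sampling for the ellipse clearance tests.
.CIRC48 <- local({
  ph <- seq(0, 2 * pi, length.out = 49L)[-49L]
  rbind(cos(ph), sin(ph))
})

# Footprint of a tilted elliptical tube on a z-plane. Returns the 2x2
# matrix F such that the footprint boundary is c_xy + F %*% (cos t, sin t).
# a, b: perpendicular semi-axes; theta: in-plane orientation in the
# perpendicular basis; tangent: unit direction (tz > 0).
.footprintF <- function(a, b, theta, tangent) {
  bas <- perpBasis(tangent)
  w1 <- cos(theta) * bas$e1 + sin(theta) * bas$e2
  w2 <- -sin(theta) * bas$e1 + cos(theta) * bas$e2
  tz <- tangent[3L]
  p1 <- a * (w1[1:2] - (w1[3L] / tz) * tangent[1:2])
  p2 <- b * (w2[1:2] - (w2[3L] / tz) * tangent[1:2])
  matrix(c(p1, p2), 2L, 2L)
}

# Per-station footprint matrices (2 x 2 x n) for one tube, with semi-axes
# optionally inflated (used for clearance checks).
.tubeF <- function(tube, inflate = 0) {
  n <- length(tube$z)
  F <- array(0, c(2L, 2L, n))
  for (k in seq_len(n))
    F[, , k] <- .footprintF(tube$a[k] + inflate, tube$b[k] + inflate,
                            tube$theta, tube$tangents[k, ])
  F
}

# Do two footprint ellipses overlap? Ellipse i is {rel + Fi v, |v|=1},
# ellipse j is {Fj v, |v|=1} (j at origin). Exact: in the frame where j
# is the unit circle, the sets overlap iff the origin lies inside the
# mapped ellipse i or the minimum distance from the origin to its
# boundary (coarse grid + Newton refinement) is <= 1.
.ellipseOverlap <- function(rel, Fi, Fj, FjInv, FiInv, circ) {
  # quick reject by bounding radii (largest singular value <= Frobenius)
  ri2 <- sum(Fi^2); rj2 <- sum(Fj^2)
  d2 <- sum(rel^2)
  if (d2 > ri2 + rj2 + 2 * sqrt(ri2 * rj2)) return(FALSE)
  # origin of j inside i?
  if (sum((FiInv %*% rel)^2) <= 1) return(TRUE)
  m <- FjInv %*% rel           # centre of i in the circle frame
  if (sum(m^2) <= 1) return(TRUE)   # centre of i inside j
  H <- FjInv %*% Fi
  # coarse scan of |m + H u(t)|^2
  P <- H %*% circ
  d2t <- (P[1L, ] + m[1L])^2 + (P[2L, ] + m[2L])^2
  if (min(d2t) <= 1) return(TRUE)
  # Newton-refine the two best local minima
  n <- ncol(circ)
  ordc <- order(d2t)
  seen <- integer(0)
  for (cand in ordc) {
    if (any(abs(((cand - seen + n / 2) %% n) - n / 2) <= 1L)) next
    seen <- c(seen, cand)
    t0 <- atan2(circ[2L, cand], circ[1L, cand])
    t <- t0
    for (it in 1:8) {
      u <- c(cos(t), sin(t)); du <- c(-sin(t), cos(t))
      p <- m + H %*% u
      Hd <- H %*% du
      g <- 2 * sum(p * Hd)
      h <- 2 * sum(Hd^2) - 2 * sum(p * (H %*% u))
      if (!is.finite(h) || abs(h) < 1e-14) break
      step <- g / h
      step <- max(min(step, 0.3), -0.3)
      t <- t - step
      if (abs(step) < 1e-10) break
    }
    u <- c(cos(t), sin(t))
    if (sum((m + H %*% u)^2) <= 1) return(TRUE)
    if (length(seen) >= 2L) break
  }
  FALSE
}

# Smooth unit-scale lateral field on the station grid: a few random
# Fourier modes per component, normalised to unit peak displacement.
# Mode count is capped so undulation wavelengths stay >= ~5 um and bend
# radii stay above the axon calibre (axons do not fold on themselves).
.smoothField <- function(z, L, nModes = max(1L, min(3L, floor(L / 5)))) {
  f <- matrix(0, length(z), 2L)
  for (cmp in 1:2) {
    v <- 0
    for (k in seq_len(nModes))
      v <- v + stats::rnorm(1, 0, 1 / k) *
        sin(2 * pi * k * z / L + stats::runif(1, 0, 2 * pi))
    f[, cmp] <- v
  }
  pk <- max(sqrt(rowSums(f^2)))
  if (pk > 0) f <- f / pk
  f
}

# Tortuosity of a lateral path (n x 2 displacement at stations z),
# after the same moving-average smoothing the measurement stage applies.
.pathTau <- function(lat, z, smoothWindow = 5L) {
  sx <- runMean(lat[, 1L], smoothWindow)
  sy <- runMean(lat[, 2L], smoothWindow)
  p <- cbind(sx, sy, z)
  seg <- sqrt(rowSums((p[-1L, ] - p[-nrow(p), ])^2))
  arc <- sum(seg)
  chord <- sqrt(sum((p[nrow(p), ] - p[1L, ])^2))
  1 - chord / arc
}

# ---- generator -----------------------------------------------------------

#' Generate a periodic in silico axon-bundle volume
#'
#' Builds a Representative Volume Element matching a tract parameter set:
#'
#' 1. the axon count follows the tract's axonal density;
#' 2. per-axon mean cross-sectional areas are drawn from the tract's
#'    lognormal (truncated at the 0.2 um resolvable outer diameter),
#'    ellipticity uniform on the tract range, random in-plane orientation;
#' 3. per-station areas receive multiplicative lognormal interlayer jitter
#'    (CV `interlayerAreaCv`) with the slice-to-slice semi-axis change
#'    capped at `interlayerSemiaxisDelta`;
#' 4. all areas are uniformly rescaled so the realised volume fraction hits
#'    the tract target (the printed density/area/volume-fraction values are
#'    not jointly consistent; the volume-fraction target governs, see the
#'    methods vignette);
#' 5. axons undulate coherently: a shared smooth lateral displacement field
#'    whose amplitude is calibrated by bisection so the mean measured-style
#'    tortuosity hits the tract mean (tolerance 0.005), plus a small
#'    independent per-axon jitter; the shared component translates every
#'    z-plane rigidly, so it cannot create overlaps;
#' 6. seed positions are placed by random sequential addition (largest
#'    first) in the periodic x-y cell, rejecting candidates whose widest
#'    footprint would come within `minGap` of a placed tube;
#' 7. the full per-station clearance is then verified against all periodic
#'    neighbours; residual violations (from per-axon jitter) shrink that
#'    axon's jitter and, if needed, re-place the tube; the generator fails
#'    loudly if the configuration is infeasible.
#'
#' Deterministic given the seed.
#'
#' @param config an [rveConfig()].
#' @return an [AxonRVE-class].
#' @examples
#' ts <- tractPreset("CC")
#' cfg <- rveConfig(ts, box = c(6, 6, 6), seed = 3)
#' rve <- generateRVE(cfg)
#' achievedStats(rve)
#' @export
generateRVE <- function(config) {
  stopifnot(inherits(config, "rveConfig"))
  withSeed(config$seed, .generateRVE(config))
}

.generateRVE <- function(cfg) {
  tp <- cfg$tractParams
  box <- cfg$box; dz <- cfg$stationSpacing
  boxVol <- prod(box)
  N <- round(tp@axonalDensity * 1e-9 * boxVol)
  if (N < 1L)
    stop(sprintf(
      "box too small: expected axon count %.2f < 1 at density %.3g /mm^3",
      tp@axonalDensity * 1e-9 * boxVol, tp@axonalDensity))
  nz <- max(2L, round(box[3L] / dz))
  z <- (seq_len(nz) - 0.5) * dz

  # (2) per-axon draws -----------------------------------------------------
  minA <- pi * 0.1^2
  meanArea <- stats::rlnorm(N, tp@areaMu, tp@areaSigma)
  for (r in seq_len(100L)) {
    low <- meanArea < minA
    if (!any(low)) break
    meanArea[low] <- stats::rlnorm(sum(low), tp@areaMu, tp@areaSigma)
  }
  meanArea <- pmax(meanArea, minA)
  E <- stats::runif(N, tp@ellipticityMin, tp@ellipticityMax)
  theta <- stats::runif(N, 0, 2 * pi)

  # (5) coherent undulation + per-axon jitter ------------------------------
  Dunit <- .smoothField(z, box[3L])
  epsAmp <- stats::runif(N, 0, cfg$axonJitterMax)
  epsFields <- lapply(seq_len(N), function(i) {
    e <- apply(matrix(stats::rnorm(nz * 2L), nz, 2L), 2L,
               runMean, window = 11L)
    e <- sweep(e, 2L, colMeans(e))
    pk <- max(sqrt(rowSums(e^2)))
    if (pk > 0) e * (epsAmp[i] / pk) else e
  })
  tauOf <- function(amp) {
    mean(vapply(seq_len(N), function(i)
      .pathTau(amp * Dunit + epsFields[[i]], z), 1))
  }
  amp <- 0
  if (tp@tortuosityMean > tauOf(0) + 1e-9) {
    ampHi <- 2
    while (tauOf(ampHi) < tp@tortuosityMean && ampHi < 64)
      ampHi <- ampHi * 2
    lo <- 0; hi <- ampHi
    for (it in seq_len(24L)) {
      mid <- (lo + hi) / 2
      if (tauOf(mid) < tp@tortuosityMean) lo <- mid else hi <- mid
      if (abs(tauOf((lo + hi) / 2) - tp@tortuosityMean) < 0.005) break
    }
    amp <- (lo + hi) / 2
  }
  D <- amp * Dunit

  mkTangents <- function(lat) {
    p <- cbind(lat, z)
    n <- nrow(p)
    tg <- rbind(p[2L, ] - p[1L, ],
                p[3:n, , drop = FALSE] - p[1:(n - 2L), , drop = FALSE],
                p[n, ] - p[n - 1L, ])
    tg / sqrt(rowSums(tg^2))
  }
  lats <- lapply(seq_len(N), function(i) D + epsFields[[i]])
  tangents <- lapply(lats, mkTangents)
  arcOf <- function(lat) {
    p <- cbind(lat, z)
    seg <- sqrt(rowSums((p[-1L, , drop = FALSE] -
                         p[-nrow(p), , drop = FALSE])^2))
    c(seg[1L], (seg[-1L] + seg[-length(seg)]) / 2, seg[length(seg)])
  }
  arcEl <- lapply(lats, arcOf)

  # (4) volume-fraction pre-scale on the base (un-jittered) sections -------
  aBase <- sqrt(meanArea * (1 + E) / pi)
  bBase <- aBase / (1 + E)
  vf0 <- sum(vapply(seq_len(N), function(i)
    pi * aBase[i] * bBase[i] * sum(arcEl[[i]]), 1)) / boxVol
  scl <- sqrt(tp@volumeFraction / vf0)
  aBase <- aBase * scl; bBase <- bBase * scl

  # (3/6) placement by random sequential addition, largest first -----------
  # Candidates are rejected if their base cross-section would come within
  # minGap of a placed tube at any station plane (periodic images included);
  # the interlayer area jitter is applied afterwards, during growth, where
  # collisions are resolved station by station.
  circ <- .CIRC48
  gap <- cfg$minGap
  # small slack above half the gap so the final exact-gap verification
  # always holds with margin
  infl <- gap / 2 + 5e-4
  baseF <- lapply(seq_len(N), function(i) {
    F <- array(0, c(2L, 2L, nz))
    for (k in seq_len(nz))
      F[, , k] <- .footprintF(aBase[i] + infl, bBase[i] + infl,
                              theta[i], tangents[[i]][k, ])
    F
  })
  invF <- function(F) {
    Fi <- array(0, dim(F))
    for (k in seq_len(dim(F)[3L])) Fi[, , k] <- solve(F[, , k])
    Fi
  }
  baseFInv <- lapply(baseF, invF)
  statRad <- function(F) {
    vapply(seq_len(dim(F)[3L]), function(k) {
      m <- F[, , k]
      tr <- sum(m^2); dt <- m[1L, 1L] * m[2L, 2L] - m[1L, 2L] * m[2L, 1L]
      sqrt((tr + sqrt(max(tr^2 - 4 * dt^2, 0))) / 2)
    }, 1)
  }
  sRad <- lapply(baseF, statRad)
  maxRad <- vapply(sRad, max, 1)
  ord <- order(-maxRad)
  shifts <- as.matrix(expand.grid(sx = c(-box[1L], 0, box[1L]),
                                  sy = c(-box[2L], 0, box[2L])))
  centers <- matrix(NA_real_, N, 2L)
  # station scan order interleaves the z range so contiguous overlap
  # regions are hit early and bad candidates fail fast
  scanOrd <- order((seq_len(nz) * 17L) %% nz)
  pairClearBase <- function(i, j, sft) {
    base <- centers[i, ] - (centers[j, ] + sft)
    dx <- base[1L] + lats[[i]][, 1L] - lats[[j]][, 1L]
    dy <- base[2L] + lats[[i]][, 2L] - lats[[j]][, 2L]
    lim <- sRad[[i]] + sRad[[j]]
    cl <- dx * dx + dy * dy <= lim * lim
    close <- scanOrd[cl[scanOrd]]
    for (k in close) {
      if (.ellipseOverlap(c(dx[k], dy[k]),
                          baseF[[i]][, , k], baseF[[j]][, , k],
                          baseFInv[[j]][, , k], baseFInv[[i]][, , k],
                          circ))
        return(FALSE)
    }
    TRUE
  }
  refreshBase <- function(i) {
    for (k in seq_len(nz)) {
      baseF[[i]][, , k] <<- .footprintF(aBase[i] + infl, bBase[i] + infl,
                                        theta[i], tangents[[i]][k, ])
      baseFInv[[i]][, , k] <<- solve(baseF[[i]][, , k])
    }
    sRad[[i]] <<- statRad(baseF[[i]])
    maxRad[i] <<- max(sRad[[i]])
  }
  placeAll <- function() {
    placedIds <- integer(0)
    for (i in ord) {
      done <- FALSE
      for (att in seq_len(cfg$maxPlaceAttempts)) {
        if (att %% 250L == 0L) {
          # re-draw the in-plane orientation: near jamming an unlucky
          # orientation can be unplaceable where another fits
          theta[i] <<- stats::runif(1, 0, 2 * pi)
          refreshBase(i)
        }
        centers[i, ] <<- stats::runif(2, 0, box[1:2])
        ok <- TRUE
        for (j in placedIds) {
          dd <- centers[i, ] - centers[j, ]
          for (s in seq_len(nrow(shifts))) {
            sft <- shifts[s, ]
            if (sum((dd - sft)^2) >
                (maxRad[i] + maxRad[j] + 2 * cfg$axonJitterMax)^2) next
            if (!pairClearBase(i, j, sft)) { ok <- FALSE; break }
          }
          if (!ok) break
        }
        if (ok) { done <- TRUE; break }
      }
      if (!done) return(i)
      placedIds <- c(placedIds, i)
    }
    0L
  }
  for (restart in seq_len(6L)) {
    fail <- placeAll()
    if (fail == 0L) break
    if (restart == 6L)
      stop(sprintf(paste0(
        "infeasible packing: axon %d (base footprint radius %.2f um) could ",
        "not be placed in %d attempts at volume fraction target %.2f; the ",
        "volume-fraction/density combination is the binding constraint"),
        fail, maxRad[fail], cfg$maxPlaceAttempts, tp@volumeFraction))
    # shave the base sections slightly and try a fresh sequence; the
    # volume-fraction rescale loop regains the loss in verified steps
    aBase <- aBase * 0.99; bBase <- bBase * 0.99
    for (i in seq_len(N)) refreshBase(i)
  }

  # neighbour lists (pairs that can ever interact, with their shift)
  nbr <- vector("list", N)
  jitHi <- 1.30   # collision checks assume jitter keeps a below this factor
  for (i in seq_len(N)) nbr[[i]] <- list()
  for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
    dd <- centers[i, ] - centers[j, ]
    for (s in seq_len(nrow(shifts))) {
      sft <- shifts[s, ]
      if (sum((dd - sft)^2) <=
          (jitHi * (maxRad[i] + maxRad[j]) + 2 * cfg$axonJitterMax)^2) {
        nbr[[i]][[length(nbr[[i]]) + 1L]] <- list(j = j, sft = sft)
        nbr[[j]][[length(nbr[[j]]) + 1L]] <- list(j = i, sft = -sft)
      }
    }
  }

  # (5b/6) growth: per-station interlayer area jitter with collision
  # resolution (redraw up to 50 times, then shrink toward the base size,
  # which is clear by construction).
  cv <- tp@interlayerAreaCv
  sdl <- sqrt(log(1 + cv^2))
  dmax <- tp@interlayerSemiaxisDelta
  aProf <- matrix(0, nz, N)
  curF <- lapply(seq_len(N), function(i) array(0, c(2L, 2L, nz)))
  curFInv <- lapply(seq_len(N), function(i) array(0, c(2L, 2L, nz)))
  mkF <- function(i, k, a) {
    .footprintF(a + infl, a / (1 + E[i]) + infl, theta[i],
                tangents[[i]][k, ])
  }
  clearAt <- function(i, k, Fi, FiInv) {
    for (nb in nbr[[i]]) {
      j <- nb$j
      rel <- centers[i, ] + lats[[i]][k, ] -
        (centers[j, ] + nb$sft + lats[[j]][k, ])
      if (j < i || aProf[k, j] > 0) {
        Fj <- curF[[j]][, , k]; FjI <- curFInv[[j]][, , k]
      } else {
        Fj <- baseF[[j]][, , k]; FjI <- baseFInv[[j]][, , k]
      }
      if (.ellipseOverlap(rel, Fi, Fj, FjI, FiInv, circ)) return(FALSE)
    }
    TRUE
  }
  for (k in seq_len(nz)) {
    for (i in seq_len(N)) {
      prev <- if (k > 1L) aProf[k - 1L, i] else NA_real_
      accepted <- NA_real_
      FA <- NULL
      for (try in seq_len(50L)) {
        cand <- aBase[i] * sqrt(stats::rlnorm(1, -sdl^2 / 2, sdl))
        cand <- min(cand, aBase[i] * jitHi)
        if (!is.na(prev))
          cand <- min(max(cand, prev - dmax), prev + dmax)
        Fi <- mkF(i, k, cand)
        FiInv <- solve(Fi)
        if (clearAt(i, k, Fi, FiInv)) {
          accepted <- cand; FA <- Fi
          break
        }
      }
      if (is.na(accepted)) {
        # shrink toward the base size (clear by construction); a few
        # bisection steps find the largest clear value
        loA <- min(aBase[i], if (is.na(prev)) aBase[i] else prev)
        hiA <- if (is.na(prev)) aBase[i] else min(prev + dmax,
                                                  aBase[i] * jitHi)
        best <- loA
        for (bs in seq_len(6L)) {
          mid <- (loA + hiA) / 2
          Fi <- mkF(i, k, mid)
          if (clearAt(i, k, Fi, solve(Fi))) { best <- mid; loA <- mid }
          else hiA <- mid
        }
        accepted <- best
        FA <- mkF(i, k, accepted)
      }
      aProf[k, i] <- accepted
      curF[[i]][, , k] <- FA
      curFInv[[i]][, , k] <- solve(FA)
    }
  }

  # finalise absolute tubes -------------------------------------------------
  mkTube <- function(i) {
    tb <- list(id = i, z = z,
               cx = centers[i, 1L] + lats[[i]][, 1L],
               cy = centers[i, 2L] + lats[[i]][, 2L],
               a = aProf[, i], b = aProf[, i] / (1 + E[i]),
               theta = theta[i], tangents = tangents[[i]])
    tb$F <- .tubeF(tb, inflate = 0)
    tb
  }
  tubesAbs <- lapply(seq_len(N), mkTube)

  # full verification; residual clashes shrink the smaller tube toward base
  for (round in seq_len(12L)) {
    if (.rveOverlapFree(tubesAbs, box, gap, circ)) break
    if (round == 12L)
      stop("could not resolve residual overlaps; configuration infeasible")
    clash <- .rveFirstClash(tubesAbs, box, gap, circ)
    tgt <- clash[which.min(maxRad[clash])]
    if (max(abs(aProf[, tgt] - aBase[tgt])) < 1e-4) {
      # already at base: shave the section outright (guaranteed progress)
      aBase[tgt] <- aBase[tgt] * 0.99
      aProf[, tgt] <- pmin(aProf[, tgt], aBase[tgt])
    } else {
      aProf[, tgt] <- aBase[tgt] + (aProf[, tgt] - aBase[tgt]) * 0.5
      if (max(abs(aProf[, tgt] - aBase[tgt])) < 1e-4)
        aProf[, tgt] <- aBase[tgt]
    }
    tubesAbs[[tgt]] <- mkTube(tgt)
  }

  # (7) realised volume fraction, rescale within target +/- SD -------------
  vfOf <- function(tl) sum(vapply(seq_len(N), function(i)
    sum(pi * tl[[i]]$a * tl[[i]]$b * arcEl[[i]]), 1)) / boxVol
  rescale <- function(tl, f) {
    for (i in seq_len(N)) {
      tl[[i]]$a <- tl[[i]]$a * f
      tl[[i]]$b <- tl[[i]]$b * f
      tl[[i]]$F <- .tubeF(tl[[i]], inflate = 0)
    }
    tl
  }
  for (it in seq_len(cfg$maxOuterIterations)) {
    vf <- vfOf(tubesAbs)
    if (abs(vf - tp@volumeFraction) / tp@volumeFraction < 0.02) break
    f <- sqrt(tp@volumeFraction / vf)
    f <- min(f, 1.01)   # grow only in small, re-verified steps
    cand <- rescale(tubesAbs, f)
    if (f > 1 && !.rveOverlapFree(cand, box, gap - 1e-9, circ)) break
    tubesAbs <- cand
  }
  vf <- vfOf(tubesAbs)
  if (abs(vf - tp@volumeFraction) > tp@volumeFractionSd)
    stop(sprintf(paste0(
      "achieved volume fraction %.3f outside target %.3f +/- %.3f; ",
      "packing is the binding constraint"), vf, tp@volumeFraction,
      tp@volumeFractionSd))

  # achieved statistics -----------------------------------------------------
  perMeanArea <- vapply(tubesAbs, function(tb) mean(pi * tb$a * tb$b), 1)
  lmu <- mean(log(perMeanArea))
  lsd <- sqrt(mean((log(perMeanArea) - lmu)^2))
  taus <- vapply(tubesAbs, function(tb)
    .pathTau(cbind(tb$cx, tb$cy), tb$z), 1)
  perMeanDiam <- 2 * sqrt(perMeanArea / pi)
  dmu <- mean(log(perMeanDiam))
  dsd <- sqrt(mean((log(perMeanDiam) - dmu)^2))
  ach <- TractStats(
    tract = paste0(tp@tract, " (in silico)"),
    areaMu = lmu, areaSigma = max(lsd, 1e-6),
    diameterMu = dmu, diameterSigma = max(dsd, 1e-6),
    ellipticityMin = min(E), ellipticityMax = max(E),
    tortuosityMean = mean(taus),
    tortuositySd = if (N > 1L) stats::sd(taus) else 0,
    axonalDensity = axonalDensity(N, boxVol),
    volumeFraction = vf,
    volumeFractionSd = tp@volumeFractionSd,
    interlayerAreaCv = tp@interlayerAreaCv,
    interlayerSemiaxisDelta = tp@interlayerSemiaxisDelta)

  new("AxonRVE", tubes = tubesAbs, box = box, periodicXY = TRUE,
      achievedStats = ach, stationSpacing = dz, minGap = cfg$minGap,
      seed = cfg$seed)
}

# Full sampled clearance check over all station planes and periodic
# images; used after any growth step and exposed via checkOverlaps().
.rveOverlapFree <- function(tubes, box, gap, circ = NULL) {
  is.null(.rveFirstClash(tubes, box, gap, circ))
}

# First clashing tube pair c(i, j), or NULL if the clearance holds.
.rveFirstClash <- function(tubes, box, gap, circ = NULL) {
  if (is.null(circ)) circ <- .CIRC48
  N <- length(tubes)
  if (N < 2L) return(NULL)
  Finf <- lapply(tubes, .tubeF, inflate = gap / 2)
  FinfInv <- lapply(Finf, function(F) {
    n <- dim(F)[3L]; Fi <- array(0, dim(F))
    for (k in seq_len(n)) Fi[, , k] <- solve(F[, , k])
    Fi
  })
  maxRad <- vapply(seq_len(N), function(i)
    sqrt(max(apply(Finf[[i]], 3L, function(m) max(colSums(m^2))))), 1)
  shifts <- as.matrix(expand.grid(sx = c(-box[1L], 0, box[1L]),
                                  sy = c(-box[2L], 0, box[2L])))
  nz <- length(tubes[[1L]]$z)
  for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
    for (s in seq_len(nrow(shifts))) {
      sft <- shifts[s, ]
      dd0 <- c(mean(tubes[[i]]$cx) - mean(tubes[[j]]$cx),
               mean(tubes[[i]]$cy) - mean(tubes[[j]]$cy)) - sft
      if (sum(dd0^2) > (maxRad[i] + maxRad[j] + 0.2)^2) next
      for (k in seq_len(nz)) {
        rel <- c(tubes[[i]]$cx[k] - tubes[[j]]$cx[k],
                 tubes[[i]]$cy[k] - tubes[[j]]$cy[k]) - sft
        if (.ellipseOverlap(rel, Finf[[i]][, , k], Finf[[j]][, , k],
                            FinfInv[[j]][, , k], FinfInv[[i]][, , k],
                            circ))
          return(c(i, j))
      }
    }
  }
  NULL
}

#' Verify the non-overlap invariant of a generated volume
#'
#' Sampled clearance check at every station plane against all periodic
#' x-y images: no two tube surfaces may come closer than the minimum gap.
#'
#' @param rve an [AxonRVE-class].
#' @param gap clearance to enforce, um; defaults to the volume's `minGap`.
#' @return TRUE if clearance holds everywhere.
#' @export
checkOverlaps <- function(rve, gap = NULL) {
  stopifnot(is(rve, "AxonRVE"))
  if (is.null(gap)) gap <- rve@minGap
  .rveOverlapFree(rve@tubes, rve@box, gap)
}

#' Round-trip validation of a generated volume
#'
#' Closes the loop the generator is built for: voxelises the volume (full
#' periodic grid for volume fraction and density; per-axon grids for the
#' morphometry) and re-measures it with the perpendicular-plane
#' measurement stage, returning the achieved tract statistics together
#' with the per-axon measurement table.
#'
#' @param rve an [AxonRVE-class].
#' @param voxelSize voxel spacing for the re-measurement, um.
#' @param stationStride stride for cross-section stations (tortuosity uses
#'   every slice regardless); default 3 for tractable runtimes.
#' @param measureAxons measure at most this many axons (all by default);
#'   volume fraction and density always use all.
#' @return a list with `stats` ([TractStats-class] of measured values),
#'   `axons` (per-axon data.frame), `volumeFraction`, `density`,
#'   `axonCount`.
#' @export
validateRVE <- function(rve, voxelSize = c(0.02, 0.02, 0.15),
                        stationStride = 3L, measureAxons = Inf) {
  stopifnot(is(rve, "AxonRVE"))
  full <- voxeliseRVE(rve, voxelSize = voxelSize)
  vf <- volumeFraction(full)
  N <- length(rve@tubes)
  dens <- axonalDensity(N, prod(rve@box))
  ids <- seq_len(N)
  if (is.finite(measureAxons) && measureAxons < N)
    ids <- ids[seq_len(measureAxons)]
  rows <- list(); stRows <- list()
  for (i in ids) {
    sub <- voxeliseTube(rve, i, voxelSize = voxelSize)
    m <- measureVolume(sub, spacing = rve@stationSpacing,
                       stationStride = stationStride)
    rows[[length(rows) + 1L]] <- m$axons
    stRows[[length(stRows) + 1L]] <- m$stations
  }
  ax <- do.call(rbind, rows)
  stTab <- do.call(rbind, stRows)
  lmu <- mean(log(ax$mean_area))
  lsd <- sqrt(mean((log(ax$mean_area) - lmu)^2))
  dmu <- mean(log(ax$mean_diameter))
  dsd <- sqrt(mean((log(ax$mean_diameter) - dmu)^2))
  st <- TractStats(
    tract = paste0(rve@achievedStats@tract, " (measured)"),
    areaMu = lmu, areaSigma = max(lsd, 1e-6),
    diameterMu = dmu, diameterSigma = max(dsd, 1e-6),
    ellipticityMin = min(ax$mean_ellipticity),
    ellipticityMax = max(ax$mean_ellipticity),
    tortuosityMean = mean(ax$tortuosity),
    tortuositySd = max(stats::sd(ax$tortuosity), 0),
    axonalDensity = dens, volumeFraction = vf,
    volumeFractionSd = rve@achievedStats@volumeFractionSd,
    interlayerAreaCv = rve@achievedStats@interlayerAreaCv,
    interlayerSemiaxisDelta = rve@achievedStats@interlayerSemiaxisDelta)
  list(stats = st, axons = ax, stations = stTab, volumeFraction = vf,
       density = dens, axonCount = N)
}
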