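# Fixture builders shared across the suite. Everything is generated in
# code at test time; no stored data.

# Voxelised circular cylinder through the box centre, axis tilted by
# `alpha` (radians) in the x-z plane. Isotropic voxels by default so
# trilinear interpolation is equally resolved in every direction.
makeCylinderVolume <- function(alpha, r = 0.5, vox = c(0.02, 0.02, 0.02),
                               box = c(4, 4, 4)) {
  d <- round(box / vox)
  xs <- (seq_len(d[1L]) - 0.5) * vox[1L]
  ys <- (seq_len(d[2L]) - 0.5) * vox[2L]
  zs <- (seq_len(d[3L]) - 0.5) * vox[3L]
  t <- c(sin(alpha), 0, cos(alpha))
  c0 <- box / 2
  lab <- array(0L, d)
  px <- matrix(xs - c0[1L], d[1L], d[2L])
  py <- matrix(rep(ys - c0[2L], each = d[1L]), d[1L], d[2L])
  for (k in seq_along(zs)) {
    pz <- zs[k] - c0[3L]
    dt <- px * t[1L] + py * t[2L] + pz * t[3L]
    qx <- px - dt * t[1L]; qy <- py - dt * t[2L]; qz <- pz - dt * t[3L]
    sl <- lab[, , k]
    sl[qx^2 + qy^2 + qz^2 <= r^2] <- 1L
    lab[, , k] <- sl
  }
  LabelVolume(lab, voxelSize = vox)
}

# Straight axis-aligned circular tube as an anisotropic label volume.
makeStraightTubeVolume <- function(r = 0.5, box = c(3, 3, 15),
                                   vox = c(0.02, 0.02, 0.15)) {
  makeCylinderVolume(0, r = r, vox = vox, box = box)
}

# A small, quick tract parameter set: same shapes as the corpus callosum
# preset but at reduced density so tiny boxes hold a handful of axons.
smallTractParams <- function(vf = 0.35, tau = 0.05) {
  ts <- tractPreset("CC")
  TractStats(tract = "test",
             areaMu = ts@areaMu, areaSigma = ts@areaSigma,
             diameterMu = ts@diameterMu, diameterSigma = ts@diameterSigma,
             ellipticityMin = 0.6, ellipticityMax = 0.9,
             tortuosityMean = tau, tortuositySd = 0.05,
             axonalDensity = 2.0e7,
             volumeFraction = vf, volumeFractionSd = 0.12)
}

# Number of 26-connected components among the voxels of one label.
count26Components <- function(vol, id) {
  d <- dim(labels3d(vol))
  idx <- which(labels3d(vol) == id)
  if (length(idx) == 0L) return(0L)
  inSet <- logical(prod(d))
  inSet[idx] <- TRUE
  seen <- logical(prod(d))
  ai <- arrayInd(idx, d)
  enc <- function(i, j, k) (k - 1L) * d[1L] * d[2L] + (j - 1L) * d[1L] + i
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0L, ]
  comp <- 0L
  for (s in seq_len(nrow(ai))) {
    st <- enc(ai[s, 1L], ai[s, 2L], ai[s, 3L])
    if (seen[st]) next
    comp <- comp + 1L
    queue <- s
    seen[st] <- TRUE
    head <- 1L
    frontier <- ai[s, , drop = FALSE]
    while (nrow(frontier) > 0L) {
      nxt <- NULL
      for (q in seq_len(nrow(frontier))) {
        nb <- sweep(off, 2L, as.integer(frontier[q, ]), "+")
        ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] &
          nb[, 2L] >= 1L & nb[, 2L] <= d[2L] &
          nb[, 3L] >= 1L & nb[, 3L] <= d[3L]
        nb <- nb[ok, , drop = FALSE]
        if (nrow(nb) == 0L) next
        ee <- enc(nb[, 1L], nb[, 2L], nb[, 3L])
        keep <- inSet[ee] & !seen[ee]
        if (any(keep)) {
          seen[ee[keep]] <- TRUE
          nxt <- rbind(nxt, nb[keep, , drop = FALSE])
        }
      }
      frontier <- if (is.null(nxt)) matrix(0L, 0L, 3L) else nxt
    }
  }
  comp
}

# Polyline circle arc (n x 3) for tortuosity closed forms.
arcPolyline <- function(fraction, r = 1, n = 4000L) {
  th <- seq(0, 2 * pi * fraction, length.out = n)
  cbind(r * cos(th), r * sin(th), 0)
}
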