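# 3D morphometry: centerlines, stations, perpendicular cross-sections,
# shape descriptors, tract aggregates.

test_that("centerline of a straight tube is the tube axis", {
  vol <- makeStraightTubeVolume(r = 0.4, box = c(3, 3, 6))
  cl <- extractCenterline(vol, 1)
  p <- clPoints(cl)
  expect_lt(max(abs(p[, 1] - 1.5)), 0.02)
  expect_lt(max(abs(p[, 2] - 1.5)), 0.02)
  expect_equal(arcLength(cl), max(p[, 3]) - min(p[, 3]), tolerance = 1e-9)
})

test_that("helical centerline recovers the analytic arc length", {
  # helix radius 0.5, pitch 10; gentle enough that 5-station smoothing
  # keeps the lateral excursion
  vox <- c(0.02, 0.02, 0.15)
  d <- c(150, 150, 60)
  lab <- array(0L, d)
  R <- 0.5; P <- 10; r <- 0.25
  xs <- (seq_len(d[1]) - 0.5) * vox[1]
  ys <- (seq_len(d[2]) - 0.5) * vox[2]
  for (k in seq_len(d[3])) {
    z <- (k - 0.5) * vox[3]
    cx <- 1.5 + R * cos(2 * pi * z / P)
    cy <- 1.5 + R * sin(2 * pi * z / P)
    sl <- lab[, , k]
    sl[outer(xs - cx, ys - cy, function(a, b) a^2 + b^2) <= r^2] <- 1L
    lab[, , k] <- sl
  }
  vol <- LabelVolume(lab, voxelSize = vox)
  cl <- extractCenterline(vol, 1)
  zspan <- diff(range(clPoints(cl)[, 3]))
  analytic <- zspan * sqrt(1 + (2 * pi * R / P)^2)
  expect_lt(abs(arcLength(cl) / analytic - 1), 0.03)
})

test_that("two-slice axons give two-point centerlines, one-slice errors", {
  lab <- array(0L, c(10, 10, 3))
  lab[4:6, 4:6, 1:2] <- 1L
  lab[2, 2, 1] <- 2L
  vol <- LabelVolume(lab, voxelSize = c(0.1, 0.1, 0.3))
  cl <- extractCenterline(vol, 1)
  expect_identical(nrow(clPoints(cl)), 2L)
  expect_equal(arcLength(cl), 0.3)
  expect_error(extractCenterline(vol, 2), "single slice")
})

test_that("station sampling trims ends and spaces by arc length", {
  cl <- Centerline(cbind(seq(0, 1.5, length.out = 151), 0, 0))
  st <- sampleStations(cl, spacing = 0.15)
  expect_identical(nrow(st$points), 9L)
  expect_true(all(abs(st$tangents[, 1] - 1) < 1e-9))
  expect_error(sampleStations(cl, spacing = 0.8), "arc length")
  # quarter-circle arc: tangents perpendicular to the radius within 2 deg
  arc <- Centerline(arcPolyline(0.25, r = 2))
  sta <- sampleStations(arc, spacing = 0.15)
  for (i in seq_len(nrow(sta$points))) {
    rad <- sta$points[i, ] / sqrt(sum(sta$points[i, ]^2))
    ang <- abs(90 - acos(abs(sum(rad * sta$tangents[i, ]))) * 180 / pi)
    expect_lt(abs(sum(rad * sta$tangents[i, ])), sin(2 * pi / 180))
  }
})

test_that("perpendicular-plane sections cancel the slice-angle distortion", {
  r <- 0.5
  for (alphaDeg in c(0, 15, 30, 45)) {
    alpha <- alphaDeg * pi / 180
    vol <- makeCylinderVolume(alpha, r = r)
    t <- c(sin(alpha), 0, cos(alpha))
    perp <- sectionArea(
      crossSection(vol, 1, point = c(2, 2, 2), tangent = t)$polygon,
      check = FALSE)
    expect_lt(abs(perp / (pi * r^2) - 1), 0.02)
    imaging <- sectionArea(
      crossSection(vol, 1, point = c(2, 2, 2),
                   tangent = c(0, 0, 1))$polygon, check = FALSE)
    expect_lt(abs(imaging / (pi * r^2 / cos(alpha)) - 1), 0.02)
  }
})

test_that("cross-section errors on planes that miss the axon", {
  vol <- makeCylinderVolume(0, r = 0.3, box = c(2, 2, 2))
  # plane entirely above the axon's extent: genuinely empty intersection
  expect_error(
    crossSection(vol, 1, point = c(1, 1, 5), tangent = c(0, 0, 1),
                 halfWidth = 0.5),
    "empty intersection")
})

test_that("section area is the shoelace area with degeneracy checks", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(sectionArea(sq), 1)
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  hexa <- cbind(cos(th), sin(th))
  expect_equal(sectionArea(hexa), 3 * sqrt(3) / 2, tolerance = 1e-12)
  expect_error(sectionArea(rbind(c(0, 0), c(1, 1), c(2, 2))), "degenerate")
  # asymmetric bow-tie: non-zero shoelace area but crossing edges
  bow <- rbind(c(0, 0), c(3, 2), c(3, 0), c(0, 1))
  expect_error(sectionArea(bow), "self-intersecting")
})

test_that("best-fit diameter is the equal-area circle diameter", {
  expect_equal(bestFitDiameter(pi), 2)
  expect_equal(round(bestFitDiameter(1), 4), 1.1284)
  expect_equal(bestFitDiameter(0.63), 2 * sqrt(0.63 / pi))
  expect_equal(round(bestFitDiameter(0.63), 3), 0.896)
  expect_error(bestFitDiameter(0), "positive")
})

test_that("moment ellipse fit recovers semi-axes, rotation invariant", {
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  circ <- cbind(cos(th), sin(th))
  ab <- fitEllipse(circ)
  expect_lt(abs(ab[["a"]] - 1), 0.01)
  expect_lt(abs(ab[["b"]] - 1), 0.01)
  ell <- cbind(cos(th), 0.5 * sin(th))
  ab2 <- fitEllipse(ell)
  expect_lt(abs(ab2[["a"]] - 1), 0.01)
  expect_lt(abs(ab2[["b"]] - 0.5), 0.005)
  for (ang in c(0.3, 1.1, 2.6)) {
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
    abr <- fitEllipse(ell %*% t(R))
    expect_equal(unname(abr), unname(ab2), tolerance = 1e-9)
  }
  expect_error(fitEllipse(rbind(c(0, 0), c(1, 0), c(1, 1))), "5 vertices")
})

test_that("ellipticity anchors and tortuosity closed forms hold", {
  expect_equal(ellipticity(1, 1), 0)
  expect_equal(ellipticity(2, 1), 1)
  expect_equal(ellipticity(1.75, 1), 0.75)
  expect_error(ellipticity(1, 0), "positive")
  # straight segment
  expect_equal(tortuosity(Centerline(cbind(0:10, 0, 0))), 0)
  # semicircle: 1 - 2/pi
  expect_equal(tortuosity(Centerline(arcPolyline(0.5))), 1 - 2 / pi,
               tolerance = 1e-6)
  # quarter circle: 1 - 2*sqrt(2)/pi
  expect_equal(tortuosity(Centerline(arcPolyline(0.25))),
               1 - 2 * sqrt(2) / pi, tolerance = 1e-6)
  # invariance under rigid motion and uniform scaling
  arc <- arcPolyline(0.5)
  R <- matrix(c(0.36, 0.48, -0.8, -0.8, 0.6, 0, 0.48, 0.64, 0.6), 3)
  moved <- 3.7 * arc %*% R + rep(c(5, -2, 1), each = nrow(arc))
  expect_equal(tortuosity(Centerline(moved)),
               tortuosity(Centerline(arc)), tolerance = 1e-9)
})

test_that("density and volume fraction are plain ratios", {
  expect_equal(axonalDensity(67, 15^3), 67 / 3375 * 1e9)
  expect_equal(signif(axonalDensity(67, 15^3), 3), 1.99e7)
  expect_equal(axonalDensity(0, 1000), 0)
  expect_equal(axonalDensity(10, 2000), axonalDensity(10, 1000) / 2)
  lab <- array(0L, c(4, 4, 4))
  expect_equal(volumeFraction(LabelVolume(lab)), 0)
  lab[] <- 1L
  expect_equal(volumeFraction(LabelVolume(lab)), 1)
  lab[1:2, , ] <- 0L
  expect_equal(volumeFraction(LabelVolume(lab)), 0.5)
})

test_that("measureVolume closes the loop on a straight axon", {
  vol <- makeStraightTubeVolume(r = 0.5, box = c(3, 3, 15))
  m <- measureVolume(vol)
  expect_identical(nrow(m$axons), 1L)
  expect_lt(abs(m$axons$volume / (15 * pi * 0.25) - 1), 0.05)
  expect_lt(abs(m$axons$mean_area / (pi * 0.25) - 1), 0.02)
  expect_lt(m$axons$tortuosity, 1e-3)
  expect_lt(m$axons$mean_ellipticity, 0.05)
  expect_equal(m$density, axonalDensity(1, prod(dim(labels3d(vol)) *
                                                voxelSize(vol))))
  expect_equal(m$volumeFraction, volumeFraction(vol))
})
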