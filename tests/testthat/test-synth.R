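# 2D and 3D phantom generators: ground-truth bookkeeping, determinism,
# corruption ordering, voxelisation fidelity.

test_that("empty phantom configuration yields a uniform background", {
  cfg <- phantom2DConfig(width = 64, height = 64, myelinFraction = 0,
                         ringCount = 0, gliaBlobCount = 0, seed = 1)
  ph <- generatePhantomImage(cfg)
  expect_equal(ph$truth$trueWhiteFraction, 0)
  expect_false(any(pixels(ph$truth$myelinMask)))
  # background texture only: everything near the 30% background level
  expect_lt(diff(range(pixels(ph$image))), 0.25)
})

test_that("phantom hits the configured myelin fraction within 0.02", {
  for (fr in c(0.25, 0.40)) {
    ph <- generatePhantomImage(phantom2DConfig(
      width = 320, height = 320, myelinFraction = fr, seed = 1))
    expect_lt(abs(ph$truth$trueWhiteFraction - fr), 0.02)
    # exact bookkeeping of the truth fraction
    expect_identical(ph$truth$trueWhiteFraction,
                     mean(pixels(ph$truth$myelinMask)))
  }
})

test_that("phantom generation is a pure function of config and seed", {
  cfg <- phantom2DConfig(width = 128, height = 128, myelinFraction = 0.3,
                         impulseNoiseFraction = 0.05,
                         illuminationGradientAmplitude = 0.2, seed = 99)
  a <- generatePhantomImage(cfg)
  b <- generatePhantomImage(cfg)
  expect_identical(pixels(a$image), pixels(b$image))
  expect_identical(pixels(a$truth$myelinMask), pixels(b$truth$myelinMask))
  d <- generatePhantomImage(phantom2DConfig(width = 128, height = 128,
    myelinFraction = 0.3, impulseNoiseFraction = 0.05,
    illuminationGradientAmplitude = 0.2, seed = 100))
  expect_false(identical(pixels(a$image), pixels(d$image)))
})

test_that("corruption is applied after truth capture", {
  cfg <- phantom2DConfig(width = 128, height = 128, myelinFraction = 0.3,
                         impulseNoiseFraction = 0.04,
                         illuminationGradientAmplitude = 0, seed = 7)
  ph <- generatePhantomImage(cfg)
  diffPix <- pixels(ph$image) != pixels(ph$clean)
  # only the impulse-hit pixels differ, and they sit at the rails
  expect_lt(mean(diffPix), 0.05)
  expect_true(all(pixels(ph$image)[diffPix] %in% c(0, 1)))
})

test_that("unreachable myelin fraction fails with the achievable range", {
  cfg <- phantom2DConfig(width = 96, height = 96, myelinFraction = 0.5,
                         ringCount = 2, seed = 1)
  expect_error(generatePhantomImage(cfg), "unreachable|achiev")
})

test_that("phantom volume voxelisation conserves analytic tube volume", {
  # one straight axis-aligned circular axon, radius 0.5 um
  vol <- makeStraightTubeVolume(r = 0.5, box = c(3, 3, 6))
  vtube <- sum(labels3d(vol) == 1L) * prod(voxelSize(vol))
  expect_lt(abs(vtube / (pi * 0.25 * 6) - 1), 0.05)
})

test_that("phantom volumes are deterministic and topologically sound", {
  ts <- smallTractParams()
  cfg <- phantom3DConfig(ts, box = c(4, 4, 4), seed = 11)
  a <- generatePhantomVolume(cfg)
  b <- generatePhantomVolume(cfg)
  expect_identical(labels3d(a$volume), labels3d(b$volume))
  ids <- setdiff(unique(as.vector(labels3d(a$volume))), 0L)
  expect_gte(length(ids), 1L)
  # per-axon truth is returned for every tube
  expect_length(a$truth, length(tubes(a$rve)))
  # every axon label forms a single 26-connected component (check the
  # unwrapped per-axon voxelisation; the periodic box splits wrapped
  # tubes across the boundary by construction)
  for (id in ids[seq_len(min(3L, length(ids)))]) {
    sub <- voxeliseTube(a$rve, id, voxelSize = voxelSize(a$volume))
    expect_identical(count26Components(sub, id), 1L)
  }
})

test_that("degenerate 3D phantom box errors out", {
  ts <- smallTractParams()
  tiny <- TractStats(tract = "tiny", areaMu = ts@areaMu,
    areaSigma = ts@areaSigma, diameterMu = ts@diameterMu,
    diameterSigma = ts@diameterSigma, ellipticityMin = 0.6,
    ellipticityMax = 0.9, tortuosityMean = 0.08, tortuositySd = 0.05,
    axonalDensity = 1e4, volumeFraction = 0.3, volumeFractionSd = 0.1)
  expect_error(generatePhantomVolume(phantom3DConfig(tiny,
    box = c(2, 2, 2), seed = 1)), "count|small")
})
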