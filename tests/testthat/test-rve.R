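# In silico volume generator: degenerate configs, determinism,
# clearance under periodicity, distribution shape, STL meshing.

test_that("degenerate config yields one straight elliptical cylinder", {
  ts <- TractStats(tract = "one", areaMu = log(1.4), areaSigma = 0.9,
    diameterMu = log(1.3), diameterSigma = 0.45,
    ellipticityMin = 0.7, ellipticityMax = 0.7,
    tortuosityMean = 0, tortuositySd = 0,
    axonalDensity = 1.6e7, volumeFraction = 0.05,
    volumeFractionSd = 0.04, interlayerAreaCv = 0,
    interlayerSemiaxisDelta = 0.05)
  rve <- generateRVE(rveConfig(ts, box = c(4, 4, 4), seed = 2,
                               axonJitterMax = 0))
  expect_length(tubes(rve), 1L)
  tb <- tubes(rve)[[1]]
  expect_lt(diff(range(tb$cx)), 1e-9)
  expect_lt(diff(range(tb$a)), 1e-9)
  expect_equal(tb$a[1] / tb$b[1] - 1, 0.7, tolerance = 1e-9)
  expect_equal(achievedStats(rve)@tortuosityMean, 0, tolerance = 1e-12)
  # box too small for one axon at the stated density
  expect_error(generateRVE(rveConfig(ts, box = c(1, 1, 1), seed = 2)),
               "box too small")
})

test_that("generation is deterministic in the seed", {
  cfg <- rveConfig(smallTractParams(), box = c(5, 5, 5), seed = 8)
  a <- generateRVE(cfg)
  b <- generateRVE(cfg)
  expect_equal(tubes(a), tubes(b))
  c2 <- generateRVE(rveConfig(smallTractParams(), box = c(5, 5, 5),
                              seed = 9))
  expect_false(isTRUE(all.equal(
    tubes(a)[[1]]$cx, tubes(c2)[[1]]$cx)))
})

test_that("clearance holds at every station, periodic images included", {
  rve <- generateRVE(rveConfig(smallTractParams(vf = 0.40),
                               box = c(6, 6, 6), seed = 13))
  expect_true(checkOverlaps(rve))
  expect_true(checkOverlaps(rve, gap = 0))   # weaker gap also clear
  # targets met
  s <- achievedStats(rve)
  expect_lt(abs(s@volumeFraction - 0.40), 0.12)
  expect_lt(abs(s@tortuosityMean - 0.05), 0.02)
  # every tube spans the full z extent
  nz <- length(tubes(rve)[[1]]$z)
  for (tb in tubes(rve)) expect_identical(length(tb$z), nz)
})

test_that("loosening the gap never makes a feasible config infeasible", {
  base <- rveConfig(smallTractParams(vf = 0.40), box = c(6, 6, 6),
                    seed = 21, minGap = 0.02)
  expect_s4_class(generateRVE(base), "AxonRVE")
  loose <- rveConfig(smallTractParams(vf = 0.40), box = c(6, 6, 6),
                     seed = 21, minGap = 0)
  expect_s4_class(generateRVE(loose), "AxonRVE")
})

test_that("per-axon areas keep the tract's lognormal shape", {
  # the volume-fraction rescale shifts location, not shape: pooled,
  # per-seed-demeaned log areas should match the input sigma
  ts <- smallTractParams(vf = 0.35)
  pooled <- unlist(lapply(1:6, function(sd) {
    rve <- generateRVE(rveConfig(ts, box = c(6, 6, 6), seed = sd))
    la <- log(vapply(tubes(rve), function(tb) mean(pi * tb$a * tb$b), 1))
    la - mean(la)
  }))
  expect_gt(length(pooled), 20)
  expect_lt(abs(sd(pooled) / ts@areaSigma - 1), 0.35)
})

test_that("round-trip measurement matches the generated geometry", {
  rve <- generateRVE(rveConfig(smallTractParams(vf = 0.35),
                               box = c(6, 6, 6), seed = 5))
  val <- validateRVE(rve, stationStride = 4L)
  expect_identical(val$axonCount, length(tubes(rve)))
  expect_identical(nrow(val$axons), length(tubes(rve)))
  # volume fraction measured on the voxel grid matches the analytic value
  expect_lt(abs(val$volumeFraction -
                achievedStats(rve)@volumeFraction), 0.01)
  # per-axon mean area within 5% of generated truth for every axon
  genA <- vapply(tubes(rve), function(tb) mean(pi * tb$a * tb$b), 1)
  relerr <- val$axons$mean_area / genA[val$axons$axon_id] - 1
  expect_lt(max(abs(relerr)), 0.05)
  # measured tortuosity mean tracks the generated paths
  expect_lt(abs(val$stats@tortuosityMean -
                achievedStats(rve)@tortuosityMean), 0.01)
})

test_that("STL meshes are watertight with correct enclosed volumes", {
  # single straight elliptical tube: closed-form volume
  ts <- TractStats(tract = "one", areaMu = log(1.4), areaSigma = 0.9,
    diameterMu = log(1.3), diameterSigma = 0.45,
    ellipticityMin = 0, ellipticityMax = 1e-9,
    tortuosityMean = 0, tortuositySd = 0,
    axonalDensity = 1.6e7, volumeFraction = 0.05,
    volumeFractionSd = 0.04, interlayerAreaCv = 0,
    interlayerSemiaxisDelta = 0.05)
  rve1 <- generateRVE(rveConfig(ts, box = c(4, 4, 4), seed = 3,
                                axonJitterMax = 0))
  dir1 <- withr::local_tempdir()
  info1 <- exportSTL(rve1, dir1)
  tb <- tubes(rve1)[[1]]
  expect_lt(abs(info1$mesh_volume /
                (pi * tb$a[1] * tb$b[1] * 4) - 1), 0.01)
  tri <- readSTL(info1$file[1])
  chk <- meshIsClosed(tri)
  expect_true(chk$closed)
  expect_equal(chk$eulerPerShell, 2)
  # a packed volume: every per-axon mesh closed, total volume matches
  # the achieved volume fraction on re-read
  rve <- generateRVE(rveConfig(smallTractParams(vf = 0.35),
                               box = c(5, 5, 5), seed = 6))
  dir2 <- withr::local_tempdir()
  info <- exportSTL(rve, dir2)
  for (fn in info$file) {
    ck <- meshIsClosed(readSTL(fn))
    expect_true(ck$closed)
    expect_equal(ck$eulerPerShell, 2)
  }
  vfSTL <- sum(vapply(info$file, function(fn)
    meshVolume(readSTL(fn)), 1)) / prod(rve@box)
  expect_lt(abs(vfSTL / achievedStats(rve)@volumeFraction - 1), 0.02)
})

test_that("periodic wrap conserves every tube's in-box voxel count", {
  rve <- generateRVE(rveConfig(smallTractParams(vf = 0.35),
                               box = c(5, 5, 5), seed = 7))
  full <- voxeliseRVE(rve, voxelSize = c(0.04, 0.04, 0.15))
  for (i in seq_along(tubes(rve))) {
    nFull <- sum(labels3d(full) == i)
    sub <- voxeliseTube(rve, i, voxelSize = c(0.04, 0.04, 0.15))
    nSub <- sum(labels3d(sub) == i)
    expect_lt(abs(nFull / nSub - 1), 0.02)
  }
})

test_that("tract presets reproduce the published parameter sets", {
  cc <- tractPreset("CC")
  expect_equal(exp(cc@areaMu), 1.42)
  expect_equal(exp(cc@areaMu - cc@areaSigma^2), 0.63, tolerance = 1e-12)
  expect_equal(exp(cc@diameterMu), 1.35)
  expect_equal(cc@tortuosityMean, 0.113)
  expect_equal(cc@axonalDensity, 2e7)
  expect_equal(cc@volumeFraction, 0.45)
  fo <- tractPreset("fo")
  expect_equal(fo@ellipticityMin, 0.7)
  expect_equal(fo@volumeFraction, 0.51)
  expect_equal(exp(fo@diameterMu - fo@diameterSigma^2), 1.41,
               tolerance = 1e-12)
  expect_error(tractPreset("XX"))
})
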