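# 2D myelin pipeline: filter semantics, morphology properties, adaptive
# binarisation, white-pixel frequency, homogeneity check, round trips.

test_that("3x3 median filter matches direct median computation", {
  # constant image unchanged
  cst <- SEMImage(matrix(0.4, 8, 8))
  expect_equal(pixels(medianFilter3x3(cst)), matrix(0.4, 8, 8))
  # single white pixel in black field vanishes
  m <- matrix(0, 9, 9); m[5, 5] <- 1
  expect_equal(max(pixels(medianFilter3x3(SEMImage(m)))), 0)
  # 3x3 raster of 1..9 (scaled): centre pixel becomes the median 5
  m3 <- matrix(1:9 / 10, 3, 3)
  out <- pixels(medianFilter3x3(SEMImage(m3)))
  expect_equal(out[2, 2], 0.5)
  # mirror padding: corner neighbourhood of the 3x3 case is
  # {1,1,2,2,4,4,5,5,1} scaled -> median 0.2
  expect_equal(out[1, 1], 0.2)
})

test_that("opening removes sub-element features and is idempotent", {
  m <- matrix(0, 32, 32); m[16, 16] <- 1
  img <- SEMImage(m)
  expect_equal(max(pixels(morphologicalOpen(img, 1))), 0)
  # solid disk of radius 10 survives opening with radius 3 (interior)
  xs <- row(m) - 16; ys <- col(m) - 16
  disk <- (xs^2 + ys^2 <= 100) * 1
  op <- pixels(morphologicalOpen(SEMImage(disk), 3))
  inner <- (xs^2 + ys^2 <= 49)
  expect_true(all(op[inner] == 1))
  # idempotence, greyscale and binary
  set.seed(1)
  g <- SEMImage(matrix(runif(1024), 32, 32))
  once <- morphologicalOpen(g, 2)
  expect_equal(pixels(morphologicalOpen(once, 2)), pixels(once),
               tolerance = 1e-12)
  bin <- BinaryImage(matrix(runif(1024) > 0.6, 32, 32))
  bonce <- morphologicalOpen(bin, 1)
  expect_identical(pixels(morphologicalOpen(bonce, 1)), pixels(bonce))
  expect_error(morphologicalOpen(g, 40), "larger")
})

test_that("background estimation is anti-extensive and recovers flats", {
  flat <- SEMImage(matrix(0.3, 64, 64))
  expect_equal(pixels(estimateBackground(flat, 10)), pixels(flat),
               tolerance = 1e-12)
  # flat background + one bright annulus: opening erases the annulus
  m <- matrix(0.3, 128, 128)
  xs <- row(m) - 64; ys <- col(m) - 64
  ring <- xs^2 + ys^2 <= 20^2 & xs^2 + ys^2 >= 12^2
  m[ring] <- 0.8
  bg <- pixels(estimateBackground(SEMImage(m), 25))
  expect_lt(max(abs(bg - 0.3)), 0.02)
  expect_true(all(bg <= m + 1e-12))
})

test_that("background subtraction clamps at zero", {
  a <- SEMImage(matrix(runif(64), 8, 8))
  expect_equal(max(pixels(subtractBackground(a, a))), 0)
  zero <- SEMImage(matrix(0, 8, 8))
  expect_equal(pixels(subtractBackground(a, zero)), pixels(a))
  b <- SEMImage(matrix(0.5, 9, 9))
  expect_error(subtractBackground(a, b), "shape")
})

test_that("adaptive binarisation follows its threshold conventions", {
  # constant image: no pixel strictly exceeds its local threshold
  cst <- SEMImage(matrix(0.5, 32, 32))
  expect_false(any(pixels(adaptiveBinarise(cst, window = 5))))
  # step edge: the white/black transition sits exactly at the step.
  # A local-mean threshold can only mark pixels whose window spans the
  # step, so the white set is the bright stripe along the edge; its dark
  # boundary recovers the true step location within one pixel.
  # dyadic levels keep the integral-image means exact, so the strict
  # tie convention is observable
  m <- matrix(0.25, 64, 64); m[33:64, ] <- 0.75
  bin <- pixels(adaptiveBinarise(SEMImage(m), window = 9,
                                 sensitivity = 1, offset = 0))
  expect_true(all(bin[33:36, ]))     # bright side of the edge
  expect_false(any(bin[1:32, ]))     # dark side stays black
  expect_false(any(bin[40:64, ]))    # deep bright interior ties to black
  # binary 0/max image keeps its white set (sensitivity 1, small floor)
  set.seed(2)
  bm <- matrix(as.numeric(runif(1024) > 0.5), 32, 32)
  out <- pixels(adaptiveBinarise(SEMImage(bm), window = 5,
                                 sensitivity = 1, offset = 0.05))
  expect_identical(out, bm > 0.5)
  expect_error(adaptiveBinarise(SEMImage(bm), window = 4), "odd")
  expect_error(adaptiveBinarise(SEMImage(bm), window = 65), "larger")
})

test_that("white-pixel frequency is a plain ratio with monotone growth", {
  all1 <- BinaryImage(matrix(TRUE, 8, 8))
  expect_equal(whitePixelFrequency(all1), 1)
  chk <- BinaryImage(outer(1:8, 1:8, function(i, j) (i + j) %% 2 == 0))
  expect_equal(whitePixelFrequency(chk), 0.5)
  # adding white pixels never decreases the frequency
  set.seed(3)
  m <- matrix(runif(400) > 0.7, 20, 20)
  f0 <- whitePixelFrequency(BinaryImage(m))
  m2 <- m; m2[which(!m2)[1:10]] <- TRUE
  expect_gte(whitePixelFrequency(BinaryImage(m2)), f0)
})

test_that("pipeline recovers phantom truth within tolerance", {
  # clean phantom at 40%
  ph <- generatePhantomImage(phantom2DConfig(width = 320, height = 320,
    myelinFraction = 0.40, seed = 5))
  r <- quantifyMyelin(ph$image)
  expect_lt(abs(r$white_fraction - ph$truth$trueWhiteFraction), 0.02)
  # corrupted phantom: 5% impulse noise + 20% illumination gradient
  phc <- generatePhantomImage(phantom2DConfig(width = 320, height = 320,
    myelinFraction = 0.40, impulseNoiseFraction = 0.05,
    illuminationGradientAmplitude = 0.2, seed = 5))
  rc <- quantifyMyelin(phc$image)
  expect_lt(abs(rc$white_fraction - phc$truth$trueWhiteFraction), 0.03)
  # all-background phantom stays near zero
  ph0 <- generatePhantomImage(phantom2DConfig(width = 320, height = 320,
    myelinFraction = 0, ringCount = 0, gliaBlobCount = 0,
    impulseNoiseFraction = 0.05, seed = 5))
  r0 <- quantifyMyelin(ph0$image)
  expect_lte(r0$white_fraction, 0.01)
  # determinism of the whole pipeline
  expect_identical(quantifyMyelin(phc$image)$white_fraction,
                   rc$white_fraction)
})

test_that("round-trip accuracy holds across fractions with corruption", {
  errs <- unlist(lapply(c(0.2, 0.3, 0.4, 0.5), function(fr) {
    vapply(1:2, function(sd) {
      ph <- generatePhantomImage(phantom2DConfig(width = 320,
        height = 320, myelinFraction = fr, impulseNoiseFraction = 0.05,
        illuminationGradientAmplitude = 0.2, seed = sd))
      quantifyMyelin(ph$image)$white_fraction -
        ph$truth$trueWhiteFraction
    }, 1)
  }))
  expect_lte(mean(abs(errs)), 0.03)
})

test_that("homogeneity summary implements the largest-SD criterion", {
  # identical fractions: all SDs zero, criterion holds
  same <- data.frame(subsample = rep(c("a", "b"), each = 2),
                     white_fraction = rep(0.4, 4))
  hs <- homogeneitySummary(same)
  expect_true(hs$withinLargestSd)
  expect_equal(unname(hs$perSubsampleSd), c(0, 0))
  # one group displaced by 10x the largest SD: criterion fails
  far <- data.frame(
    subsample = rep(c("a", "b", "c"), each = 2),
    white_fraction = c(0.40, 0.42, 0.41, 0.39, 0.60, 0.62))
  expect_false(homogeneitySummary(far)$withinLargestSd)
  # hand-computed oracle: three groups
  g <- data.frame(subsample = rep(c("a", "b", "c"), each = 2),
                  white_fraction = c(0.40, 0.42, 0.39, 0.41, 0.38, 0.44))
  hg <- homogeneitySummary(g)
  expect_equal(round(hg$grandMean, 4), 0.4067)
  # by hand: means 0.41, 0.40, 0.41; sds 0.0141, 0.0141, 0.0424;
  # max |mean - grand| = 0.0067 < 0.0424
  expect_true(hg$withinLargestSd)
  expect_error(homogeneitySummary(
    data.frame(subsample = c("a", "a", "b"),
               white_fraction = c(0.4, 0.41, 0.4))), ">= 2")
})
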