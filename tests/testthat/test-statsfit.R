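# Lognormal machinery: closed-form MLE, derived descriptors, printed-pair
# inversion, moment agreement, Q-Q construction, density histograms.

test_that("lognormal MLE recovers parameters and derived values", {
  set.seed(10)
  x <- rlnorm(50000, 0, 1)
  f <- fitLognormal(x)
  expect_lt(abs(f@mode / exp(-1) - 1), 0.05)
  expect_lt(abs(f@median / 1 - 1), 0.02)
  # internal identities
  expect_equal(f@mode, exp(f@mu - f@sigma^2))
  expect_equal(f@arithMean, exp(f@mu + f@sigma^2 / 2))
  expect_true(f@mode < f@median && f@median < f@arithMean)
  # cross-check against an independent MLE implementation
  if (requireNamespace("fitdistrplus", quietly = TRUE)) {
    ref <- fitdistrplus::fitdist(x[1:5000], "lnorm")
    f2 <- fitLognormal(x[1:5000])
    expect_equal(unname(ref$estimate[["meanlog"]]), f2@mu,
                 tolerance = 1e-4)
    expect_equal(unname(ref$estimate[["sdlog"]]), f2@sigma,
                 tolerance = 1e-3)
  }
  expect_error(fitLognormal(rep(2, 100)), "sigma")
  expect_error(fitLognormal(c(x[1:20], -1)), "positive")
  expect_error(fitLognormal(x[1:5]), "10")
})

test_that("MLE errors shrink at the asymptotic rate", {
  # mu within 3 SE and sigma within 3 SE in >= 99% of replicates
  hits <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    x <- rlnorm(1000, 0.5, 0.8)
    f <- fitLognormal(x)
    seMu <- 0.8 / sqrt(1000)
    seSg <- 0.8 / sqrt(2 * 1000)
    abs(f@mu - 0.5) <= 3 * seMu && abs(f@sigma - 0.8) <= 3 * seSg
  }, TRUE)
  expect_gte(mean(hits), 0.99)
})

test_that("moment-agreement check separates lognormal from pathologies", {
  set.seed(21)
  x <- rlnorm(10000, 0.3, 0.9)
  f <- fitLognormal(x)
  mc <- momentConsistency(x, f)
  expect_true(mc$passes)
  # uniform[1,2] is close to lognormal in its first two moments:
  # the check is insensitive here, and that is documented behaviour
  u <- runif(10000, 1, 2)
  expect_true(momentConsistency(u, fitLognormal(u))$passes)
  # heavy two-point mixture must fail
  m2 <- c(rep(0.1, 5000), rep(10, 5000))
  expect_false(momentConsistency(m2, fitLognormal(m2))$passes)
})

test_that("printed mode/median pairs invert exactly", {
  p <- modeMedianToParams(0.63, 1.42)
  expect_equal(round(unname(p), 4), c(0.3507, 0.9015))
  expect_error(modeMedianToParams(1.42, 0.63), "below")
  expect_error(modeMedianToParams(1, 1), "below")
  # round trip params -> (mode, median) -> params
  for (pm in list(c(0.63, 1.42), c(0.5, 1.35), c(0.98, 2.32),
                  c(1.07, 1.35), c(1.00, 1.30), c(1.41, 1.81))) {
    pp <- modeMedianToParams(pm[1], pm[2])
    mode <- exp(pp[["mu"]] - pp[["sigma"]]^2)
    med <- exp(pp[["mu"]])
    expect_equal(c(mode, med), pm, tolerance = 1e-12)
  }
})

test_that("Q-Q data line up exactly on a perfect quantile grid", {
  n <- 500
  tq <- qnorm((seq_len(n) - 0.5) / n)
  x <- exp(0.4 + 0.9 * tq)
  qq <- qqLognormal(sample(x))
  pred <- qq$referenceLine[["intercept"]] +
    qq$referenceLine[["slope"]] * qq$theoreticalQuantiles
  expect_lt(max(abs(qq$sampleQuantiles - pred)), 1e-6)
  # determinism on a fixed sample
  set.seed(4)
  y <- rlnorm(10)
  expect_identical(qqLognormal(y), qqLognormal(y))
  expect_error(qqLognormal(c(y, -1)), "positive")
  # heavy right-tail contamination bends the top quantiles above the line
  set.seed(5)
  z <- c(rlnorm(2000, 0, 0.5), rlnorm(60, 2.5, 0.3))
  qz <- qqLognormal(z)
  tail <- seq(length(z) - 19, length(z))
  predTail <- qz$referenceLine[["intercept"]] +
    qz$referenceLine[["slope"]] * qz$theoreticalQuantiles[tail]
  expect_true(all(qz$sampleQuantiles[tail] > predTail))
})

test_that("density histograms integrate to one", {
  set.seed(6)
  x <- rlnorm(5000, 0, 0.7)
  h <- densityHistogram(x, 0.1)
  widths <- diff(h$breaks)
  expect_equal(sum(h$density * widths), 1, tolerance = 1e-9)
  # single bin covering everything
  h1 <- densityHistogram(c(0.2, 0.3, 0.4), 1)
  expect_equal(sum(h1$density * diff(h1$breaks)), 1)
  # uniform samples are flat within sampling error
  u <- runif(20000)
  hu <- densityHistogram(u, 0.1)
  expect_lt(max(abs(hu$density - 1)), 0.12)
})

test_that("tract parameter recovery: printed pairs simulate and refit", {
  # every printed (mode, median) pair: simulate 50k, fit, recover
  pairs <- list(c(0.63, 1.42), c(0.5, 1.35), c(0.98, 2.32),
                c(1.07, 1.35), c(1.00, 1.30), c(1.41, 1.81))
  for (i in seq_along(pairs)) {
    p <- modeMedianToParams(pairs[[i]][1], pairs[[i]][2])
    set.seed(3000 + i)
    f <- fitLognormal(rlnorm(50000, p[["mu"]], p[["sigma"]]))
    expect_lt(abs(f@mode / pairs[[i]][1] - 1), 0.05)
    expect_lt(abs(f@median / pairs[[i]][2] - 1), 0.02)
  }
})
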