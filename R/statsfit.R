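#' Maximum-likelihood lognormal fit
#'
#' Closed-form MLE on the log scale: `mu = mean(log x)` and `sigma` the
#' root-mean-square deviation of `log x` (divisor n). The derived
#' descriptive values follow the lognormal identities: mode
#' `exp(mu - sigma^2)`, median `exp(mu)`, arithmetic mean
#' `exp(mu + sigma^2/2)` and arithmetic SD `mean * sqrt(exp(sigma^2) - 1)`.
#' For sigma > 0, mode < median < arithmetic mean always.
#'
#' @param samples positive numeric vector, n >= 10.
#' @return a [LognormalFit-class].
#' @examples
#' set.seed(1)
#' fitLognormal(rlnorm(1000, 0, 1))
#' @export
fitLognormal <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) < 10L) stop("need at least 10 samples")
  if (any(!is.finite(samples)) || any(samples <= 0))
    stop("all samples must be positive and finite")
  lx <- log(samples)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))
  if (sigma <= 0)
    stop("degenerate sample (zero log-scale variance); sigma must be > 0")
  am <- exp(mu + sigma^2 / 2)
  new("LognormalFit", mu = mu, sigma = sigma, n = length(samples),
      mode = exp(mu - sigma^2), median = exp(mu),
      arithMean = am, arithSd = am * sqrt(exp(sigma^2) - 1))
}

#' Arithmetic-moment agreement check for a lognormal fit
#'
#' Compares the arithmetic mean and SD implied by the fitted (mu, sigma)
#' with the mean and SD computed directly from the sample. Agreement of
#' the two sets of numbers is the criterion used to accept the lognormal
#' as a good description of the data.
#'
#' @param samples the fitted sample.
#' @param fit the [LognormalFit-class] computed from `samples`.
#' @param tol relative tolerance; default 0.10.
#' @return a list with `passes` (logical), `relErrMean`, `relErrSd`.
#' @export
momentConsistency <- function(samples, fit, tol = 0.10) {
  stopifnot(is(fit, "LognormalFit"))
  m <- mean(samples)
  s <- stats::sd(samples)
  relM <- abs(fit@arithMean - m) / m
  relS <- abs(fit@arithSd - s) / s
  list(passes = relM <= tol && relS <= tol,
       relErrMean = relM, relErrSd = relS)
}

#' Lognormal parameters from printed mode and median
#'
#' Exact inversion of the mode/median identities: `mu = log(median)`,
#' `sigma = sqrt(log(median / mode))`. Used to rebuild tract-level
#' lognormal parameter sets from the published mode/median pairs.
#'
#' @param mode lognormal mode, 0 < mode < median.
#' @param median lognormal median.
#' @return named numeric `c(mu =, sigma =)`.
#' @examples
#' modeMedianToParams(0.63, 1.42)  # mu 0.3507, sigma 0.9015
#' @export
modeMedianToParams <- function(mode, median) {
  if (mode <= 0 || median <= 0) stop("mode and median must be positive")
  if (mode >= median)
    stop("mode must be strictly below median for a lognormal")
  c(mu = log(median), sigma = sqrt(log(median / mode)))
}

#' Q-Q data of log-transformed samples against the normal
#'
#' If a quantity is lognormal, its logarithm is normal; the Q-Q plot of
#' sorted `log(samples)` against standard-normal quantiles at plotting
#' positions `(i - 0.5)/n` is then a straight line. The reference line is
#' fitted through the quartiles (the `qqline` convention), so data that
#' are exactly a normal quantile grid lie on it exactly.
#'
#' @param samples positive numeric vector, n >= 10.
#' @return a list with `sampleQuantiles` (sorted log values),
#'   `theoreticalQuantiles`, and `referenceLine` (`c(intercept, slope)`).
#' @export
qqLognormal <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) < 10L) stop("need at least 10 samples")
  if (any(samples <= 0)) stop("all samples must be positive")
  lx <- sort(log(samples))
  n <- length(lx)
  tq <- stats::qnorm((seq_len(n) - 0.5) / n)
  qs <- stats::quantile(lx, c(0.25, 0.5, 0.75), names = FALSE)
  qt <- stats::quantile(tq, c(0.25, 0.5, 0.75), names = FALSE)
  slope <- (qs[3L] - qs[1L]) / (qt[3L] - qt[1L])
  list(sampleQuantiles = lx, theoreticalQuantiles = tq,
       referenceLine = c(intercept = qs[2L] - slope * qt[2L],
                         slope = slope))
}

#' Probability-density histogram
#'
#' Histogram normalised so that the density integrates to one
#' (`sum(density * width) == 1`), the scale on which the tract
#' distributions are compared with their fitted lognormals.
#'
#' @param samples numeric vector.
#' @param binWidth positive bin width, data units.
#' @return a list with `breaks` (bin edges) and `density`.
#' @export
densityHistogram <- function(samples, binWidth) {
  stopifnot(binWidth > 0, length(samples) >= 1L)
  lo <- floor(min(samples) / binWidth) * binWidth
  hi <- ceiling(max(samples) / binWidth) * binWidth
  if (hi <= lo) hi <- lo + binWidth
  breaks <- seq(lo, hi, by = binWidth)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  h <- graphics::hist(samples, breaks = breaks, plot = FALSE)
  list(breaks = h$breaks, density = h$density)
}
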