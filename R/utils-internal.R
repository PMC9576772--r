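# Internal numeric helpers shared across modules. Nothing here is exported.

# Run expr with a locally-seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a distinct 31-bit sub-seed from a master seed and a stream index.
subSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 9973) %% 2147483647)
}

# Mirror (symmetric) padding of a matrix by w pixels on every side.
padMirror <- function(m, w) {
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(w >= 1, w <= nr, w <= nc)
  ri <- c(w:1, seq_len(nr), nr:(nr - w + 1L))
  ci <- c(w:1, seq_len(nc), nc:(nc - w + 1L))
  m[ri, ci, drop = FALSE]
}

# Replicate (edge) padding of a matrix by w pixels on every side.
padReplicate <- function(m, w) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rep(1L, w), seq_len(nr), rep(nr, w))
  ci <- c(rep(1L, w), seq_len(nc), rep(nc, w))
  m[ri, ci, drop = FALSE]
}

# Exact median of 9 values, vectorised over pixels: the classical
# 19-comparator sorting network. x is a list of 9 equally-sized vectors.
median9 <- function(x) {
  sw <- function(i, j) {
    lo <- pmin(x[[i]], x[[j]]); hi <- pmax(x[[i]], x[[j]])
    x[[i]] <<- lo; x[[j]] <<- hi
  }
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 4); sw(6, 9); sw(5, 8)
  sw(4, 7); sw(2, 5); sw(3, 6)
  sw(5, 8); sw(5, 3); sw(7, 5); sw(5, 3)
  x[[5]]
}

# Local mean over a w x w window (w odd) with replicate padding, via an
# integral image; exact and O(n).
localMean <- function(m, w) {
  stopifnot(w %% 2L == 1L, w >= 3L)
  if (w > 2L * min(dim(m)) - 1L)
    stop("window larger than image")
  h <- (w - 1L) %/% 2L
  p <- padReplicate(m, h)
  np <- nrow(p); mp <- ncol(p)
  # summed-area table with a zero top/left border
  s <- matrix(0, np + 1L, mp + 1L)
  s[-1L, -1L] <- apply(apply(p, 2L, cumsum), 1L, cumsum) |> t()
  i1 <- seq_len(nrow(m)); j1 <- seq_len(ncol(m))
  # window rows i1..i1+w-1 in padded frame
  tot <- s[i1 + w, j1 + w, drop = FALSE] - s[i1, j1 + w, drop = FALSE] -
    s[i1 + w, j1, drop = FALSE] + s[i1, j1, drop = FALSE]
  tot / (w * w)
}

# Shoelace signed area of a polygon given as an n x 2 matrix (open ring).
signedArea <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  sum(x * y2 - x2 * y) / 2
}

# Centroid and second central moments of a polygon interior (Green's
# theorem closed forms). Returns list(area, cx, cy, cov) with cov the
# 2x2 covariance of the uniform density over the interior.
polygonMoments <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  cr <- x * y2 - x2 * y
  A <- sum(cr) / 2
  if (abs(A) < .Machine$double.eps * 100)
    stop("degenerate polygon (zero area)")
  cx <- sum((x + x2) * cr) / (6 * A)
  cy <- sum((y + y2) * cr) / (6 * A)
  Ixx <- sum((x^2 + x * x2 + x2^2) * cr) / 12
  Iyy <- sum((y^2 + y * y2 + y2^2) * cr) / 12
  Ixy <- sum((x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y) * cr) / 24
  # central second moments per unit area
  cov <- matrix(c(Ixx / A - cx^2, Ixy / A - cx * cy,
                  Ixy / A - cx * cy, Iyy / A - cy^2), 2L, 2L)
  if (A < 0) { A <- -A }
  list(area = A, cx = cx, cy = cy, cov = cov)
}

# Does the closed polygon (n x 2) contain point pt? Ray-casting.
pointInPolygon <- function(pt, p) {
  x <- p[, 1L]; y <- p[, 2L]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  xi <- x; yi <- y; xj <- x[j]; yj <- y[j]
  cross <- ((yi > pt[2L]) != (yj > pt[2L])) &
    (pt[1L] < (xj - xi) * (pt[2L] - yi) / (yj - yi) + xi)
  (sum(cross) %% 2L) == 1L
}

# Trilinear interpolation of a 3D numeric array at physical points.
# pts: n x 3 matrix in um; vox: spacing; origin: corner of voxel (1,1,1).
# Values outside the grid evaluate to `outside`. If periodicXY, x/y wrap
# with period dim*vox.
trilinear <- function(arr, pts, vox, origin = c(0, 0, 0),
                      outside = 0, periodicXY = FALSE) {
  d <- dim(arr)
  # continuous voxel-centre coordinates
  u <- (pts[, 1L] - origin[1L]) / vox[1L] - 0.5
  v <- (pts[, 2L] - origin[2L]) / vox[2L] - 0.5
  w <- (pts[, 3L] - origin[3L]) / vox[3L] - 0.5
  if (periodicXY) {
    u <- u %% d[1L]
    v <- v %% d[2L]
  }
  i0 <- floor(u); j0 <- floor(v); k0 <- floor(w)
  fu <- u - i0; fv <- v - j0; fw <- w - k0
  gi <- function(i, j, k) {
    if (periodicXY) {
      i <- i %% d[1L]; j <- j %% d[2L]
      ok <- k >= 0 & k <= d[3L] - 1L
    } else {
      ok <- i >= 0 & i <= d[1L] - 1L & j >= 0 & j <= d[2L] - 1L &
        k >= 0 & k <= d[3L] - 1L
    }
    out <- rep(outside, length(i))
    if (any(ok))
      out[ok] <- arr[cbind(i[ok] + 1L, j[ok] + 1L, k[ok] + 1L)]
    out
  }
  c000 <- gi(i0, j0, k0);     c100 <- gi(i0 + 1, j0, k0)
  c010 <- gi(i0, j0 + 1, k0); c110 <- gi(i0 + 1, j0 + 1, k0)
  c001 <- gi(i0, j0, k0 + 1);     c101 <- gi(i0 + 1, j0, k0 + 1)
  c011 <- gi(i0, j0 + 1, k0 + 1); c111 <- gi(i0 + 1, j0 + 1, k0 + 1)
  c00 <- c000 * (1 - fu) + c100 * fu
  c10 <- c010 * (1 - fu) + c110 * fu
  c01 <- c001 * (1 - fu) + c101 * fu
  c11 <- c011 * (1 - fu) + c111 * fu
  c0 <- c00 * (1 - fv) + c10 * fv
  c1 <- c01 * (1 - fv) + c11 * fv
  c0 * (1 - fw) + c1 * fw
}

# Centered moving average with shrinking windows at the ends.
runMean <- function(x, window) {
  n <- length(x)
  if (window <= 1L || n < 3L) return(x)
  h <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L); hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# A stable orthonormal basis (e1, e2) perpendicular to unit vector t.
perpBasis <- function(t) {
  t <- t / sqrt(sum(t^2))
  ref <- if (abs(t[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * t) * t
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(t[2L] * e1[3L] - t[3L] * e1[2L],
          t[3L] * e1[1L] - t[1L] * e1[3L],
          t[1L] * e1[2L] - t[2L] * e1[1L])
  list(e1 = e1, e2 = e2)
}
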