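# Surface meshing and binary STL output for generated axon volumes.
# Each tube is lofted from its per-station footprint rings (fixed 32
# vertices per ring) and capped flat at the box faces; tubes crossing the
# periodic x-y boundary are clipped to the box and the wrapped remainder
# emitted as separate closed shells.

.RING_N <- 32L

# Ring polygon (n x 2) of tube tb at station k, optionally shifted.
.ringPoly <- function(tb, k, shift = c(0, 0), n = .RING_N) {
  ph <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  circ <- rbind(cos(ph), sin(ph))
  P <- tb$F[, , k] %*% circ
  cbind(P[1L, ] + tb$cx[k] + shift[1L], P[2L, ] + tb$cy[k] + shift[2L])
}

# Sutherland-Hodgman clip of a convex polygon to the rectangle
# [0, bx] x [0, by]. Returns an m x 2 matrix (possibly 0 rows).
.clipRect <- function(p, bx, by) {
  clipHalf <- function(p, inside, isect) {
    n <- nrow(p)
    if (n == 0L) return(p)
    out <- matrix(0, 2L * n, 2L)
    m <- 0L
    for (i in seq_len(n)) {
      a <- p[i, ]; b <- p[if (i == n) 1L else i + 1L, ]
      ia <- inside(a); ib <- inside(b)
      if (ia) { m <- m + 1L; out[m, ] <- a }
      if (xor(ia, ib)) { m <- m + 1L; out[m, ] <- isect(a, b) }
    }
    out[seq_len(m), , drop = FALSE]
  }
  lerp <- function(a, b, t) a + t * (b - a)
  p <- clipHalf(p, function(q) q[1L] >= 0,
                function(a, b) lerp(a, b, (0 - a[1L]) / (b[1L] - a[1L])))
  p <- clipHalf(p, function(q) q[1L] <= bx,
                function(a, b) lerp(a, b, (bx - a[1L]) / (b[1L] - a[1L])))
  p <- clipHalf(p, function(q) q[2L] >= 0,
                function(a, b) lerp(a, b, (0 - a[2L]) / (b[2L] - a[2L])))
  p <- clipHalf(p, function(q) q[2L] <= by,
                function(a, b) lerp(a, b, (by - a[2L]) / (b[2L] - a[2L])))
  p
}

# Resample a closed polygon to exactly n vertices by arc length.
.resampleRing <- function(p, n = .RING_N) {
  m <- nrow(p)
  q <- rbind(p, p[1L, ])
  seg <- sqrt(rowSums((q[-1L, , drop = FALSE] - q[-(m + 1L), ,
                                                  drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  L <- s[m + 1L]
  if (L <= 0) return(NULL)
  tt <- seq(0, L, length.out = n + 1L)[-(n + 1L)]
  i <- findInterval(tt, s, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), m)
  w <- (tt - s[i]) / pmax(seg[i], .Machine$double.eps)
  q[i, , drop = FALSE] * (1 - w) + q[i + 1L, , drop = FALSE] * w
}

# Align ring vertex 0 with a reference point (rotate vertex order only).
.alignRing <- function(p, ref) {
  if (is.null(ref)) return(p)
  d2 <- (p[, 1L] - ref[1L])^2 + (p[, 2L] - ref[2L])^2
  k <- which.min(d2)
  if (k > 1L) p <- p[c(k:nrow(p), 1:(k - 1L)), , drop = FALSE]
  p
}

# Loft a stack of aligned rings (list of n x 2, one per z) into triangles;
# caps close the first and last ring. Rings are normalised to
# counter-clockwise orientation so walls and caps wind consistently
# outward. Returns an nTri x 9 matrix.
.loftShell <- function(rings, zs) {
  rings <- lapply(rings, function(r)
    if (signedArea(r) < 0) r[rev(seq_len(nrow(r))), , drop = FALSE] else r)
  nR <- length(rings)
  n <- nrow(rings[[1L]])
  tris <- list()
  for (k in seq_len(nR - 1L)) {
    A <- cbind(rings[[k]], zs[k])
    B <- cbind(rings[[k + 1L]], zs[k + 1L])
    j2 <- c(2:n, 1L)
    tris[[length(tris) + 1L]] <-
      cbind(A, A[j2, , drop = FALSE], B)
    tris[[length(tris) + 1L]] <-
      cbind(A[j2, , drop = FALSE], B[j2, , drop = FALSE], B)
  }
  capFan <- function(ring, zf, flip) {
    cen <- colMeans(ring)
    j2 <- c(2:n, 1L)
    a <- cbind(ring, zf); b <- cbind(ring[j2, , drop = FALSE], zf)
    c0 <- matrix(rep(c(cen, zf), each = n), n, 3L)
    if (flip) cbind(c0, b, a) else cbind(c0, a, b)
  }
  tris[[length(tris) + 1L]] <- capFan(rings[[1L]], zs[1L], flip = TRUE)
  tris[[length(tris) + 1L]] <- capFan(rings[[nR]], zs[nR], flip = FALSE)
  tri <- do.call(rbind, tris)
  # enforce outward orientation globally via the signed volume
  if (meshVolume(tri) < 0)
    tri <- tri[, c(1:3, 7:9, 4:6), drop = FALSE]
  tri
}

#' Signed volume enclosed by a triangle mesh
#'
#' Divergence-theorem volume of a closed, consistently oriented
#' triangulation; positive for outward orientation.
#'
#' @param tri numeric matrix, one triangle per row as
#'   (x1,y1,z1,x2,y2,z2,x3,y3,z3).
#' @return enclosed volume (um^3 for meshes in um).
#' @export
meshVolume <- function(tri) {
  v1 <- tri[, 1:3, drop = FALSE]
  v2 <- tri[, 4:6, drop = FALSE]
  v3 <- tri[, 7:9, drop = FALSE]
  sum(v1[, 1L] * (v2[, 2L] * v3[, 3L] - v2[, 3L] * v3[, 2L]) -
      v1[, 2L] * (v2[, 1L] * v3[, 3L] - v2[, 3L] * v3[, 1L]) +
      v1[, 3L] * (v2[, 1L] * v3[, 2L] - v2[, 2L] * v3[, 1L])) / 6
}

#' Watertightness check for a triangle mesh
#'
#' A closed orientable shell has every undirected edge shared by exactly
#' two triangles and Euler characteristic V - E + F = 2 per connected
#' shell. Returns a list with `closed`, `eulerPerShell` and counts.
#'
#' @param tri triangle matrix as in [meshVolume()].
#' @param tol coordinate rounding tolerance for vertex identification.
#' @return list with `closed` (logical), `nVertices`, `nEdges`, `nFaces`,
#'   `nShells`, `eulerPerShell`.
#' @export
meshIsClosed <- function(tri, tol = 1e-9) {
  V <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE],
             tri[, 7:9, drop = FALSE])
  key <- apply(round(V / tol) * tol, 1L, paste, collapse = "/")
  uid <- match(key, unique(key))
  nF <- nrow(tri)
  f <- cbind(uid[seq_len(nF)], uid[nF + seq_len(nF)],
             uid[2L * nF + seq_len(nF)])
  edges <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  ek <- paste(pmin(edges[, 1L], edges[, 2L]),
              pmax(edges[, 1L], edges[, 2L]))
  cnt <- table(ek)
  closed <- all(cnt == 2L)
  nV <- length(unique(uid)); nE <- length(cnt)
  # connected shells via union-find on faces sharing vertices
  parent <- seq_len(nV)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (r in seq_len(nF)) {
    a <- find(f[r, 1L]); b <- find(f[r, 2L]); c3 <- find(f[r, 3L])
    parent[b] <- a; parent[find(c3)] <- a
  }
  roots <- vapply(seq_len(nV), find, 1L)
  shells <- unique(roots)
  nS <- length(shells)
  euler <- (nV - nE + nF) / nS
  list(closed = closed, nVertices = nV, nEdges = nE, nFaces = nF,
       nShells = nS, eulerPerShell = euler)
}

# Build the triangle mesh (possibly several shells) for one tube,
# clipping to the periodic box.
.tubeMesh <- function(tb, box, clip = TRUE) {
  nz <- length(tb$z)
  rings0 <- lapply(seq_len(nz), function(k) .ringPoly(tb, k))
  allIn <- all(vapply(rings0, function(r)
    all(r[, 1L] >= 0 & r[, 1L] <= box[1L] &
        r[, 2L] >= 0 & r[, 2L] <= box[2L]), TRUE))
  if (allIn || !clip) {
    rings <- rings0
    ref <- NULL
    for (k in seq_len(nz)) {
      rings[[k]] <- .alignRing(rings[[k]], ref)
      ref <- rings[[k]][1L, ]
    }
    # tubes span the full z extent: extend the end rings to the box faces
    rings <- c(rings[1L], rings, rings[nz])
    zsFull <- c(0, tb$z, box[3L])
    return(list(.loftShell(rings, zsFull)))
  }
  # wrapped: clip each candidate image to the box
  shells <- list()
  for (sx in c(-box[1L], 0, box[1L])) for (sy in c(-box[2L], 0, box[2L])) {
    clipped <- lapply(seq_len(nz), function(k) {
      cp <- .clipRect(.ringPoly(tb, k, shift = c(sx, sy)),
                      box[1L], box[2L])
      if (nrow(cp) >= 3L && abs(signedArea(cp)) > 1e-8) cp else NULL
    })
    present <- !vapply(clipped, is.null, TRUE)
    if (!any(present)) next
    # maximal consecutive runs of non-empty sections
    r <- rle(present)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (q in which(r$values)) {
      ks <- starts[q]:ends[q]
      if (length(ks) < 2L) next
      rings <- vector("list", length(ks))
      ref <- NULL
      for (m in seq_along(ks)) {
        rs <- .resampleRing(clipped[[ks[m]]])
        if (is.null(rs)) next
        rings[[m]] <- .alignRing(rs, ref)
        ref <- rings[[m]][1L, ]
      }
      keep <- !vapply(rings, is.null, TRUE)
      if (sum(keep) < 2L) next
      rr <- rings[keep]
      zz <- tb$z[ks][keep]
      if (ks[1L] == 1L && keep[1L]) {
        rr <- c(rr[1L], rr); zz <- c(0, zz)
      }
      if (ks[length(ks)] == nz && keep[length(keep)]) {
        rr <- c(rr, rr[length(rr)]); zz <- c(zz, box[3L])
      }
      shells[[length(shells) + 1L]] <- .loftShell(rr, zz)
    }
  }
  shells
}

#' Export a generated axon volume as STL surface meshes
#'
#' Writes one binary STL per axon plus a combined file. Each axon surface
#' is a closed, consistently outward-oriented triangulation lofted from
#' its per-station footprint rings (32 vertices per ring) with flat caps
#' at the box faces; tubes crossing the periodic x-y boundary are clipped
#' to the box and their wrapped remainder written as separate closed
#' shells of the same solid. Units are micrometres. Every mesh is checked
#' for watertightness before writing; a defective mesh aborts the export.
#'
#' @param rve an [AxonRVE-class].
#' @param path output directory (created if missing).
#' @param prefix file-name prefix.
#' @return invisibly, a data.frame with per-axon mesh volume and files.
#' @export
exportSTL <- function(rve, path, prefix = "axon") {
  stopifnot(is(rve, "AxonRVE"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character(0); vols <- numeric(0)
  allTri <- list()
  for (i in seq_along(rve@tubes)) {
    shells <- .tubeMesh(rve@tubes[[i]], rve@box)
    tri <- do.call(rbind, shells)
    chk <- meshIsClosed(tri)
    if (!chk$closed || abs(chk$eulerPerShell - 2) > 1e-9)
      stop(sprintf("internal error: axon %d mesh is not watertight", i))
    fn <- file.path(path, sprintf("%s_%03d.stl", prefix, i))
    writeSTL(tri, fn, solidName = sprintf("%s_%03d_um", prefix, i))
    files <- c(files, fn)
    vols <- c(vols, meshVolume(tri))
    allTri[[i]] <- tri
  }
  comb <- file.path(path, sprintf("%s_combined.stl", prefix))
  writeSTL(do.call(rbind, allTri), comb,
           solidName = paste0(prefix, "_combined_um"))
  invisible(data.frame(axon_id = seq_along(rve@tubes), file = files,
                       mesh_volume = vols))
}

#' Write a binary STL file
#'
#' @param tri triangle matrix (n x 9), coordinates in micrometres.
#' @param path output file.
#' @param solidName name embedded in the 80-byte header (units noted
#'   there, as the format has no unit field).
#' @export
writeSTL <- function(tri, path, solidName = "axoncyto_um") {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", substr(solidName, 1L, 79L)))[1:80]
  writeBin(hdr, con)
  n <- nrow(tri)
  writeBin(as.integer(n), con, size = 4L, endian = "little")
  v1 <- tri[, 1:3, drop = FALSE]
  v2 <- tri[, 4:6, drop = FALSE]
  v3 <- tri[, 7:9, drop = FALSE]
  e1 <- v2 - v1; e2 <- v3 - v1
  nrm <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
               e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
               e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  block <- cbind(nrm, v1, v2, v3)
  fb <- writeBin(as.numeric(t(block)), raw(), size = 4L,
                 endian = "little")
  rec <- matrix(raw(50L * n), 50L, n)
  rec[1:48, ] <- matrix(fb, 48L, n)
  writeBin(as.vector(rec), con)
  invisible(path)
}

#' Read a binary STL file
#'
#' Minimal reader for round-trip checks of exported meshes.
#'
#' @param path STL file written by [writeSTL()] (binary format).
#' @return triangle matrix (n x 9).
#' @export
readSTL <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80L))
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  rec <- matrix(readBin(con, "raw", 50L * n), 50L, n)
  vals <- readBin(as.vector(rec[1:48, ]), "numeric", 12L * n,
                  size = 4L, endian = "little")
  m <- matrix(vals, 12L, n)
  t(m[4:12, , drop = FALSE])
}
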