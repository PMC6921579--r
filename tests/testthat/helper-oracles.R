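# Independent oracle implementations used to validate the package's
# optimised code paths. These deliberately use the most direct algorithm
# available (double loops, flood fill, gift wrapping) and share no code
# with the implementations they check.

# All-pairs absolute-difference speckle activity, direct double loop.
oracleGD <- function(frames, meanPair = TRUE) {
  nT <- dim(frames)[3]
  acc <- matrix(0, dim(frames)[1], dim(frames)[2])
  for (k in seq_len(nT - 1)) {
    for (l in (k + 1):nT) {
      acc <- acc + abs(frames[, , k] - frames[, , l])
    }
  }
  if (meanPair) acc / (nT * (nT - 1) / 2) else acc
}

# BFS flood fill over a logical 3D array; returns an integer label array
# (0 = background), labels in discovery order of a raster scan.
oracleFloodFill <- function(fg, connectivity = 26) {
  d <- dim(fg)
  offs <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0 & offs$dz == 0), ]
  if (connectivity == 6)
    offs <- offs[abs(offs$dy) + abs(offs$dx) + abs(offs$dz) == 1, ]
  lab <- array(0L, d)
  nextLab <- 0L
  for (z in seq_len(d[3])) for (y in seq_len(d[1])) for (x in seq_len(d[2])) {
    if (!fg[y, x, z] || lab[y, x, z] != 0L) next
    nextLab <- nextLab + 1L
    queue <- matrix(c(y, x, z), ncol = 3)
    lab[y, x, z] <- nextLab
    while (nrow(queue) > 0) {
      cur <- queue[1, , drop = FALSE]
      queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(offs))) {
        ny <- cur[1] + offs$dy[k]; nx <- cur[2] + offs$dx[k]
        nz <- cur[3] + offs$dz[k]
        if (ny >= 1 && ny <= d[1] && nx >= 1 && nx <= d[2] &&
            nz >= 1 && nz <= d[3] && fg[ny, nx, nz] &&
            lab[ny, nx, nz] == 0L) {
          lab[ny, nx, nz] <- nextLab
          queue <- rbind(queue, c(ny, nx, nz))
        }
      }
    }
  }
  lab
}

# Per-pixel window-sort median with edge-duplicating reflection.
oracleMedian <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  refl <- function(i, n) {
    j <- (i - 1) %% (2 * n)
    j <- ifelse(j < 0, j + 2 * n, j)
    ifelse(j < n, j, 2 * n - 1 - j) + 1
  }
  out <- m
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ii <- refl((i - r):(i + r), h)
    jj <- refl((j - r):(j + r), w)
    out[i, j] <- stats::median(m[ii, jj])
  }
  out
}

# Grayscale opening with a disc, brute-force min/max over in-bounds
# offsets.
oracleOpenDisc <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dy^2 + off$dx^2 <= r^2 + 1e-9, ]
  stage <- function(src, fun) {
    out <- matrix(NA_real_, h, w)
    for (i in seq_len(h)) for (j in seq_len(w)) {
      ii <- i + off$dy; jj <- j + off$dx
      ok <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
      out[i, j] <- fun(src[cbind(ii[ok], jj[ok])])
    }
    out
  }
  stage(stage(m, min), max)
}

# Gift-wrapping (Jarvis march) convex hull; returns area and perimeter.
oracleHull <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  start <- which.min(pts[, 1] * 1e9 + pts[, 2])
  hull <- start
  repeat {
    cur <- hull[length(hull)]
    cand <- setdiff(seq_len(n), cur)
    best <- cand[1]
    for (k in cand[-1]) {
      cross <- (pts[best, 1] - pts[cur, 1]) * (pts[k, 2] - pts[cur, 2]) -
               (pts[best, 2] - pts[cur, 2]) * (pts[k, 1] - pts[cur, 1])
      if (cross < 0 ||
          (abs(cross) < 1e-12 &&
           sum((pts[k, ] - pts[cur, ])^2) > sum((pts[best, ] - pts[cur, ])^2)))
        best <- k
    }
    if (best == start) break
    hull <- c(hull, best)
    if (length(hull) > n + 1) stop("gift wrapping failed to close")
  }
  hp <- pts[hull, , drop = FALSE]
  m <- nrow(hp)
  jn <- c(2:m, 1)
  area <- abs(sum(hp[, 1] * hp[jn, 2] - hp[jn, 1] * hp[, 2])) / 2
  per <- sum(sqrt(rowSums((hp[jn, ] - hp)^2)))
  list(S = area, P = per)
}

# Closed-form paired / two-sample equal-variance t statistics.
oraclePairedT <- function(before, after) {
  d <- after - before
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1))
}
oracleUnpairedT <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  t <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * stats::pt(-abs(t), df = na + nb - 2))
}
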