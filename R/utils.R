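#' @import methods
#' @importFrom stats dnorm quantile median rnorm runif rpois rlnorm sd aov
#'   kruskal.test TukeyHSD p.adjust pnorm approx predict aggregate
#' @importFrom utils capture.output combn read.csv write.csv
#' @importFrom grDevices gray
NULL

# Seed-splitting: every internal source of randomness derives its own seed from
# the user-facing one, so adding a stage never perturbs another stage's draws.
deriveSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  s <- (abs(as.double(seed)) %% 1e6) * 1009 + abs(as.double(tag)) * 9176 + 1
  as.integer(s %% 2147483629)
}

# Apply a linear operator M (m x n) along one axis of a 3D array (n = dim[axis]).
applyAxis <- function(a, M, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  out <- M %*% m
  dn <- d[perm]; dn[1] <- nrow(M)
  out <- array(out, dn)
  aperm(out, order(perm))
}

gaussKernelMatrix <- function(n, sigma) {
  idx <- outer(seq_len(n), seq_len(n), "-")
  K <- exp(-(idx^2) / (2 * sigma^2))
  K[abs(idx) > ceiling(4 * sigma)] <- 0
  K / rowSums(K)
}

# Separable 3D Gaussian blur; sigmaVox per axis in voxel units, 0 = no-op.
gaussianBlur3D <- function(a, sigmaVox) {
  stopifnot(length(sigmaVox) == 3L, all(sigmaVox >= 0))
  for (ax in 1:3) {
    if (sigmaVox[ax] > 1e-8) {
      a <- applyAxis(a, gaussKernelMatrix(dim(a)[ax], sigmaVox[ax]), ax)
    }
  }
  a
}

# Block-mean downsampling to a fixed output grid (axes may be non-divisible).
blockMean3D <- function(a, outDim) {
  stopifnot(length(outDim) == 3L, all(outDim >= 1))
  for (ax in 1:3) {
    n <- dim(a)[ax]; m <- outDim[ax]
    grp <- pmin(m, 1L + floor((seq_len(n) - 1L) * m / n))
    M <- matrix(0, m, n)
    M[cbind(grp, seq_len(n))] <- 1
    M <- M / rowSums(M)
    a <- applyAxis(a, M, ax)
  }
  a
}

# Otsu's threshold on a numeric vector (maximizes between-class variance).
otsuThreshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) <= 0) return(r[1])
  h <- tabulate(pmin(nbins, 1L + floor((x - r[1]) / diff(r) * nbins)), nbins)
  p <- h / sum(h)
  mids <- r[1] + (seq_len(nbins) - 0.5) / nbins * diff(r)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[nbins]
  bc <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  bc[!is.finite(bc)] <- -Inf
  mids[which.max(bc)]
}

# 26-connected component labelling of a logical 3D mask (iterative BFS).
connComp3D <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nOff <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  nOff <- nOff[rowSums(abs(nOff)) > 0, , drop = FALSE]
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  coords <- arrayInd(idx, d)
  inMask <- array(FALSE, d); inMask[idx] <- TRUE
  cur <- 0L
  for (k in seq_along(idx)) {
    if (lab[idx[k]] != 0L) next
    cur <- cur + 1L
    frontier <- matrix(coords[k, ], 1L)
    lab[idx[k]] <- cur
    while (nrow(frontier) > 0L) {
      cand <- frontier[rep(seq_len(nrow(frontier)), each = nrow(nOff)), , drop = FALSE] +
        nOff[rep(seq_len(nrow(nOff)), nrow(frontier)), , drop = FALSE]
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
            cand[, 2] >= 1 & cand[, 2] <= d[2] &
            cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      if (nrow(cand) == 0L) break
      li <- cand[, 1] + d[1] * (cand[, 2] - 1L) + d[1] * d[2] * (cand[, 3] - 1L)
      keep <- inMask[li] & lab[li] == 0L
      li <- unique(li[keep])
      if (length(li) == 0L) break
      lab[li] <- cur
      frontier <- arrayInd(li, d)
    }
  }
  lab
}

# Vectorised trilinear interpolation; pts is an n x 3 matrix of 1-based
# fractional (z,y,x) array coordinates. Out-of-range points return `outside`.
trilinear <- function(a, pts, outside = 0) {
  d <- dim(a)
  n <- nrow(pts)
  val <- rep(outside, n)
  ok <- pts[, 1] >= 1 & pts[, 1] <= d[1] &
        pts[, 2] >= 1 & pts[, 2] <= d[2] &
        pts[, 3] >= 1 & pts[, 3] <= d[3]
  if (!any(ok)) return(val)
  p <- pts[ok, , drop = FALSE]
  f0 <- pmin(floor(p), matrix(rep(d - 1L, each = nrow(p)), ncol = 3))
  fr <- p - f0
  acc <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dz) fr[, 1] else 1 - fr[, 1]) *
         (if (dy) fr[, 2] else 1 - fr[, 2]) *
         (if (dx) fr[, 3] else 1 - fr[, 3])
    li <- (f0[, 1] + dz) + d[1] * (f0[, 2] + dy - 1) + d[1] * d[2] * (f0[, 3] + dx - 1)
    acc <- acc + w * a[li]
  }
  val[ok] <- acc
  val
}

# Intensity-weighted centroid of a 3D array, 0-based (z,y,x) voxel coordinates.
weightedCentroid <- function(a) {
  s <- sum(a)
  if (s <= 0) return(c(NA_real_, NA_real_, NA_real_))
  d <- dim(a)
  zc <- sum(rowSums(a, dims = 1) * (seq_len(d[1]) - 1)) / s
  ym <- apply(a, 2, sum)
  yc <- sum(ym * (seq_len(d[2]) - 1)) / s
  xm <- apply(a, 3, sum)
  xc <- sum(xm * (seq_len(d[3]) - 1)) / s
  c(zc, yc, xc)
}

# Circular moving average, odd window.
circularMA <- function(x, window = 5L) {
  stopifnot(window %% 2L == 1L)
  h <- (window - 1L) %/% 2L
  n <- length(x)
  xe <- c(x[(n - h + 1L):n], x, x[1:h])
  as.numeric(stats::filter(xe, rep(1 / window, window), sides = 2))[(h + 1L):(h + n)]
}

# FNV-1a hash of a canonical JSON rendering; stable under key reordering.
configHash <- function(x) {
  canon <- function(v) {
    if (is.list(v) && !is.null(names(v))) v <- lapply(v[order(names(v))], canon)
    else if (is.list(v)) v <- lapply(v, canon)
    v
  }
  s <- jsonlite::toJSON(canon(x), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

rot90ccw <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
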