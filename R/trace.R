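#' Pair a tail-containing frame with its sperm head
#'
#' Finds the nucleus region nearest to the tail's proximal end in the
#' co-registered nuclei channel and returns its median intensity as the
#' normalization reference. Two equidistant candidates are resolved toward
#' the earlier (lower-id) component and the pairing is flagged ambiguous.
#'
#' @param nucleiCrop 3D array: the nuclei-channel crop co-registered with the
#'   frame.
#' @param proximalVox numeric(3) 0-based (z,y,x) voxel coordinate of the
#'   tail's proximal end, in crop coordinates.
#' @param spacing voxel spacing, um.
#' @param searchRadius maximum head-to-tail distance, um.
#' @param minVoxels minimum nucleus component size.
#' @return list(reference, centroid, flag) where flag is "" / "ambiguous" /
#'   "unpaired" (reference is NA when unpaired).
#' @export
pairHead <- function(nucleiCrop, proximalVox, spacing = c(0.5, 0.2, 0.2),
                     searchRadius = 5, minVoxels = 20L) {
  th <- otsuThreshold(nucleiCrop)
  mask <- nucleiCrop >= th & nucleiCrop > 0
  unpaired <- list(reference = NA_real_, centroid = c(NA, NA, NA),
                   flag = "unpaired")
  if (!any(mask)) return(unpaired)
  comps <- connComp3D(mask)
  nc <- max(comps)
  cands <- list()
  for (k in seq_len(nc)) {
    sel <- comps == k
    if (sum(sel) < minVoxels) next
    w <- nucleiCrop; w[!sel] <- 0
    cen <- weightedCentroid(w)
    dist <- sqrt(sum(((cen - proximalVox) * spacing)^2))
    cands[[length(cands) + 1L]] <- list(k = k, centroid = cen, dist = dist,
                                        ref = median(nucleiCrop[sel]))
  }
  if (length(cands) == 0L) return(unpaired)
  d <- vapply(cands, `[[`, numeric(1), "dist")
  ok <- which(d <= searchRadius)
  if (length(ok) == 0L) return(unpaired)
  best <- ok[which.min(d[ok])]
  flag <- if (sum(abs(d[ok] - d[best]) < 1e-9) > 1L) "ambiguous" else ""
  if (flag == "ambiguous") best <- min(ok[abs(d[ok] - d[best]) < 1e-9])
  list(reference = cands[[best]]$ref, centroid = cands[[best]]$centroid,
       flag = flag)
}

# Longest geodesic path through a 26-connected foreground mask: BFS from an
# arbitrary foreground voxel to its farthest voxel u, then BFS from u; the
# path to the farthest voxel v approximates the tubular centerline.
longestPath3D <- function(mask) {
  d <- dim(mask)
  nOff <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  nOff <- nOff[rowSums(abs(nOff)) > 0, , drop = FALSE]
  bfs <- function(startLi) {
    distm <- array(NA_integer_, d); parent <- array(0L, d)
    distm[startLi] <- 0L
    frontier <- startLi
    while (length(frontier)) {
      fc <- arrayInd(frontier, d)
      cand <- fc[rep(seq_len(nrow(fc)), each = nrow(nOff)), , drop = FALSE] +
        nOff[rep(seq_len(nrow(nOff)), nrow(fc)), , drop = FALSE]
      par <- rep(frontier, each = nrow(nOff))
      okb <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
             cand[, 2] >= 1 & cand[, 2] <= d[2] &
             cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[okb, , drop = FALSE]; par <- par[okb]
      li <- cand[, 1] + d[1] * (cand[, 2] - 1L) + d[1] * d[2] * (cand[, 3] - 1L)
      new <- mask[li] & is.na(distm[li])
      li <- li[new]; par <- par[new]
      if (!length(li)) break
      dup <- !duplicated(li)
      li <- li[dup]; par <- par[dup]
      distm[li] <- distm[frontier[1]] + 1L
      parent[li] <- par
      frontier <- li
    }
    list(dist = distm, parent = parent)
  }
  start <- which(mask)[1]
  b1 <- bfs(start)
  u <- which.max(b1$dist)
  b2 <- bfs(u)
  v <- which.max(b2$dist)
  path <- integer()
  cur <- v
  while (cur != 0L && cur != u) {
    path <- c(cur, path)
    cur <- b2$parent[cur]
  }
  path <- c(u, path)
  arrayInd(path, d)
}

# Intensity along a path as a small transverse disc average (radius in um):
# robust to the sampled path riding a bright nanodomain stripe rather than
# the geometric axis.
pathIntensity <- function(crop, gp, spacing, radius = 0.3, nSpokes = 8L) {
  n <- nrow(gp)
  # tangents by central differences
  tg <- rbind(gp[2, ] - gp[1, ],
              (gp[pmin(n, 2:(n - 1) + 1), , drop = FALSE] -
               gp[pmax(1, 2:(n - 1) - 1), , drop = FALSE]),
              gp[n, ] - gp[n - 1, ])
  tg <- tg / pmax(sqrt(rowSums(tg^2)), 1e-9)
  pts <- gp
  wsum <- trilinear(crop, sweep(gp, 2, spacing, "/") + 1)
  count <- rep(1, n)
  for (k in seq_len(nSpokes)) {
    th <- 2 * pi * (k - 1) / nSpokes
    off <- t(vapply(seq_len(n), function(i) {
      t1 <- tg[i, ]
      ref <- if (abs(t1[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
      nv <- ref - sum(ref * t1) * t1
      nv <- nv / sqrt(sum(nv^2))
      bv <- c(t1[2] * nv[3] - t1[3] * nv[2], t1[3] * nv[1] - t1[1] * nv[3],
              t1[1] * nv[2] - t1[2] * nv[1])
      radius * (cos(th) * nv + sin(th) * bv)
    }, numeric(3)))
    wsum <- wsum + trilinear(crop, sweep(gp + off, 2, spacing, "/") + 1)
    count <- count + 1
  }
  wsum / count
}

# Approximate transverse flux profile: area-weighted average over filled
# discs orthogonal to the path (rings of spokes, weight proportional to ring
# radius). The flux falls to half its interior plateau exactly at the tube's
# physical end.
fluxProfile <- function(crop, gp, spacing, R = 0.7, nRings = 4L,
                        nSpokes = 12L) {
  acc <- 0; wtot <- 0
  for (k in seq_len(nRings)) {
    rk <- (k - 0.5) / nRings * R
    acc <- acc + rk * pathIntensity(crop, gp, spacing, radius = rk,
                                    nSpokes = nSpokes)
    wtot <- wtot + rk
  }
  acc / wtot
}

# Shift each path sample to the intensity centroid of its transverse plane:
# straightens samples that ride a bright stripe or cut a corner at the ends.
recentrePath <- function(crop, gp, spacing, radius = 0.5, nSpokes = 8L,
                         nRings = 3L) {
  n <- nrow(gp)
  tg <- rbind(gp[2, ] - gp[1, ],
              gp[pmin(n, 3:n), , drop = FALSE] -
                gp[pmax(1, 1:(n - 2)), , drop = FALSE],
              gp[n, ] - gp[n - 1, ])
  tg <- tg / pmax(sqrt(rowSums(tg^2)), 1e-9)
  out <- gp
  offs <- expand.grid(k = seq_len(nRings), j = seq_len(nSpokes))
  uu <- offs$k / nRings * radius * cos(2 * pi * (offs$j - 1) / nSpokes)
  vv <- offs$k / nRings * radius * sin(2 * pi * (offs$j - 1) / nSpokes)
  for (i in seq_len(n)) {
    t1 <- tg[i, ]
    ref <- if (abs(t1[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
    nv <- ref - sum(ref * t1) * t1; nv <- nv / sqrt(sum(nv^2))
    bv <- c(t1[2] * nv[3] - t1[3] * nv[2], t1[3] * nv[1] - t1[1] * nv[3],
            t1[1] * nv[2] - t1[2] * nv[1])
    pts <- rbind(gp[i, ], sweep(uu %o% nv + vv %o% bv, 2, gp[i, ], "+"))
    w <- trilinear(crop, sweep(pts, 2, spacing, "/") + 1)
    W <- sum(w)
    if (W > 1e-12) {
      du <- sum(c(0, uu) * w) / W
      dv <- sum(c(0, vv) * w) / W
      out[i, ] <- gp[i, ] + du * nv + dv * bv
    }
  }
  out
}

traceRejection <- function(reason) {
  stop(structure(class = c("csq_trace_rejected", "error", "condition"),
                 list(message = paste("trace rejected:", reason),
                      call = sys.call(-1))))
}

#' Linearize a scrubbed tail signal
#'
#' Extracts the tail centerline (longest geodesic path through the Otsu
#' foreground), smooths it, samples arclength at a fixed step, and reads the
#' intensity along the centerline by trilinear interpolation. Position 0 is
#' the proximal end: the end nearer \code{proximalHint} when given, otherwise
#' the native path start (flagged "unoriented").
#'
#' @param crop 3D array of the scrubbed frame (nuclei/noise removed).
#' @param spacing voxel spacing, um.
#' @param step arclength sampling step, um.
#' @param minLength minimum acceptable path length, um; shorter signals raise
#'   a condition of class "csq_trace_rejected".
#' @param proximalHint optional 0-based (z,y,x) voxel coordinate of the paired
#'   head used to orient the trace.
#' @param frameId identifier stored on the trace.
#' @return A \linkS4class{SpermTrace} (raw intensities, not yet normalized).
#' @export
linearizeTail <- function(crop, spacing = c(0.5, 0.2, 0.2), step = 0.2,
                          minLength = 10, proximalHint = NULL,
                          frameId = "frame") {
  if (max(crop) <= 0) traceRejection("no signal in frame")
  th <- otsuThreshold(crop)
  mask <- crop >= th
  if (!any(mask)) traceRejection("no voxels above threshold")
  comps <- connComp3D(mask)
  sums <- vapply(seq_len(max(comps)), function(k) sum(crop[comps == k]),
                 numeric(1))
  core <- comps == which.max(sums)
  # extend to half the threshold so the tapered tube ends are kept, but stay
  # within the connected component that contains the core signal
  ext <- connComp3D(crop >= th / 2)
  seedVox <- which(core)[which.max(crop[core])]
  mask <- ext == ext[seedVox]
  pv <- longestPath3D(mask)  # 1-based voxel coords along path
  if (nrow(pv) < 3L) traceRejection("skeleton path too short")
  phys <- sweep(pv - 1, 2, spacing, "*")
  # smooth the voxel staircase with coordinate-wise smoothing splines: the
  # anisotropic hop chain otherwise both inflates the arclength (zigzag) and
  # would lose its ends to a windowed filter
  if (nrow(phys) >= 8L) {
    idx <- seq_len(nrow(phys))
    dfree <- max(4, min(10, nrow(phys) - 2, round(nrow(phys) / 12)))
    phys <- vapply(1:3, function(j)
      stats::predict(stats::smooth.spline(idx, phys[, j], df = dfree),
                     idx)$y, numeric(nrow(phys)))
  }
  seg <- sqrt(rowSums(diff(phys)^2))
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  if (total < minLength)
    traceRejection(sprintf("path length %.2f um below minimum %.2f um",
                           total, minLength))
  flags <- character()
  if (!is.null(proximalHint)) {
    hint <- proximalHint * spacing
    d0 <- sqrt(sum((phys[1, ] - hint)^2))
    d1 <- sqrt(sum((phys[nrow(phys), ] - hint)^2))
    if (d1 < d0) {
      phys <- phys[rev(seq_len(nrow(phys))), , drop = FALSE]
      arc <- rev(total - arc)
    }
  } else flags <- c(flags, "unoriented")
  grid <- seq(0, total, by = step)
  interp <- function(col) approx(arc, col, xout = grid, rule = 2)$y
  gp <- cbind(interp(phys[, 1]), interp(phys[, 2]), interp(phys[, 3]))
  for (it in 1:2) gp <- recentrePath(crop, gp, spacing)
  # re-parameterize by arclength after recentering
  arc2 <- c(0, cumsum(sqrt(rowSums(diff(gp)^2))))
  grid <- seq(0, arc2[length(arc2)], by = step)
  gp <- cbind(approx(arc2, gp[, 1], grid, rule = 2)$y,
              approx(arc2, gp[, 2], grid, rule = 2)$y,
              approx(arc2, gp[, 3], grid, rule = 2)$y)
  inten <- pathIntensity(crop, gp, spacing)
  # trim at the tube ends: the transverse-flux profile drops steeply where
  # the tube terminates, so each end is placed at the outermost inflection
  # (steepest descent) of the flux taper; a path grown on a permissive mask
  # is thereby cut back to the physical extent
  flux <- fluxProfile(crop, gp, spacing)
  n <- length(flux)
  sm <- as.numeric(stats::filter(flux, rep(1 / 3, 3), sides = 2))
  sm[1] <- flux[1]; sm[n] <- flux[n]
  mid <- grid >= quantile(grid, 0.25) & grid <= quantile(grid, 0.75)
  ref <- median(sm[mid])   # interior plateau, taper excluded
  lo <- grid[1]; hi <- grid[n]
  kL <- which(sm >= 0.85 * ref)[1]
  if (!is.na(kL) && kL > 2L) {
    g <- diff(sm[1:kL])
    iL <- which.max(g)
    lo <- (grid[iL] + grid[iL + 1L]) / 2
  }
  kR <- rev(which(sm >= 0.85 * ref))[1]
  if (!is.na(kR) && kR < n - 1L) {
    g <- diff(sm[kR:n])
    iR <- kR + which.min(g) - 1L
    hi <- (grid[iR] + grid[iR + 1L]) / 2
  }
  if (hi > lo + step) {
    newGrid <- seq(lo, hi, by = step)
    if (newGrid[length(newGrid)] < hi - 1e-9) newGrid <- c(newGrid, hi)
    gp <- cbind(approx(grid, gp[, 1], newGrid, rule = 2)$y,
                approx(grid, gp[, 2], newGrid, rule = 2)$y,
                approx(grid, gp[, 3], newGrid, rule = 2)$y)
    inten <- approx(grid, inten, newGrid, rule = 2)$y
    grid <- newGrid - lo
  }
  if (max(grid) < minLength)
    traceRejection(sprintf("path length %.2f um below minimum %.2f um",
                           max(grid), minLength))
  pathVox <- sweep(gp, 2, spacing, "/")  # 0-based
  new("SpermTrace", arclength = grid, intensity = pmax(inten, 0),
      nucleusReference = NA_real_, path = pathVox, frameId = frameId,
      flags = flags)
}

#' Normalize a trace to its paired nucleus intensity
#'
#' @param trace a \linkS4class{SpermTrace} with raw intensities.
#' @param reference nucleus reference intensity, > 0.
#' @return the trace with intensity divided by the reference, the reference
#'   stored, and flag "normalized" appended.
#' @export
normalizeTrace <- function(trace, reference) {
  if (!is.finite(reference) || reference <= 0)
    stop(paste("cannot normalize an unpaired trace (no nucleus reference);",
               "use raw-intensity mode instead"))
  new("SpermTrace", arclength = trace@arclength,
      intensity = trace@intensity / reference,
      nucleusReference = reference, path = trace@path,
      frameId = trace@frameId, flags = union(trace@flags, "normalized"))
}

#' Overlay multiple traces on a common arclength grid
#'
#' @param traces list of \linkS4class{SpermTrace}.
#' @param step common grid step, um.
#' @return list(arclength, mean, sd, matrix) where matrix is traces x
#'   positions with NA beyond each trace's extent; mean/sd are computed over
#'   the available entries.
#' @export
overlayTraces <- function(traces, step = 0.2) {
  if (length(traces) == 0L) stop("at least one trace required")
  maxLen <- max(vapply(traces, function(t) max(t@arclength), numeric(1)))
  grid <- seq(0, maxLen, by = step)
  M <- t(vapply(traces, function(t) {
    v <- approx(t@arclength, t@intensity, xout = grid)$y
    v  # NA outside the trace extent
  }, numeric(length(grid))))
  mu <- colMeans(M, na.rm = TRUE)
  sdv <- apply(M, 2, function(cc) {
    cc <- cc[!is.na(cc)]
    if (length(cc) > 1L) sd(cc) else 0
  })
  list(arclength = grid, mean = mu, sd = sdv, matrix = M)
}

#' First sustained intensity drop along a trace
#'
#' The reference level is the mean intensity over the first
#' \code{baselineWindow} micrometres from the midpiece/principal-piece
#' interface (arclength 0). The drop position is the smallest arclength at
#' which intensity falls below \code{fraction} x reference and stays below it
#' for at least \code{sustainWindow} micrometres; traces that never drop are
#' censored at the tail length.
#'
#' @param trace a normalized \linkS4class{SpermTrace}.
#' @param fraction drop fraction f, 0 < f < 1 (e.g. 0.7 or 0.5).
#' @param baselineWindow baseline averaging window, um.
#' @param sustainWindow minimum sustained-below duration, um (0 gives the
#'   pointwise variant).
#' @return list(position, censored, reference).
#' @export
continuityFirstDrop <- function(trace, fraction, baselineWindow = 2,
                                sustainWindow = 1) {
  stopifnot(fraction > 0, fraction < 1)
  arc <- trace@arclength; int <- trace@intensity
  ref <- mean(int[arc <= baselineWindow])
  thr <- fraction * ref
  below <- int < thr
  n <- length(arc)
  for (i in seq_len(n)) {
    if (!below[i]) next
    win <- which(arc >= arc[i] & arc <= arc[i] + sustainWindow)
    endReached <- max(arc) < arc[i] + sustainWindow
    if (all(below[win]) && !(endReached && length(win) == 1L))
      return(list(position = arc[i], censored = FALSE, reference = ref))
  }
  list(position = max(arc), censored = TRUE, reference = ref)
}
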