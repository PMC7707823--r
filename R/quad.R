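#' Extract a transversal cross-section of the tail
#'
#' Resamples the frame intensity into the plane orthogonal to the local
#' centerline tangent at a given arclength, averaged over a span along the
#' tail. The default position targets the proximal principal piece close to
#' the annulus, where the CatSper1 signal is most intense.
#'
#' @param crop 3D array the trace was extracted from (scrubbed frame).
#' @param trace the \linkS4class{SpermTrace} carrying the sampled centerline.
#' @param positionUm arclength of the section centre, um from the proximal end.
#' @param spanUm averaging span along the tail, um.
#' @param spacing voxel spacing of the crop, um.
#' @param pixelSpacing patch pixel size, um.
#' @param patchRadiusUm patch half-extent, um.
#' @param cellId identifier stored on the section.
#' @return A \linkS4class{CrossSection}; flagged "curved" when the local
#'   radius of curvature is smaller than the span.
#' @export
extractCrossSection <- function(crop, trace, positionUm = 2, spanUm = 1,
                                spacing = c(0.5, 0.2, 0.2),
                                pixelSpacing = 0.05, patchRadiusUm = 1.2,
                                cellId = "cell") {
  arc <- trace@arclength
  if (positionUm < 0 || positionUm + spanUm > max(arc))
    stop(sprintf("section window [%.2f, %.2f] um lies beyond the trace extent %.2f um",
                 positionUm, positionUm + spanUm, max(arc)))
  pathPhys <- sweep(trace@path, 2, spacing, "*")
  planeAt <- function(s) {
    i <- which.min(abs(arc - s))
    i0 <- max(1L, i - 2L); i1 <- min(length(arc), i + 2L)
    tg <- pathPhys[i1, ] - pathPhys[i0, ]
    tg <- tg / sqrt(sum(tg^2))
    list(center = pathPhys[i, ], tangent = tg, idx = i)
  }
  sPos <- seq(positionUm, positionUm + spanUm, length.out = 5)
  mid <- planeAt(positionUm + spanUm / 2)
  tg <- mid$tangent
  ref <- if (abs(tg[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  nv <- ref - sum(ref * tg) * tg; nv <- nv / sqrt(sum(nv^2))
  bv <- c(tg[2] * nv[3] - tg[3] * nv[2], tg[3] * nv[1] - tg[1] * nv[3],
          tg[1] * nv[2] - tg[2] * nv[1])
  half <- ceiling(patchRadiusUm / pixelSpacing)
  n <- 2L * half + 1L
  u <- ((1:n) - half - 1) * pixelSpacing
  v <- rev(u)
  UV <- expand.grid(vi = seq_len(n), ui = seq_len(n))
  U <- matrix(u[UV$ui], n, n); V <- matrix(v[UV$vi], n, n)
  buildPatch <- function(offU, offV) {
    img <- matrix(0, n, n)
    for (s in sPos) {
      pl <- planeAt(s)
      ctr <- pl$center + offU * nv + offV * bv
      pts <- matrix(ctr, n * n, 3, byrow = TRUE) +
        u[UV$ui] %o% nv + v[UV$vi] %o% bv
      voxPts <- sweep(pts, 2, spacing, "/") + 1
      img <- img + matrix(trilinear(crop, voxPts), n, n)
    }
    img / length(sPos)
  }
  # the extracted skeleton rides the bright nanodomain shell rather than the
  # geometric axis; re-centre the patch on its intensity centroid (the ring
  # is symmetric about the true axis) before sampling
  offU <- 0; offV <- 0
  img <- buildPatch(offU, offV)
  for (it in 1:3) {
    w <- pmax(img - stats::quantile(img, 0.5), 0)
    tw <- sum(w)
    if (tw <= 0) break
    dU <- sum(w * U) / tw; dV <- sum(w * V) / tw
    offU <- offU + dU; offV <- offV + dV
    img <- buildPatch(offU, offV)
    if (sqrt(dU^2 + dV^2) < pixelSpacing / 4) break
  }
  # radius of curvature over the span: R = span / turning angle; flag R < span
  tA <- planeAt(positionUm)$tangent; tB <- planeAt(positionUm + spanUm)$tangent
  ang <- acos(pmin(1, pmax(-1, sum(tA * tB))))
  flags <- if (ang > 1) "curved" else character()
  new("CrossSection", image = img, pixelSpacing = pixelSpacing,
      cellId = cellId, span = spanUm, rotation = 0, flags = flags)
}

quadrantSums <- function(img) {
  n <- nrow(img); half <- (n - 1L) %/% 2L
  top <- seq_len(half); bot <- (half + 2L):n
  left <- seq_len(half); right <- (half + 2L):n
  c(TR = sum(img[top, right]), TL = sum(img[top, left]),
    BL = sum(img[bot, left]), BR = sum(img[bot, right]))
}

#' Align a cross-section by its brightest quadrant
#'
#' Rotates the patch by a multiple of 90 degrees (counterclockwise positive)
#' so that the Cartesian quadrant with the greatest summed intensity sits
#' top-right, mirroring the manual alignment convention. Ties resolve to the
#' smallest rotation.
#'
#' @param section a \linkS4class{CrossSection}.
#' @return the section rotated, with the applied rotation recorded (degrees).
#' @export
alignQuadrant <- function(section) {
  img <- section@image
  best <- 0L; bestVal <- -Inf
  cur <- img
  for (k in 0:3) {
    qs <- quadrantSums(cur)
    if (qs["TR"] > bestVal + 1e-12) { bestVal <- qs["TR"]; best <- k }
    cur <- rot90ccw(cur)
  }
  out <- img
  if (best > 0) for (k in seq_len(best)) out <- rot90ccw(out)
  new("CrossSection", image = out, pixelSpacing = section@pixelSpacing,
      cellId = section@cellId, span = section@span,
      rotation = section@rotation + 90 * best, flags = section@flags)
}

#' Superpose aligned cross-sections
#'
#' Each section is normalized by its total intensity, then the patch stack is
#' averaged pixelwise.
#'
#' @param sections list of aligned \linkS4class{CrossSection} of one size.
#' @return A \linkS4class{CrossSection} holding the cumulative image.
#' @export
superposeSections <- function(sections) {
  if (length(sections) == 0L) stop("at least one section required")
  dims <- vapply(sections, function(s) nrow(s@image), integer(1))
  if (length(unique(dims)) != 1L) stop("sections differ in patch size")
  acc <- 0
  for (s in sections) {
    tot <- sum(s@image)
    acc <- acc + if (tot > 0) s@image / tot else s@image
  }
  img <- acc / length(sections)
  new("CrossSection", image = img, pixelSpacing = sections[[1]]@pixelSpacing,
      cellId = "superposition", span = sections[[1]]@span, rotation = 0,
      flags = character())
}

#' Sample the 80-area angular intensity profile
#'
#' Eighty circular sampling areas are placed on a ring at the membrane radius,
#' 4.5 degrees apart, ordered counterclockwise from the +u axis; each area
#' value is the mean intensity within the area. When no ring radius is given
#' it is fitted per section by maximizing the mean ring intensity.
#'
#' @param section an aligned \linkS4class{CrossSection}.
#' @param ringRadiusUm ring radius, um (NULL = fit).
#' @param areaRadiusUm sampling-area radius, um (default: half the
#'   inter-centre arc, at least one pixel).
#' @return A \linkS4class{QuadProfile} with areas filled (delta not yet
#'   computed; see \code{\link{quadDelta}}).
#' @export
sample80Areas <- function(section, ringRadiusUm = NULL, areaRadiusUm = NULL) {
  img <- section@image
  n <- nrow(img); half <- (n - 1L) %/% 2L
  px <- section@pixelSpacing
  maxR <- half * px
  angles <- (seq_len(80L) - 1L) * 4.5 * pi / 180
  meanRing <- function(R, aR) {
    mean(vapply(angles, function(a) areaMean(img, px, R * cos(a), R * sin(a), aR),
                numeric(1)))
  }
  if (is.null(ringRadiusUm)) {
    cand <- seq(2 * px, 0.85 * maxR, by = px)
    vals <- vapply(cand, function(R)
      meanRing(R, max(px, R * pi / 80)), numeric(1))
    ringRadiusUm <- cand[which.max(vals)]
  }
  if (is.null(areaRadiusUm))
    areaRadiusUm <- max(px, ringRadiusUm * pi / 80)
  if (ringRadiusUm + areaRadiusUm > maxR)
    stop(sprintf("ring radius %.2f + area radius %.2f um exceeds the patch half-extent %.2f um",
                 ringRadiusUm, areaRadiusUm, maxR))
  areas <- vapply(angles, function(a)
    areaMean(img, px, ringRadiusUm * cos(a), ringRadiusUm * sin(a),
             areaRadiusUm), numeric(1))
  new("QuadProfile", areas = areas, peakIdx = integer(4), valleyIdx = integer(4),
      peaks = rep(NA_real_, 4), valleys = rep(NA_real_, 4),
      delta = NA_real_, deltaPairwise = NA_real_,
      rotation = section@rotation, flag = "")
}

# Mean intensity within a circular area centred at (u0, v0) um; rows of img
# run from +v (top) downward, columns from -u to +u.
areaMean <- function(img, px, u0, v0, aR) {
  n <- nrow(img); half <- (n - 1L) %/% 2L
  ci <- half + 1 + u0 / px   # column of the centre (fractional)
  ri <- half + 1 - v0 / px   # row of the centre (fractional)
  rpx <- aR / px
  r0 <- max(1L, floor(ri - rpx)); r1 <- min(n, ceiling(ri + rpx))
  c0 <- max(1L, floor(ci - rpx)); c1 <- min(n, ceiling(ci + rpx))
  rows <- r0:r1; cols <- c0:c1
  dd <- outer((rows - ri)^2, (cols - ci)^2, "+")
  sel <- dd <= max(rpx, 0.5)^2
  if (!any(sel)) return(img[round(ri), round(ci)])
  mean(img[rows, cols][sel])
}

#' Peaks, valleys and the delta statistic of an 80-area profile
#'
#' The angular profile is smoothed with a circular moving average; the four
#' highest smoothed local maxima are the peaks, and each valley is the
#' smoothed minimum strictly between consecutive peaks (circularly). Peak and
#' valley VALUES are read from the unsmoothed profile at those locations, so
#' an ideal unit-contrast quadrilateral yields delta = 1 exactly. delta =
#' mean(peaks) - mean(valleys); the per-pair variant averages each peak minus
#' its following valley. Profiles with fewer than four smoothed maxima are
#' flagged "non_quadrilateral" and fall back to the top-4/bottom-4 smoothed
#' values (an angularly homogeneous profile thus gives delta = 0, the
#' baseline).
#'
#' @param profile a \linkS4class{QuadProfile} with areas filled.
#' @param window circular moving-average window, in areas (odd).
#' @return the profile with peaks, valleys and delta filled.
#' @export
quadDelta <- function(profile, window = 5L) {
  x <- profile@areas
  n <- length(x)
  sm <- circularMA(x, window)
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
  isMax <- sm > sm[nxt] & sm >= sm[prv]
  maxIdx <- which(isMax)
  flag <- ""
  h <- (window - 1L) %/% 2L
  refine <- function(i, fun) {
    win <- ((i - 1L + seq(-h, h)) %% n) + 1L
    win[fun(x[win])]
  }
  if (length(maxIdx) >= 4L) {
    peakIdx <- maxIdx[order(sm[maxIdx], decreasing = TRUE)][1:4]
    # smoothing can turn an isolated peak into a plateau whose edge wins the
    # local-maximum test; refine each location to the raw extremum nearby
    peakIdx <- sort(vapply(peakIdx, refine, integer(1), fun = which.max))
    valleyIdx <- integer(4)
    for (k in 1:4) {
      a <- peakIdx[k]; b <- peakIdx[if (k == 4) 1 else k + 1]
      ring <- if (b > a) (a + 1):(b - 1) else c(if (a < n) (a + 1):n else NULL,
                                                if (b > 1) 1:(b - 1) else NULL)
      if (length(ring) == 0L) ring <- a
      valleyIdx[k] <- refine(ring[which.min(sm[ring])], which.min)
    }
    peaks <- x[peakIdx]; valleys <- x[valleyIdx]
  } else {
    flag <- "non_quadrilateral"
    ord <- order(sm, decreasing = TRUE)
    peakIdx <- sort(ord[1:4]); valleyIdx <- sort(rev(ord)[1:4])
    peaks <- sm[peakIdx]; valleys <- sm[valleyIdx]
  }
  delta <- mean(peaks) - mean(valleys)
  deltaPair <- mean(peaks - valleys)
  new("QuadProfile", areas = x, peakIdx = as.integer(peakIdx),
      valleyIdx = as.integer(valleyIdx), peaks = peaks, valleys = valleys,
      delta = delta, deltaPairwise = deltaPair,
      rotation = profile@rotation, flag = flag)
}

#' Per-region delta summary table
#'
#' @param deltas numeric vector of per-cell delta values.
#' @param regions factor/character of region labels, same length.
#' @return data.frame(region, n, mean_delta, sem_delta) with one flagged row
#'   (n = 0, NA summaries) per empty region level.
#' @export
regionDeltaTable <- function(deltas, regions) {
  if (length(deltas) != length(regions))
    stop("deltas and regions differ in length")
  regions <- as.factor(regions)
  rows <- lapply(levels(regions), function(r) {
    v <- deltas[regions == r]
    data.frame(region = r, n = length(v),
               mean_delta = if (length(v)) mean(v) else NA_real_,
               sem_delta = if (length(v) > 1) sd(v) / sqrt(length(v))
                           else if (length(v) == 1) 0 else NA_real_,
               flagged = length(v) == 0L)
  })
  do.call(rbind, rows)
}
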