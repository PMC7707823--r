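#' SignatureSpec: parameters of one signature class in a simulated volume
#'
#' Describes how many objects of a class ("sperm", "nucleus" or "noise") to
#' expect per cubic micrometre and how to render each instance. Use the
#' constructors \code{\link{spermSpec}}, \code{\link{nucleusSpec}} and
#' \code{\link{noiseSpec}}.
#'
#' @slot signatureClass one of "sperm", "nucleus", "noise".
#' @slot abundance expected object count per um^3.
#' @slot params named list of class-specific geometry/intensity parameters.
#' @export
setClass("SignatureSpec", representation(
  signatureClass = "character", abundance = "numeric", params = "list"
))

setValidity("SignatureSpec", function(object) {
  msg <- character()
  if (!object@signatureClass %in% c("sperm", "nucleus", "noise"))
    msg <- c(msg, "class must be sperm/nucleus/noise")
  if (length(object@abundance) != 1L || object@abundance < 0)
    msg <- c(msg, "abundance must be a single value >= 0")
  if (object@signatureClass == "sperm") {
    a <- object@params$nanodomainAngles
    if (any(a < 0 | a >= 360)) msg <- c(msg, "nanodomain angles must lie in [0,360)")
    if (anyDuplicated(a)) msg <- c(msg, "nanodomain angles must be pairwise distinct")
  }
  if (length(msg)) msg else TRUE
})

#' Sperm signature specification
#'
#' A sperm is rendered as a smoothly curved flagellar tube whose cross-section
#' carries intensity maxima at the nanodomain angles (four by default,
#' 90 degrees apart — the quadrilateral CatSper arrangement), plus a bright
#' head at the proximal end. Intensities are on a head-normalized scale
#' (head = 1 by default).
#'
#' @param abundance expected sperm per um^3.
#' @param tailLength mean tail (principal piece) length, um.
#' @param tailLengthSd SD of the per-cell tail length, um.
#' @param tailRadius radius of the nanodomain ring around the axoneme, um.
#' @param curvatureSd SD of the slowly varying centerline curvature, rad/um.
#' @param maxCurvature hard curvature bound, rad/um (keeps linearization
#'   well-posed).
#' @param nanodomainAngles angular positions of the longitudinal nanodomain
#'   stripes, degrees in [0,360); each cell additionally receives a uniformly
#'   random roll so section orientation is random, as in real imaging.
#' @param peakWidthDeg angular Gaussian width of each stripe, degrees.
#' @param peakIntensity stripe (peak) intensity.
#' @param valleyIntensity inter-stripe (valley) ring intensity.
#' @param headSigma Gaussian sigmas of the head/nucleus blob (z,y,x), um.
#' @param headIntensity peak head intensity (the normalization reference).
#' @return A \linkS4class{SignatureSpec}.
#' @export
spermSpec <- function(abundance, tailLength = 12, tailLengthSd = 1,
                      tailRadius = 0.4, curvatureSd = 0.08, maxCurvature = 0.25,
                      nanodomainAngles = c(45, 135, 225, 315),
                      peakWidthDeg = 18, peakIntensity = 0.7,
                      valleyIntensity = 0.25, headSigma = c(1.0, 0.8, 0.8),
                      headIntensity = 1.0) {
  new("SignatureSpec", signatureClass = "sperm", abundance = abundance, params = list(
    tailLength = tailLength, tailLengthSd = tailLengthSd,
    tailRadius = tailRadius, curvatureSd = curvatureSd,
    maxCurvature = maxCurvature, nanodomainAngles = nanodomainAngles,
    peakWidthDeg = peakWidthDeg, peakIntensity = peakIntensity,
    valleyIntensity = valleyIntensity, headSigma = headSigma,
    headIntensity = headIntensity))
}

#' Somatic nucleus signature specification
#'
#' @param abundance expected nuclei per um^3.
#' @param radii Gaussian sigmas of the ellipsoid (z,y,x), um.
#' @param radiusJitter lognormal sdlog of a per-object size factor.
#' @param intensity peak intensity.
#' @return A \linkS4class{SignatureSpec}.
#' @export
nucleusSpec <- function(abundance, radii = c(1.8, 1.4, 1.4),
                        radiusJitter = 0.15, intensity = 0.9) {
  new("SignatureSpec", signatureClass = "nucleus", abundance = abundance, params = list(
    radii = radii, radiusJitter = radiusJitter, intensity = intensity))
}

#' Noise signature specification
#'
#' Noise objects are compact blobs with parabolic radial profile
#' I0 (1 - (d/r)^2)+ so their voxel occupancy is exact: a voxel is occupied
#' iff its unblurred noise intensity is nonzero.
#'
#' @param abundance expected blobs per um^3.
#' @param radiusMeanlog,radiusSdlog lognormal parameters of the blob radius (um).
#' @param intensityMin,intensityMax uniform range of the blob peak intensity.
#' @return A \linkS4class{SignatureSpec}.
#' @export
noiseSpec <- function(abundance, radiusMeanlog = log(0.5), radiusSdlog = 0.4,
                      intensityMin = 0.2, intensityMax = 0.8) {
  new("SignatureSpec", signatureClass = "noise", abundance = abundance, params = list(
    radiusMeanlog = radiusMeanlog, radiusSdlog = radiusSdlog,
    intensityMin = intensityMin, intensityMax = intensityMax))
}

# Truncated anisotropic Gaussian patch for in-place accumulation by the
# caller (avoids copying the full volume per splat). center/sigma in physical
# um (z,y,x); returns NULL or list(zi, yi, xi, blob) of 1-based index ranges.
gaussPatch <- function(dimGlobal, center, sigma, amplitude, spacing, trunc = 3) {
  lo <- pmax(1L, as.integer(floor((center - trunc * sigma) / spacing)) + 1L)
  hi <- pmin(dimGlobal, as.integer(ceiling((center + trunc * sigma) / spacing)) + 1L)
  if (any(lo > hi)) return(NULL)
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  gz <- exp(-(((zi - 1) * spacing[1] - center[1])^2) / (2 * sigma[1]^2))
  gy <- exp(-(((yi - 1) * spacing[2] - center[2])^2) / (2 * sigma[2]^2))
  gx <- exp(-(((xi - 1) * spacing[3] - center[3])^2) / (2 * sigma[3]^2))
  blob <- amplitude * (gz %o% gy %o% gx)
  # compact support: zero the corners beyond the truncation ellipsoid
  rz <- ((zi - 1) * spacing[1] - center[1]) / (trunc * sigma[1])
  ry <- ((yi - 1) * spacing[2] - center[2]) / (trunc * sigma[2])
  rx <- ((xi - 1) * spacing[3] - center[3]) / (trunc * sigma[3])
  rr <- outer(outer(rz^2, ry^2, "+"), rx^2, "+")
  blob[rr > 1] <- 0
  list(zi = zi, yi = yi, xi = xi, blob = blob)
}

# Sample a bounded-curvature 3D centerline: unit steps of ds with a slowly
# varying (AR(1)) curvature vector clipped at maxCurv. Returns n x 3 physical
# coordinates plus tangents, normals (parallel-transported), binormals.
sampleCenterline <- function(start, dir0, length, ds, curvSd, maxCurv,
                             corLength = 3) {
  n <- max(2L, as.integer(round(length / ds)) + 1L)
  pos <- matrix(0, n, 3); tan <- matrix(0, n, 3)
  nor <- matrix(0, n, 3); bin <- matrix(0, n, 3)
  pos[1, ] <- start
  t <- dir0 / sqrt(sum(dir0^2))
  # a stable initial normal
  ref <- if (abs(t[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  nv <- ref - sum(ref * t) * t; nv <- nv / sqrt(sum(nv^2))
  rho <- exp(-ds / corLength)
  k <- rnorm(3, 0, curvSd)
  tan[1, ] <- t; nor[1, ] <- nv; bin[1, ] <- c(
    t[2] * nv[3] - t[3] * nv[2], t[3] * nv[1] - t[1] * nv[3],
    t[1] * nv[2] - t[2] * nv[1])
  for (i in 2:n) {
    k <- rho * k + sqrt(1 - rho^2) * rnorm(3, 0, curvSd)
    kp <- k - sum(k * t) * t            # curvature acts orthogonally
    kn <- sqrt(sum(kp^2))
    if (kn > maxCurv) kp <- kp * (maxCurv / kn)
    t <- t + ds * kp
    t <- t / sqrt(sum(t^2))
    pos[i, ] <- pos[i - 1, ] + ds * t
    nv <- nv - sum(nv * t) * t
    nv <- nv / sqrt(sum(nv^2))
    tan[i, ] <- t; nor[i, ] <- nv
    bin[i, ] <- c(t[2] * nv[3] - t[3] * nv[2], t[3] * nv[1] - t[1] * nv[3],
                  t[1] * nv[2] - t[2] * nv[1])
  }
  list(pos = pos, tangent = tan, normal = nor, binormal = bin)
}

# Angular intensity law of the nanodomain ring, degrees in, intensity out.
angularLaw <- function(thetaDeg, angles, widthDeg, peak, valley) {
  v <- rep(0, length(thetaDeg))
  for (a in angles) {
    dd <- abs(((thetaDeg - a + 180) %% 360) - 180)
    v <- v + exp(-dd^2 / (2 * widthDeg^2))
  }
  valley + (peak - valley) * pmin(v, 1)
}

#' Render a synthetic 3D training/evaluation environment
#'
#' Places Poisson-distributed numbers of sperm, somatic-nucleus and noise
#' signatures into a 3D volume, convolves with a Gaussian blur kernel, adds
#' background, and returns the volume together with exact ground truth
#' (object table, per-voxel attribution labels, tail centerlines). Identical
#' seed, specs and shape give bit-identical output.
#'
#' @param specs list of \linkS4class{SignatureSpec}.
#' @param shape integer(3) voxel counts (z, y, x).
#' @param spacing numeric(3) voxel size (z, y, x), um.
#' @param blurSigma isotropic Gaussian blur sigma, um (0 disables blur).
#' @param background list(offset=, sd=): constant offset plus Gaussian read
#'   noise added to the composite channel (clamped at 0).
#' @param seed integer seed; all randomness derives from it.
#' @return A \linkS4class{SimulatedEnvironment}.
#' @examples
#' env <- renderEnvironment(list(spermSpec(0), noiseSpec(0)), shape = c(8, 16, 16),
#'                          blurSigma = 0, background = list(offset = 0, sd = 0),
#'                          seed = 1)
#' nrow(gtObjects(envTruth(env)))
#' @export
renderEnvironment <- function(specs, shape,
                              spacing = c(0.5, 0.2, 0.2),
                              blurSigma = 0.15,
                              background = list(offset = 0.02, sd = 0.01),
                              seed) {
  if (missing(seed)) stop("renderEnvironment() requires an explicit seed")
  if (blurSigma < 0) stop("blurSigma must be >= 0")
  stopifnot(length(shape) == 3L, all(shape >= 2), length(spacing) == 3L,
            all(spacing > 0))
  shape <- as.integer(shape)
  ext <- (shape - 1) * spacing
  diag <- sqrt(sum(ext^2))
  for (sp in specs) {
    stopifnot(is(sp, "SignatureSpec"))
    if (sp@signatureClass == "sperm" && sp@abundance > 0 &&
        sp@params$tailLength > diag)
      stop(sprintf(paste0("volume too small: tail length %.1f um exceeds the ",
                          "volume diagonal %.1f um at the given spacing"),
                   sp@params$tailLength, diag))
  }
  set.seed(deriveSeed(seed, 1L))
  volUm3 <- prod(shape * spacing)
  zero <- array(0, shape)
  chTail <- zero; chHead <- zero; chNucleus <- zero; chNoise <- zero
  labels <- array(0L, shape)
  eps <- 1e-12
  rows <- list(); centerlines <- list()
  objId <- 0L
  ds <- 0.1

  claimVoxels <- function(localDelta) {
    # first-writer-wins attribution of newly nonzero voxels
    idx <- which(localDelta > eps & labels == 0L)
    labels[idx] <<- objId
    idx
  }

  for (sp in specs) {
    n <- rpois(1, sp@abundance * volUm3)
    if (n == 0) next
    p <- sp@params
    for (i in seq_len(n)) {
      objId <- objId + 1L
      clipped <- FALSE
      if (sp@signatureClass == "sperm") {
        before <- chTail + chHead
        center <- runif(3) * ext
        dir0 <- rnorm(3); dir0 <- dir0 / sqrt(sum(dir0^2))
        roll <- runif(1, 0, 360)
        L <- max(2, rnorm(1, p$tailLength, p$tailLengthSd))
        start <- center + 1.5 * max(p$headSigma) * dir0
        cl <- sampleCenterline(start, dir0, L, ds, p$curvatureSd, p$maxCurvature)
        shellSigma <- 0.08   # tight sub-tubes keep the ring hollow at the axis
        lineFactor <- sqrt(2 * pi) * shellSigma / ds
        nAng <- 24L
        angs <- seq(0, 360, length.out = nAng + 1L)[-(nAng + 1L)]
        arcStep <- 2 * pi * p$tailRadius / nAng
        angFactor <- max(1, sqrt(2 * pi) * shellSigma / arcStep)
        amp <- angularLaw(angs + roll, p$nanodomainAngles, p$peakWidthDeg,
                          p$peakIntensity, p$valleyIntensity) /
               (lineFactor * angFactor)
        sg <- rep(shellSigma, 3)
        ca <- cos(angs * pi / 180); sa <- sin(angs * pi / 180)
        for (ii in seq_len(nrow(cl$pos))) {
          base <- cl$pos[ii, ]
          for (jj in seq_len(nAng)) {
            pt <- base + p$tailRadius *
              (ca[jj] * cl$normal[ii, ] + sa[jj] * cl$binormal[ii, ])
            if (any(pt < -3 * shellSigma | pt > ext + 3 * shellSigma)) {
              clipped <- TRUE
              next
            }
            g <- gaussPatch(shape, pt, sg, amp[jj], spacing)
            if (!is.null(g))
              chTail[g$zi, g$yi, g$xi] <- chTail[g$zi, g$yi, g$xi] + g$blob
          }
        }
        if (any(center - 3 * p$headSigma < 0 | center + 3 * p$headSigma > ext))
          clipped <- TRUE
        g <- gaussPatch(shape, center, p$headSigma, p$headIntensity, spacing)
        if (!is.null(g))
          chHead[g$zi, g$yi, g$xi] <- chHead[g$zi, g$yi, g$xi] + g$blob
        delta <- (chTail + chHead) - before
        claimVoxels(delta)
        cen <- weightedCentroid(delta)
        centerlines[[as.character(objId)]] <-
          sweep(cl$pos, 2, spacing, "/")  # 0-based voxel coordinates
        rows[[objId]] <- data.frame(
          object_id = objId, class = "sperm",
          cz = cen[1], cy = cen[2], cx = cen[3],
          orientation_deg = roll, clipped = clipped,
          params_json = as.character(jsonlite::toJSON(list(
            tailLength = L, tailRadius = p$tailRadius,
            nanodomainAngles = p$nanodomainAngles,
            peakIntensity = p$peakIntensity,
            valleyIntensity = p$valleyIntensity,
            headIntensity = p$headIntensity,
            head = center / spacing), auto_unbox = TRUE, digits = 6)),
          stringsAsFactors = FALSE)
      } else if (sp@signatureClass == "nucleus") {
        before <- chNucleus
        center <- runif(3) * ext
        sizeF <- rlnorm(1, 0, p$radiusJitter)
        sg <- p$radii * sizeF
        if (any(center - 3 * sg < 0 | center + 3 * sg > ext)) clipped <- TRUE
        g <- gaussPatch(shape, center, sg, p$intensity, spacing)
        if (!is.null(g))
          chNucleus[g$zi, g$yi, g$xi] <- chNucleus[g$zi, g$yi, g$xi] + g$blob
        delta <- chNucleus - before
        claimVoxels(delta)
        cen <- weightedCentroid(delta)
        rows[[objId]] <- data.frame(
          object_id = objId, class = "nucleus",
          cz = cen[1], cy = cen[2], cx = cen[3],
          orientation_deg = 0, clipped = clipped,
          params_json = as.character(jsonlite::toJSON(list(
            radii = sg, intensity = p$intensity), auto_unbox = TRUE,
            digits = 6)),
          stringsAsFactors = FALSE)
      } else { # noise blob, parabolic compact profile
        center <- runif(3) * ext
        r <- rlnorm(1, p$radiusMeanlog, p$radiusSdlog)
        I0 <- runif(1, p$intensityMin, p$intensityMax)
        d <- dim(chNoise)
        lo <- pmax(1L, as.integer(floor((center - r) / spacing)) + 1L)
        hi <- pmin(d, as.integer(ceiling((center + r) / spacing)) + 1L)
        if (any(center - r < 0 | center + r > ext)) clipped <- TRUE
        if (all(lo <= hi)) {
          zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
          dz <- ((zi - 1) * spacing[1] - center[1])^2
          dy <- ((yi - 1) * spacing[2] - center[2])^2
          dx <- ((xi - 1) * spacing[3] - center[3])^2
          dd <- outer(outer(dz, dy, "+"), dx, "+")
          blob <- I0 * pmax(1 - dd / r^2, 0)  # pmax(x, 0) keeps dim()
          before <- chNoise[zi, yi, xi]
          chNoise[zi, yi, xi] <- before + blob
          idxLocal <- which(blob > eps)
          coords <- arrayInd(idxLocal, dim(blob))
          gi <- (coords[, 1] + lo[1] - 1L) +
                d[1] * (coords[, 2] + lo[2] - 2L) +
                d[1] * d[2] * (coords[, 3] + lo[3] - 2L)
          free <- labels[gi] == 0L
          labels[gi[free]] <- objId
        }
        rows[[objId]] <- data.frame(
          object_id = objId, class = "noise",
          cz = center[1] / spacing[1], cy = center[2] / spacing[2],
          cx = center[3] / spacing[3],
          orientation_deg = 0, clipped = clipped,
          params_json = as.character(jsonlite::toJSON(list(
            radius = r, intensity = I0), auto_unbox = TRUE, digits = 6)),
          stringsAsFactors = FALSE)
      }
    }
  }

  objects <- if (length(rows)) do.call(rbind, rows) else data.frame(
    object_id = integer(), class = character(), cz = numeric(),
    cy = numeric(), cx = numeric(), orientation_deg = numeric(),
    clipped = logical(), params_json = character(), stringsAsFactors = FALSE)

  nr <- sum(chNoise > 0) / length(chNoise)
  classSperm <- chTail + chHead
  sigVox <- rep(blurSigma, 3) / spacing
  blurIt <- function(a) if (blurSigma > 0) gaussianBlur3D(a, sigVox) else a
  composite <- blurIt(classSperm + chNucleus + chNoise)
  if (background$offset != 0 || background$sd != 0) {
    composite <- composite + background$offset +
      rnorm(length(composite), 0, background$sd)
    composite <- pmax(composite, 0)
  }
  channels <- list(
    nuclei = VoxelGrid(blurIt(chHead + chNucleus), spacing, "nuclei"),
    catsper = VoxelGrid(blurIt(chTail), spacing, "catsper"),
    noise = VoxelGrid(chNoise, spacing, "noise"),
    class_sperm = VoxelGrid(classSperm, spacing, "class_sperm"),
    class_nucleus = VoxelGrid(chNucleus, spacing, "class_nucleus"),
    class_noise = VoxelGrid(chNoise, spacing, "class_noise"))
  new("SimulatedEnvironment",
      volume = VoxelGrid(composite, spacing, "composite"),
      channels = channels, labels = labels,
      truth = new("GroundTruth", objects = objects, noiseRate = nr),
      centerlines = centerlines, seed = as.numeric(seed))
}

#' Render a 2D quadrilateral nanodomain cross-section
#'
#' Produces a ring image whose angular intensity law has maxima at exactly
#' four given angles — a synthetic stand-in for one transversal projection of
#' the flagellum at the principal piece.
#'
#' @param radius ring radius, um.
#' @param peakPositions exactly 4 angles in degrees (counterclockwise from +u).
#' @param peakWidthDeg angular Gaussian width of each peak, degrees.
#' @param peakHeight,valleyHeight intensities, peakHeight >= valleyHeight >= 0.
#' @param noiseSd additive Gaussian noise SD (0 = noiseless).
#' @param seed integer seed for the noise.
#' @param pixelSpacing um per pixel.
#' @param ringWidth radial Gaussian width of the ring, um.
#' @param patchRadius half-extent of the square patch, um.
#' @return A \linkS4class{CrossSection}.
#' @export
renderQuadCrossSection <- function(radius, peakPositions,
                                   peakWidthDeg = 25, peakHeight = 1,
                                   valleyHeight = 0, noiseSd = 0, seed = 1,
                                   pixelSpacing = 0.02,
                                   ringWidth = radius * 0.3,
                                   patchRadius = radius * 2) {
  if (length(peakPositions) != 4L)
    stop("exactly 4 peak positions are required (the nanodomain count is fixed at 4)")
  if (!(peakHeight >= valleyHeight && valleyHeight >= 0))
    stop("need peakHeight >= valleyHeight >= 0")
  half <- ceiling(patchRadius / pixelSpacing)
  n <- 2L * half + 1L
  u <- ((1:n) - half - 1) * pixelSpacing        # columns: -u .. +u
  v <- rev(u)                                    # rows: +v at top
  U <- matrix(u, n, n, byrow = TRUE)
  V <- matrix(v, n, n)
  r <- sqrt(U^2 + V^2)
  th <- (atan2(V, U) * 180 / pi) %% 360
  img <- angularLaw(th, peakPositions, peakWidthDeg, peakHeight, valleyHeight) *
    exp(-(r - radius)^2 / (2 * ringWidth^2))
  if (noiseSd > 0) {
    set.seed(deriveSeed(seed, 7L))
    img <- pmax(img + rnorm(length(img), 0, noiseSd), 0)  # pmax(x, 0) keeps dim()
  }
  new("CrossSection", image = img, pixelSpacing = pixelSpacing,
      cellId = "synthetic", span = 0, rotation = 0, flags = character())
}
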