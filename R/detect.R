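#' Tile a volume into analytical frames
#'
#' Frames of a fixed voxel shape are proposed on a regular grid; the final
#' origin along each axis is clamped so the tiling always covers the volume
#' boundary when stride <= frame shape.
#'
#' @param volume a \linkS4class{VoxelGrid}.
#' @param frameShape integer(3) frame shape (z,y,x), each <= volume shape.
#' @param stride integer(3) strictly positive step between frame origins.
#' @return An \linkS4class{AnalyticalFrameSet} (unclassified).
#' @export
extractFrames <- function(volume, frameShape, stride = frameShape) {
  d <- dim(voxelData(volume))
  frameShape <- as.integer(frameShape); stride <- as.integer(stride)
  if (any(stride <= 0L)) stop("stride must be strictly positive on every axis")
  if (any(frameShape > d)) stop("frameShape exceeds the volume shape")
  axisOrigins <- function(ax) {
    last <- d[ax] - frameShape[ax]
    o <- seq(0L, last, by = stride[ax])
    if (o[length(o)] < last) o <- c(o, last)
    o
  }
  og <- as.matrix(expand.grid(z = axisOrigins(1), y = axisOrigins(2),
                              x = axisOrigins(3)))
  a <- voxelData(volume)
  crops <- lapply(seq_len(nrow(og)), function(i) {
    a[og[i, 1] + seq_len(frameShape[1]),
      og[i, 2] + seq_len(frameShape[2]),
      og[i, 3] + seq_len(frameShape[3]), drop = FALSE]
  })
  n <- nrow(og)
  new("AnalyticalFrameSet", crops = crops, origins = og,
      frameShape = frameShape, spacing = voxelSpacing(volume),
      scores = matrix(NA_real_, n, 3,
                      dimnames = list(NULL, c("sperm", "nucleus", "noise"))),
      predictedClass = rep(NA_character_, n),
      coords = matrix(NA_real_, n, 3))
}

# Weighted-PCA shape summary of one intensity band: voxel count (log1p),
# weighted sd along the principal axes (um), anisotropy ratios, centroid
# offset from the frame centre (um), and mean band intensity.
bandShape <- function(x, sel, spacing, center) {
  if (sum(sel) < 5L)
    return(c(log1p(sum(sel)), 0, 0, 0, 1, 1, 0, 0))
  co <- sweep(arrayInd(which(sel), dim(x)), 2, spacing, "*")
  w <- pmax(x[sel], 1e-6)
  mu <- colSums(co * w) / sum(w)
  cc <- sweep(co, 2, mu, "-")
  cv <- crossprod(cc * sqrt(w)) / sum(w)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev <- pmax(ev, 1e-12)
  c(log1p(sum(sel)), sqrt(ev[1]), sqrt(ev[2]), sqrt(ev[3]),
    ev[2] / ev[1], ev[3] / ev[1],
    sqrt(sum((mu - center)^2)), mean(x[sel]))
}

# Feature vector of one frame crop. Frames are candidate-centred, so
# intensities are normalized to the peak of the centre object (max over a
# small centred window) rather than a global quantile — neighbouring objects
# in the frame then cannot corrupt the scale. Features: global intensity
# summaries; weighted-PCA shape statistics of three intensity bands (bright
# core / mid "tail" band / Otsu foreground — an elongated mid band is the
# signature of a flagellum, while a blurred blob's mid band is an isotropic
# shell); the same core/mid statistics restricted to a centred ball (the
# centre object only); and coarse block means.
frameFeatures <- function(crop, grid, spacing) {
  d <- dim(crop)
  med <- median(crop)
  cwin <- pmax(1L, as.integer(round(0.6 / spacing)))
  cmid <- (d + 1) / 2
  zi <- max(1, floor(cmid[1] - cwin[1])):min(d[1], ceiling(cmid[1] + cwin[1]))
  yi <- max(1, floor(cmid[2] - cwin[2])):min(d[2], ceiling(cmid[2] + cwin[2]))
  xi <- max(1, floor(cmid[3] - cwin[3])):min(d[3], ceiling(cmid[3] + cwin[3]))
  centerPeak <- max(crop[zi, yi, xi])
  sc <- centerPeak - med + 1e-6
  x <- (crop - med) / sc
  center <- (d - 1) / 2 * spacing
  q <- as.numeric(quantile(x, c(0.5, 0.9, 0.99)))
  glob <- c(mean(x), sd(x), max(x), q)
  coreSel <- x >= 0.5
  midSel <- x >= 0.12 & x < 0.45
  core <- bandShape(x, coreSel, spacing, center)
  mid <- bandShape(x, midSel, spacing, center)
  th <- otsuThreshold(x)
  fg <- bandShape(x, x >= th & x > 0.05, spacing, center)
  # centred ball (radius 2.5 um): statistics of the centre object alone
  co <- arrayInd(seq_along(x), d)
  rr <- array(sqrt(((co[, 1] - cmid[1]) * spacing[1])^2 +
                   ((co[, 2] - cmid[2]) * spacing[2])^2 +
                   ((co[, 3] - cmid[3]) * spacing[3])^2), d)
  ball <- rr <= 2.5
  coreC <- bandShape(x, coreSel & ball, spacing, center)
  midC <- bandShape(x, midSel & ball, spacing, center)
  sh <- shellFeatures(x, spacing, cmid)
  # sorted block means: orientation-invariant summary of how the bright mass
  # is spread over the frame (a tail direction must not change the features)
  fb <- sort(as.numeric(blockMean3D(x, grid)), decreasing = TRUE)
  c(glob, core, mid, fg, coreC, midC, sh, fb)
}

# Directional shell profile around the frame centre: voxels are binned by
# radial shell and by direction (26 cone bins); per shell the sorted top bin
# means plus cross-shell sustained-direction minima. A flagellum attached to
# the centre blob gives one direction with high intensity in EVERY shell; a
# nucleus is isotropic and fades with radius; noise neighbours light up a
# single shell only.
shellFeatures <- function(x, spacing, cmid, edges = c(1.2, 2.2, 3.2, 4.2)) {
  d <- dim(x)
  co <- arrayInd(seq_along(x), d)
  off <- sweep(co, 2, cmid)
  off <- sweep(off, 2, spacing, "*")
  r <- sqrt(rowSums(off^2))
  dirs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, ]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  nS <- length(edges) - 1L
  m <- matrix(0, nS, nrow(dirs))
  inAny <- r >= edges[1] & r < edges[nS + 1L]
  if (any(inAny)) {
    u <- off[inAny, , drop = FALSE] / r[inAny]
    binDir <- max.col(u %*% t(dirs))
    binShell <- findInterval(r[inAny], edges)
    key <- factor((binShell - 1L) * nrow(dirs) + binDir,
                  levels = seq_len(nS * nrow(dirs)))
    mv <- tapply(as.numeric(x)[inAny], key, mean)
    mv[is.na(mv)] <- 0
    m <- matrix(mv, nS, nrow(dirs), byrow = TRUE)
  }
  tops <- as.numeric(apply(m, 1, function(row) sort(row, decreasing = TRUE)[1:4]))
  sus12 <- max(pmin(m[1, ], m[2, ]))
  sus23 <- max(pmin(m[2, ], m[3, ]))
  sus123 <- max(pmin(pmin(m[1, ], m[2, ]), m[3, ]))
  c(tops, sus12, sus23, sus123)
}

featureMatrix <- function(frames, grid) {
  t(vapply(frames@crops, frameFeatures, grid = grid, spacing = frames@spacing,
           FUN.VALUE = numeric(prod(grid) + 61L)))
}

#' Label frames against simulation ground truth
#'
#' A frame is labelled "sperm" when it contains a sperm head well inside the
#' frame (at least \code{headMarginUm} from every face) together with at
#' least \code{minTailUm} of that cell's tail centerline — i.e. a localizable
#' head-plus-tail view. Otherwise it is "nucleus" when it holds at least
#' \code{minFrac} of a somatic nucleus's attributed voxels, else "noise"
#' (pure noise, partial/edge views and essentially empty frames). When the
#' environment carries no centerlines (e.g. read back from disk) the sperm
#' rule falls back to the voxel-fraction rule used for nuclei.
#'
#' @param frames an \linkS4class{AnalyticalFrameSet} extracted from \code{env}.
#' @param env the source \linkS4class{SimulatedEnvironment}.
#' @param minFrac minimum fraction of an object's voxels inside the frame.
#' @param headMarginUm minimum head distance from the frame faces, um.
#' @param minTailUm minimum tail centerline length inside the frame, um.
#' @return character vector of labels, one per frame.
#' @export
labelFrames <- function(frames, env, minFrac = 0.25, headMarginUm = 1,
                        minTailUm = 1.5) {
  obj <- gtObjects(envTruth(env))
  lab <- env@labels
  nObj <- max(0L, max(lab))
  if (nObj == 0L) return(rep("noise", nFrames(frames)))
  totals <- tabulate(lab[lab > 0L], nbins = nObj)
  cls <- rep(NA_character_, nObj)
  cls[obj$object_id] <- obj$class
  fs <- frames@frameShape
  spc <- frames@spacing
  sperm <- obj[obj$class == "sperm", , drop = FALSE]
  heads <- lapply(seq_len(nrow(sperm)), function(j)
    as.numeric(jsonlite::fromJSON(sperm$params_json[j])$head))
  cl <- env@centerlines
  haveCl <- length(cl) > 0L
  ds <- 0.1  # centerline sampling step used by the renderer, um
  vapply(seq_len(nFrames(frames)), function(i) {
    o <- frames@origins[i, ]
    isSperm <- FALSE
    if (haveCl && nrow(sperm)) {
      loUm <- o * spc + headMarginUm
      hiUm <- (o + fs - 1) * spc - headMarginUm
      for (j in seq_len(nrow(sperm))) {
        h <- heads[[j]] * spc
        if (all(h >= loUm & h <= hiUm)) {
          pv <- cl[[as.character(sperm$object_id[j])]]
          if (!is.null(pv)) {
            inside <- pv[, 1] >= o[1] & pv[, 1] <= o[1] + fs[1] - 1 &
                      pv[, 2] >= o[2] & pv[, 2] <= o[2] + fs[2] - 1 &
                      pv[, 3] >= o[3] & pv[, 3] <= o[3] + fs[3] - 1
            if (sum(inside) * ds >= minTailUm) { isSperm <- TRUE; break }
          }
        }
      }
    }
    sub <- lab[o[1] + seq_len(fs[1]), o[2] + seq_len(fs[2]),
               o[3] + seq_len(fs[3])]
    tab <- tabulate(sub[sub > 0L], nbins = nObj)
    frac <- ifelse(totals > 0, tab / totals, 0)
    if (!haveCl && any(frac >= minFrac & cls == "sperm", na.rm = TRUE))
      isSperm <- TRUE
    if (isSperm) "sperm"
    else if (any(frac >= minFrac & cls == "nucleus", na.rm = TRUE)) "nucleus"
    else "noise"
  }, character(1))
}

# Box local-maximum filter: running max over a (2*half+1) box per axis.
boxMax3D <- function(a, half) {
  for (ax in 1:3) {
    if (half[ax] < 1L) next
    n <- dim(a)[ax]
    shifted <- a
    for (s in seq_len(half[ax])) {
      idxF <- c((1L + s):n, rep(n, s))      # value from i+s (clamped)
      idxB <- c(rep(1L, s), 1L:(n - s))     # value from i-s (clamped)
      if (ax == 1L) shifted <- pmax(shifted, a[idxF, , , drop = FALSE],
                                    a[idxB, , , drop = FALSE])
      if (ax == 2L) shifted <- pmax(shifted, a[, idxF, , drop = FALSE],
                                    a[, idxB, , drop = FALSE])
      if (ax == 3L) shifted <- pmax(shifted, a[, , idxF, drop = FALSE],
                                    a[, , idxB, drop = FALSE])
    }
    a <- shifted
  }
  a
}

#' Propose candidate object locations as bright local maxima
#'
#' Candidates are voxels above the Otsu threshold of the volume that are
#' maximal within a box neighborhood of the given physical radius — bright
#' blob centres (sperm heads, somatic nuclei, noise blobs). The classifier
#' decides which candidates are sperm.
#'
#' @param volume a \linkS4class{VoxelGrid}.
#' @param neighborhoodUm half-size of the local-maximum box, um.
#' @param threshold intensity floor; default: Otsu over the volume.
#' @return matrix (n x 3) of 0-based (z,y,x) voxel coordinates, ordered by
#'   decreasing peak intensity.
#' @export
findCandidates <- function(volume, neighborhoodUm = 0.8, threshold = NULL) {
  a <- voxelData(volume)
  if (max(a) - min(a) <= 1e-12) return(matrix(numeric(), 0L, 3L))
  if (is.null(threshold)) threshold <- otsuThreshold(a)
  half <- pmax(1L, as.integer(round(neighborhoodUm / voxelSpacing(volume))))
  mx <- boxMax3D(a, half)
  idx <- which(a >= threshold & a >= mx - 1e-12)
  if (length(idx) == 0L) return(matrix(numeric(), 0L, 3L))
  idx <- idx[order(a[idx], decreasing = TRUE)]
  arrayInd(idx, dim(a)) - 1L
}

# Frame of shape fs centred on a 0-based voxel coordinate, clamped to bounds.
centeredOrigin <- function(center, fs, d) {
  pmin(pmax(as.integer(round(center - (fs - 1) / 2)), 0L), d - fs)
}

cropAt <- function(a, origin, fs) {
  a[origin[1] + seq_len(fs[1]), origin[2] + seq_len(fs[2]),
    origin[3] + seq_len(fs[3]), drop = FALSE]
}

# Unclamped centred origin (may be negative near the volume boundary).
centeredOriginPadded <- function(center, fs) {
  as.integer(round(center - (fs - 1) / 2))
}

# Crop with background padding: the frame keeps its centre on the candidate
# even at the volume boundary; voxels outside the volume take `fill`.
cropPadded <- function(a, origin, fs, fill) {
  d <- dim(a)
  out <- array(fill, fs)
  lo <- pmax(origin, 0L); hi <- pmin(origin + fs - 1L, d - 1L)
  if (any(lo > hi)) return(out)
  out[(lo[1] - origin[1] + 1L):(hi[1] - origin[1] + 1L),
      (lo[2] - origin[2] + 1L):(hi[2] - origin[2] + 1L),
      (lo[3] - origin[3] + 1L):(hi[3] - origin[3] + 1L)] <-
    a[(lo[1] + 1L):(hi[1] + 1L), (lo[2] + 1L):(hi[2] + 1L),
      (lo[3] + 1L):(hi[3] + 1L)]
  out
}

#' Train the sperm-signature frame classifier
#'
#' A supervised iteration over synthetic environments with predefined object
#' coordinates: analytical frames are centred on the known object locations
#' (sperm heads, somatic nuclei, noise blobs) with small random positional
#' jitter, complemented by hard negatives — bright local maxima away from any
#' annotated object — and random background frames (both labelled noise).
#' Frames are reduced to intensity-normalized morphology features and fed to
#' a small multilayer perceptron (single hidden layer, softmax over
#' sperm/nucleus/noise). Training is reproducible given the seed and the loss
#' trajectory is recorded.
#'
#' @param environments list of \linkS4class{SimulatedEnvironment}.
#' @param frameShape integer(3) analytical frame shape (z,y,x) voxels.
#' @param hidden hidden-layer size of the MLP.
#' @param decay L2 weight decay.
#' @param maxit maximum optimizer iterations.
#' @param grid integer(3) block-mean feature grid.
#' @param nJitter jittered copies per annotated object.
#' @param jitterUm positional jitter half-range, um.
#' @param maxNoisePerEnv cap on sampled noise-blob examples per environment.
#' @param nRestarts ensemble size: independent random restarts whose softmax
#'   outputs are averaged at prediction time.
#' @param seed integer training seed.
#' @return A \linkS4class{SpermDetector}.
#' @export
trainDetector <- function(environments, frameShape = c(16L, 40L, 40L),
                          hidden = 16L, decay = 1e-3, maxit = 300L,
                          grid = c(3L, 4L, 4L), nJitter = 2L, jitterUm = 0.8,
                          maxNoisePerEnv = 20L, nRestarts = 3L, seed = 1L) {
  frameShape <- as.integer(frameShape)
  set.seed(deriveSeed(seed, 10L))
  crops <- list(); y <- character()
  spacing <- voxelSpacing(envVolume(environments[[1]]))
  for (env in environments) {
    a <- voxelData(envVolume(env))
    d <- dim(a)
    bg <- median(a)
    obj <- gtObjects(envTruth(env))
    addExample <- function(centerVox, label) {
      o <- centeredOriginPadded(centerVox, frameShape)
      crops[[length(crops) + 1L]] <<- cropPadded(a, o, frameShape, bg)
      y <<- c(y, label)
    }
    jittered <- function(centerVox) {
      lapply(c(0L, seq_len(nJitter)), function(k) {
        if (k == 0L) centerVox
        else centerVox + runif(3, -jitterUm, jitterUm) / spacing
      })
    }
    refPhys <- NULL  # head positions for sperm, centroids otherwise:
    if (nrow(obj)) {  # the anchor a centred frame of that object would use
      refs <- list()
      for (j in seq_len(nrow(obj))) {
        cls <- obj$class[j]
        centerVox <- if (cls == "sperm")
          as.numeric(jsonlite::fromJSON(obj$params_json[j])$head)
        else c(obj$cz[j], obj$cy[j], obj$cx[j])
        refs[[j]] <- centerVox * spacing
        if (cls == "noise" &&
            sum(y == "noise") > maxNoisePerEnv * length(environments)) next
        for (cv in jittered(centerVox)) addExample(cv, cls)
      }
      refPhys <- do.call(rbind, refs)
    }
    # hard negatives: candidate peaks away from every annotated anchor
    # (includes mid-tail ridge peaks, teaching the model that only
    # head-centred views count as sperm)
    cand <- findCandidates(envVolume(env))
    if (nrow(cand)) {
      candPhys <- sweep(cand, 2, spacing, "*")
      nHard <- 0L
      for (ci in seq_len(nrow(cand))) {
        if (nHard >= 10L) break
        if (!is.null(refPhys)) {
          dd <- sqrt(rowSums(sweep(refPhys, 2, candPhys[ci, ])^2))
          if (min(dd) < 2.5) next
        }
        addExample(cand[ci, ], "noise"); nHard <- nHard + 1L
      }
    }
    # random background frames
    for (k in 1:6) addExample(runif(3) * (d - 1), "noise")
  }
  fr <- new("AnalyticalFrameSet", crops = crops,
            origins = matrix(0L, length(crops), 3L), frameShape = frameShape,
            spacing = spacing,
            scores = matrix(NA_real_, length(crops), 3),
            predictedClass = rep(NA_character_, length(crops)),
            coords = matrix(NA_real_, length(crops), 3))
  X <- featureMatrix(fr, grid)
  classes <- c("sperm", "nucleus", "noise")
  missing <- setdiff(classes, unique(y))
  if (length(missing))
    stop("class(es) absent from the training frames: ",
         paste(missing, collapse = ", "))
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd); scl[scl < 1e-8] <- 1
  Xs2 <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  yi <- nnet::class.ind(factor(y, levels = classes))
  # inverse-frequency sample weights keep the rare sperm class from being
  # swamped by the abundant noise/empty frames
  freq <- table(factor(y, levels = classes))
  w <- as.numeric(length(y) / (3 * freq[y]))
  # a small ensemble of random restarts averages away the occasional poor
  # optimum of the single-hidden-layer fit
  fits <- vector("list", nRestarts)
  hist <- NULL
  for (r in seq_len(nRestarts)) {
    set.seed(deriveSeed(seed, 11L + r))
    log <- utils::capture.output(
      fits[[r]] <- nnet::nnet(Xs2, yi, weights = w, size = hidden,
                              decay = decay, maxit = maxit, softmax = TRUE,
                              MaxNWts = 100000L, trace = TRUE))
    vals <- regmatches(log, regexpr("value[ ]+[0-9.eE+-]+", log))
    hist <- rbind(hist, data.frame(
      restart = r, step = seq_along(vals),
      value = as.numeric(sub("value[ ]+", "", vals))))
  }
  model <- list(fits = fits, center = ctr, scale = scl)
  new("SpermDetector", model = model, frameShape = frameShape,
      featureGrid = as.integer(grid), classes = classes, history = hist,
      seed = as.numeric(seed),
      hash = configHash(list(frameShape = frameShape, hidden = hidden,
                             decay = decay, maxit = maxit, grid = grid,
                             nRestarts = nRestarts, seed = seed)))
}

# Mean softmax score over the ensemble members.
detectorScores <- function(detector, X) {
  Xs <- sweep(sweep(X, 2, detector@model$center, "-"), 2,
              detector@model$scale, "/")
  acc <- 0
  for (f in detector@model$fits) acc <- acc + predict(f, Xs, type = "raw")
  sc <- acc / length(detector@model$fits)
  colnames(sc) <- detector@classes
  sc
}

#' Score frames with a trained detector
#'
#' Fills per-class scores and the predicted class (argmax; exact ties broken
#' by the class priority sperm > nucleus > noise, conservative toward recall).
#'
#' @param frames an \linkS4class{AnalyticalFrameSet}.
#' @param detector a \linkS4class{SpermDetector} trained at the same frame shape.
#' @return the frame set with scores and predicted classes filled.
#' @export
classifyFrames <- function(frames, detector) {
  if (!identical(frames@frameShape, detector@frameShape))
    stop("detector was trained at frame shape ",
         paste(detector@frameShape, collapse = "x"))
  X <- featureMatrix(frames, detector@featureGrid)
  sc <- detectorScores(detector, X)
  pred <- apply(sc, 1, function(r) {
    best <- which(r >= max(r) - 1e-12)
    detector@classes[min(best)]
  })
  frames@scores <- sc
  frames@predictedClass <- as.character(pred)
  frames
}

# Representative object coordinate of one crop: intensity-weighted centroid
# of the Otsu component containing (or nearest) the frame centre, restricted
# to the component's voxels within `localUm` of the centre — frames are
# candidate-centred, and without the restriction two touching cells would
# collapse onto one shared component centroid. 0-based volume voxel coords.
repCoordinate <- function(crop, origin, spacing, localUm = 2.5) {
  th <- otsuThreshold(crop)
  mask <- crop >= th
  if (!any(mask)) return(origin + (dim(crop) - 1) / 2)
  comps <- connComp3D(mask)
  d <- dim(crop)
  cen <- round((d + 1) / 2)
  keep <- comps[cen[1], cen[2], cen[3]]
  if (keep == 0L) {
    idx <- which(comps > 0L)
    co <- arrayInd(idx, d)
    dd <- rowSums(sweep(co, 2, cen)^2)
    keep <- comps[idx[which.min(dd)]]
  }
  sel <- crop
  sel[comps != keep] <- 0
  co <- arrayInd(seq_along(sel), d)
  rr <- sqrt(((co[, 1] - cen[1]) * spacing[1])^2 +
             ((co[, 2] - cen[2]) * spacing[2])^2 +
             ((co[, 3] - cen[3]) * spacing[3])^2)
  sel[array(rr, d) > localUm] <- 0
  weightedCentroid(sel) + origin
}

#' Detect sperm signatures in a volume
#'
#' Proposes candidate locations as bright local maxima
#' (\code{\link{findCandidates}}), scores an analytical frame centred on each
#' candidate, keeps frames whose sperm score reaches the threshold, attaches
#' a representative coordinate to each (intensity-weighted centroid of the
#' dominant thresholded component of the frame), and applies greedy
#' non-maximum suppression: a frame whose coordinate falls within
#' \code{nmsRadius} of a higher-scoring retained frame is dropped.
#'
#' @param volume a \linkS4class{VoxelGrid}.
#' @param detector a trained \linkS4class{SpermDetector}.
#' @param scoreThreshold sperm-score threshold in [0,1] (Inf gives no frames).
#' @param nmsRadius suppression radius, um.
#' @param neighborhoodUm candidate local-maximum neighborhood, um.
#' @return An \linkS4class{AnalyticalFrameSet} of sperm-positive frames with
#'   coordinates filled (possibly empty).
#' @export
detectSperm <- function(volume, detector, scoreThreshold = 0.5,
                        nmsRadius = 1.2, neighborhoodUm = 0.8) {
  a <- voxelData(volume)
  d <- dim(a)
  fs <- detector@frameShape
  cand <- findCandidates(volume, neighborhoodUm)
  empty <- new("AnalyticalFrameSet", crops = list(),
               origins = matrix(0L, 0L, 3L), frameShape = fs,
               spacing = voxelSpacing(volume),
               scores = matrix(NA_real_, 0L, 3L,
                               dimnames = list(NULL, detector@classes)),
               predictedClass = character(),
               coords = matrix(NA_real_, 0L, 3L))
  if (nrow(cand) == 0L || !is.finite(scoreThreshold) && scoreThreshold > 0)
    return(empty)
  bg <- median(a)
  origins <- t(vapply(seq_len(nrow(cand)), function(i)
    centeredOriginPadded(cand[i, ], fs), integer(3)))
  fr <- new("AnalyticalFrameSet",
            crops = lapply(seq_len(nrow(origins)), function(i)
              cropPadded(a, origins[i, ], fs, bg)),
            origins = origins, frameShape = fs,
            spacing = voxelSpacing(volume),
            scores = matrix(NA_real_, nrow(origins), 3L),
            predictedClass = rep(NA_character_, nrow(origins)),
            coords = matrix(NA_real_, nrow(origins), 3L))
  fr <- classifyFrames(fr, detector)
  keep <- which(fr@scores[, "sperm"] >= scoreThreshold)
  fr <- subsetFrames(fr, keep)
  if (nFrames(fr) == 0L) return(fr)
  coords <- t(vapply(seq_len(nFrames(fr)), function(i)
    repCoordinate(fr@crops[[i]], fr@origins[i, ], fr@spacing), numeric(3)))
  fr@coords <- coords
  phys <- sweep(coords, 2, fr@spacing, "*")
  ord <- order(fr@scores[, "sperm"], decreasing = TRUE)
  kept <- integer()
  for (i in ord) {
    if (length(kept) == 0L ||
        min(sqrt(rowSums(sweep(phys[kept, , drop = FALSE], 2, phys[i, ])^2))) >
          nmsRadius)
      kept <- c(kept, i)
  }
  subsetFrames(fr, sort(kept))
}

subsetFrames <- function(frames, idx) {
  new("AnalyticalFrameSet", crops = frames@crops[idx],
      origins = frames@origins[idx, , drop = FALSE],
      frameShape = frames@frameShape, spacing = frames@spacing,
      scores = frames@scores[idx, , drop = FALSE],
      predictedClass = frames@predictedClass[idx],
      coords = frames@coords[idx, , drop = FALSE])
}

#' Evaluate detections against ground truth
#'
#' Greedy one-to-one matching of detection coordinates to true sperm centroids
#' by increasing physical distance within the matching radius. Sensitivity is
#' TP/(TP+FN). Object-level specificity is the fraction of non-sperm objects
#' (somatic nuclei and noise blobs) not claimed by an unmatched sperm-positive
#' detection within the radius; matched detections do not flag bystanders.
#'
#' @param detections sperm-positive \linkS4class{AnalyticalFrameSet} with
#'   coordinates, or an n x 3 matrix of 0-based (z,y,x) voxel coordinates.
#' @param truth a \linkS4class{GroundTruth}.
#' @param spacing voxel spacing, um (taken from the frame set when omitted).
#' @param matchingRadius matching radius, um, > 0.
#' @return A \linkS4class{DetectionReport}.
#' @export
evaluateDetections <- function(detections, truth, spacing = NULL,
                               matchingRadius = 5) {
  if (matchingRadius <= 0) stop("matchingRadius must be > 0")
  if (is(detections, "AnalyticalFrameSet")) {
    coords <- detections@coords
    if (is.null(spacing)) spacing <- detections@spacing
  } else coords <- as.matrix(detections)
  if (is.null(spacing)) stop("spacing required when detections is a matrix")
  obj <- gtObjects(truth)
  sperm <- obj[obj$class == "sperm", , drop = FALSE]
  other <- obj[obj$class != "sperm", , drop = FALSE]
  nDet <- nrow(coords); nSperm <- nrow(sperm)
  detPhys <- sweep(coords, 2, spacing, "*")
  spPhys <- cbind(sperm$cz * spacing[1], sperm$cy * spacing[2],
                  sperm$cx * spacing[3])
  matchedDet <- integer(); matchedObj <- integer(); dists <- numeric()
  if (nDet > 0 && nSperm > 0) {
    D <- outer(seq_len(nDet), seq_len(nSperm), Vectorize(function(i, j)
      sqrt(sum((detPhys[i, ] - spPhys[j, ])^2))))
    while (TRUE) {
      m <- which.min(D)
      if (length(m) == 0L || !is.finite(D[m]) || D[m] > matchingRadius) break
      ij <- arrayInd(m, dim(D))
      matchedDet <- c(matchedDet, ij[1]); matchedObj <- c(matchedObj, ij[2])
      dists <- c(dists, D[m])
      D[ij[1], ] <- Inf; D[, ij[2]] <- Inf
      if (all(!is.finite(D))) break
    }
  }
  tp <- length(matchedDet)
  fn <- nSperm - tp
  fp <- nDet - tp
  sens <- if (nSperm > 0) tp / nSperm else NA_real_
  spec <- NA_real_
  if (nrow(other) > 0) {
    unm <- setdiff(seq_len(nDet), matchedDet)
    flagged <- 0L
    if (length(unm)) {
      otPhys <- cbind(other$cz * spacing[1], other$cy * spacing[2],
                      other$cx * spacing[3])
      for (j in seq_len(nrow(otPhys))) {
        dd <- sqrt(rowSums(sweep(detPhys[unm, , drop = FALSE], 2,
                                 otPhys[j, ])^2))
        if (any(dd <= matchingRadius)) flagged <- flagged + 1L
      }
    }
    spec <- 1 - flagged / nrow(other)
  }
  matches <- data.frame(
    detection = matchedDet,
    object_id = if (tp) sperm$object_id[matchedObj] else integer(),
    distance_um = dists)
  new("DetectionReport", tp = as.integer(tp), fn = as.integer(fn),
      fp = as.integer(fp), sensitivity = sens, specificity = spec,
      matchingRadius = matchingRadius, noiseRate = NA_real_,
      matches = matches)
}

#' Remove detected nuclei and noise from an analytical frame
#'
#' The reverse of environment production: bright connected components of the
#' frame are isolated, each is re-classified by the detector in a
#' single-component frame, and components called nucleus or noise are replaced
#' by the local background estimate. Sperm-attributed signal is left
#' untouched.
#'
#' @param crop 3D array, one sperm-positive frame crop.
#' @param detector the trained \linkS4class{SpermDetector}.
#' @param spacing voxel spacing, um.
#' @param minVoxels components smaller than this are treated as noise.
#' @return the scrubbed crop (same shape).
#' @export
scrubFrame <- function(crop, detector, spacing = c(0.5, 0.2, 0.2),
                       minVoxels = 10L) {
  th <- otsuThreshold(crop)
  mask <- crop >= th
  if (!any(mask)) return(crop)
  bg <- median(crop[!mask])
  if (!is.finite(bg)) bg <- 0
  comps <- connComp3D(mask)
  out <- crop
  for (k in seq_len(max(comps))) {
    sel <- comps == k
    if (sum(sel) < minVoxels) { out[sel] <- bg; next }
    solo <- array(bg, dim(crop))
    solo[sel] <- crop[sel]
    f <- frameFeatures(solo, detector@featureGrid, spacing)
    sc <- detectorScores(detector, matrix(f, 1))
    if (detector@classes[which.max(sc)] != "sperm") out[sel] <- bg
  }
  out
}

#' Detector sensitivity as a function of training-environment noise rate
#'
#' Renders fresh environments at each noise abundance, runs the detector, and
#' tabulates the mean and SD of the per-environment sensitivity together with
#' the mean measured noise voxel occupancy.
#'
#' @param detector a trained \linkS4class{SpermDetector}.
#' @param noiseAbundances numeric vector of noise-blob abundances (per um^3).
#' @param nEnvsPerRate environments per abundance (>= 2).
#' @param baseSpecs list of non-noise \linkS4class{SignatureSpec} (sperm and
#'   nucleus) defining the environments.
#' @param shape,spacing,blurSigma,background forwarded to
#'   \code{\link{renderEnvironment}}.
#' @param scoreThreshold,matchingRadius detection/evaluation parameters.
#' @param seed integer seed.
#' @return data.frame(noise_abundance, noise_rate, mean_sensitivity,
#'   sd_sensitivity, n_envs, flagged).
#' @export
sensitivityVsNoise <- function(detector, noiseAbundances, nEnvsPerRate,
                               baseSpecs, shape, spacing = c(0.5, 0.2, 0.2),
                               blurSigma = 0.15,
                               background = list(offset = 0.02, sd = 0.01),
                               scoreThreshold = 0.5, matchingRadius = 5,
                               seed = 1L) {
  if (nEnvsPerRate < 2) stop("nEnvsPerRate must be >= 2")
  rows <- lapply(seq_along(noiseAbundances), function(ri) {
    sens <- numeric(); rates <- numeric()
    for (k in seq_len(nEnvsPerRate)) {
      env <- renderEnvironment(
        c(baseSpecs, list(noiseSpec(noiseAbundances[ri]))), shape, spacing,
        blurSigma, background, seed = deriveSeed(seed, ri * 1000L + k))
      det <- detectSperm(envVolume(env), detector,
                         scoreThreshold = scoreThreshold)
      rep <- evaluateDetections(det, envTruth(env), spacing, matchingRadius)
      sens <- c(sens, sensitivity(rep))
      rates <- c(rates, noiseRate(envTruth(env)))
    }
    flagged <- all(is.na(sens))
    data.frame(noise_abundance = noiseAbundances[ri],
               noise_rate = mean(rates),
               mean_sensitivity = mean(sens, na.rm = !flagged),
               sd_sensitivity = if (flagged) NA_real_ else sd(sens, na.rm = TRUE),
               n_envs = nEnvsPerRate, flagged = flagged)
  })
  do.call(rbind, rows)
}
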