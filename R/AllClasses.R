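#' VoxelGrid: a 3D fluorescence intensity volume
#'
#' Container for a single-channel 3D intensity grid with physical voxel
#' spacing. Axis order is fixed as (z, y, x) with 0-based voxel coordinates in
#' every exported table; intensities are arbitrary fluorescence units.
#'
#' @slot data 3D numeric array, non-negative finite intensities, dim (z, y, x).
#' @slot spacing numeric(3), physical voxel size per axis in micrometres.
#' @slot channel single character label (e.g. "composite", "nuclei", "catsper").
#' @export
setClass("VoxelGrid", representation(
  data = "array", spacing = "numeric", channel = "character"
))

setValidity("VoxelGrid", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L) msg <- c(msg, "data must be a 3D array")
  if (any(!is.finite(object@data)) || any(object@data < 0))
    msg <- c(msg, "intensities must be finite and >= 0")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive values (z,y,x)")
  if (length(object@channel) != 1L) msg <- c(msg, "channel must be length 1")
  if (length(msg)) msg else TRUE
})

#' Construct a VoxelGrid
#'
#' @param data 3D numeric array (z, y, x).
#' @param spacing physical voxel size per axis, micrometres, order (z, y, x).
#' @param channel channel label.
#' @return A \linkS4class{VoxelGrid}.
#' @examples
#' vg <- VoxelGrid(array(0, c(4, 8, 8)), spacing = c(0.5, 0.2, 0.2))
#' dim(voxelData(vg))
#' @export
VoxelGrid <- function(data, spacing = c(0.5, 0.2, 0.2), channel = "composite") {
  new("VoxelGrid", data = data, spacing = as.numeric(spacing), channel = channel)
}

#' @describeIn VoxelGrid the intensity array (z, y, x)
#' @param x,object a VoxelGrid
#' @export
voxelData <- function(x) x@data

#' @describeIn VoxelGrid voxel spacing in micrometres (z, y, x)
#' @export
voxelSpacing <- function(x) x@spacing

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelGrid '%s': %d x %d x %d voxels (z,y,x), spacing %s um\n",
              object@channel, d[1], d[2], d[3],
              paste(signif(object@spacing, 3), collapse = " x ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

#' GroundTruth: per-object labels and coordinates for a simulated volume
#'
#' One row per rendered object. Coordinates are 0-based voxel indices (z,y,x)
#' of the intensity-weighted object centroid; `orientation_deg` is the roll of
#' the nanodomain frame for sperm (0 otherwise); `clipped` flags objects whose
#' rendered signal intersects the volume boundary.
#'
#' @slot objects data.frame with columns object_id, class, cz, cy, cx,
#'   orientation_deg, clipped, params_json.
#' @slot noiseRate fraction of voxels occupied by (unblurred) noise objects.
#' @export
setClass("GroundTruth", representation(
  objects = "data.frame", noiseRate = "numeric"
))

setValidity("GroundTruth", function(object) {
  need <- c("object_id", "class", "cz", "cy", "cx", "orientation_deg",
            "clipped", "params_json")
  msg <- character()
  if (!all(need %in% names(object@objects)))
    msg <- c(msg, paste("objects must have columns:", paste(need, collapse = ", ")))
  if (length(object@noiseRate) != 1L || object@noiseRate < 0 || object@noiseRate > 1)
    msg <- c(msg, "noiseRate must be a single value in [0,1]")
  if (nrow(object@objects) &&
      !all(object@objects$class %in% c("sperm", "nucleus", "noise")))
    msg <- c(msg, "class must be sperm/nucleus/noise")
  if (length(msg)) msg else TRUE
})

#' @describeIn GroundTruth the object table
#' @param x a GroundTruth
#' @export
gtObjects <- function(x) x@objects

#' @describeIn GroundTruth fraction of voxels occupied by noise objects
#' @export
noiseRate <- function(x) x@noiseRate

setMethod("show", "GroundTruth", function(object) {
  tab <- table(factor(object@objects$class,
                      levels = c("sperm", "nucleus", "noise")))
  cat(sprintf("GroundTruth: %d objects (%s), noise voxel occupancy %.4f\n",
              nrow(object@objects),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              object@noiseRate))
})

#' SimulatedEnvironment: a rendered training/evaluation volume with truth
#'
#' @slot volume composite \linkS4class{VoxelGrid} the detector sees
#'   (all signatures, blurred, plus background).
#' @slot channels named list of VoxelGrid: "nuclei" (somatic nuclei + sperm
#'   heads, blurred), "catsper" (tails only, blurred), "noise" (unblurred noise
#'   signal, used for exact occupancy), and unblurred per-class attribution
#'   channels "class_sperm", "class_nucleus", "class_noise".
#' @slot labels integer array, per-voxel ground-truth object id (0 = none;
#'   first-writer-wins on the rare overlaps).
#' @slot truth \linkS4class{GroundTruth}.
#' @slot centerlines named list (by sperm object id) of n x 3 matrices of
#'   0-based (z,y,x) voxel coordinates of the tail centerline samples.
#' @slot seed the seed the environment was rendered from.
#' @export
setClass("SimulatedEnvironment", representation(
  volume = "VoxelGrid", channels = "list", labels = "array",
  truth = "GroundTruth", centerlines = "list", seed = "numeric"
))

setMethod("show", "SimulatedEnvironment", function(object) {
  cat("SimulatedEnvironment (seed ", object@seed, ")\n", sep = "")
  show(object@volume)
  show(object@truth)
})

#' @describeIn SimulatedEnvironment the composite volume
#' @param x a SimulatedEnvironment
#' @export
envVolume <- function(x) x@volume

#' @describeIn SimulatedEnvironment the ground truth
#' @export
envTruth <- function(x) x@truth

#' @describeIn SimulatedEnvironment named auxiliary channel list
#' @export
envChannels <- function(x) x@channels

#' AnalyticalFrameSet: fixed-size sub-volume crops proposed over a volume
#'
#' @slot crops list of 3D arrays, all of identical shape.
#' @slot origins integer matrix (n x 3), 0-based (z,y,x) frame corners.
#' @slot frameShape integer(3) voxel shape of every crop.
#' @slot spacing numeric(3) voxel spacing inherited from the source volume.
#' @slot scores numeric matrix (n x 3), per-class scores (sperm, nucleus,
#'   noise); NA until classified.
#' @slot predictedClass character(n); NA until classified.
#' @slot coords numeric matrix (n x 3), representative object coordinate per
#'   frame in 0-based voxel units; NA until detection.
#' @export
setClass("AnalyticalFrameSet", representation(
  crops = "list", origins = "matrix", frameShape = "integer",
  spacing = "numeric", scores = "matrix", predictedClass = "character",
  coords = "matrix"
))

setValidity("AnalyticalFrameSet", function(object) {
  msg <- character()
  if (length(object@crops) != nrow(object@origins))
    msg <- c(msg, "one origin per crop required")
  if (length(object@crops) &&
      !all(vapply(object@crops, function(cr) identical(dim(cr), dim(object@crops[[1]])),
                  logical(1))))
    msg <- c(msg, "all crops must share one frame shape")
  sc <- object@scores[is.finite(object@scores)]
  if (length(sc) && (any(sc < -1e9))) msg <- c(msg, "scores must be finite")
  if (length(msg)) msg else TRUE
})

#' @describeIn AnalyticalFrameSet number of frames
#' @param x an AnalyticalFrameSet
#' @export
nFrames <- function(x) length(x@crops)

#' @describeIn AnalyticalFrameSet 0-based frame origins (n x 3)
#' @export
frameOrigins <- function(x) x@origins

#' @describeIn AnalyticalFrameSet per-class score matrix
#' @export
frameScores <- function(x) x@scores

#' @describeIn AnalyticalFrameSet representative coordinates (n x 3, 0-based voxels)
#' @export
frameCoords <- function(x) x@coords

setMethod("show", "AnalyticalFrameSet", function(object) {
  cat(sprintf("AnalyticalFrameSet: %d frames of %s voxels\n",
              length(object@crops), paste(object@frameShape, collapse = "x")))
  if (any(!is.na(object@predictedClass))) {
    tab <- table(object@predictedClass)
    cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

#' SpermDetector: a trained frame classifier
#'
#' @slot model fitted nnet multinomial classifier.
#' @slot frameShape integer(3) frame shape the model was trained at.
#' @slot featureGrid integer(3) block-mean downsampling grid of the features.
#' @slot classes character(3) class order of the score columns.
#' @slot history data.frame of training loss per reported iteration.
#' @slot seed training seed.
#' @slot hash configuration hash.
#' @export
setClass("SpermDetector", representation(
  model = "ANY", frameShape = "integer", featureGrid = "integer",
  classes = "character", history = "data.frame", seed = "numeric",
  hash = "character"
))

setMethod("show", "SpermDetector", function(object) {
  nw <- if (length(object@model$fits)) length(object@model$fits[[1]]$wts) else 0L
  cat(sprintf(
    "SpermDetector: MLP ensemble (%d restarts) on %s frames, grid %s, %d weights each\n",
    length(object@model$fits), paste(object@frameShape, collapse = "x"),
    paste(object@featureGrid, collapse = "x"), nw))
  if (nrow(object@history))
    cat(sprintf("  final training loss %.5g after %d reported steps\n",
                object@history$value[nrow(object@history)], nrow(object@history)))
})

#' @describeIn SpermDetector training loss history
#' @param x a SpermDetector
#' @export
trainingHistory <- function(x) x@history

#' DetectionReport: coordinate-matched detector evaluation
#'
#' Sensitivity = TP/(TP+FN) over true sperm; object-level specificity = the
#' fraction of non-sperm ground-truth objects not claimed by an unmatched
#' sperm-positive detection within the matching radius.
#'
#' @slot tp,fn,fp integer counts.
#' @slot sensitivity,specificity fractions in [0,1] (NA when undefined).
#' @slot matchingRadius micrometres.
#' @slot noiseRate noise occupancy of the evaluated environment.
#' @slot matches data.frame pairing detection and object ids with distances.
#' @export
setClass("DetectionReport", representation(
  tp = "integer", fn = "integer", fp = "integer",
  sensitivity = "numeric", specificity = "numeric",
  matchingRadius = "numeric", noiseRate = "numeric", matches = "data.frame"
))

setValidity("DetectionReport", function(object) {
  msg <- character()
  for (nm in c("sensitivity", "specificity")) {
    v <- slot(object, nm)
    if (length(v) == 1L && is.finite(v) && (v < 0 || v > 1))
      msg <- c(msg, paste(nm, "must lie in [0,1]"))
  }
  if (object@tp < 0 || object@fn < 0 || object@fp < 0)
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @describeIn DetectionReport TP/(TP+FN)
#' @param x a DetectionReport
#' @export
sensitivity <- function(x) x@sensitivity

#' @describeIn DetectionReport object-level specificity
#' @export
specificity <- function(x) x@specificity

setMethod("show", "DetectionReport", function(object) {
  cat(sprintf(
    "DetectionReport: TP=%d FN=%d FP=%d | sensitivity %.3f, specificity %.3f (radius %.1f um)\n",
    object@tp, object@fn, object@fp, object@sensitivity, object@specificity,
    object@matchingRadius))
})

#' SpermTrace: a linearized, nucleus-normalizable tail intensity profile
#'
#' @slot arclength strictly increasing positions along the tail (um), 0 at the
#'   proximal (head-adjacent) end of the CatSper-positive principal piece.
#' @slot intensity intensity per position (raw or nucleus-normalized).
#' @slot nucleusReference nucleus intensity used for normalization (NA if
#'   unpaired / not yet normalized).
#' @slot path n x 3 matrix of 0-based (z,y,x) voxel coordinates of the sampled
#'   centerline (same length as arclength).
#' @slot frameId source frame identifier.
#' @slot flags character vector ("unpaired", "ambiguous_head", "normalized", ...).
#' @export
setClass("SpermTrace", representation(
  arclength = "numeric", intensity = "numeric", nucleusReference = "numeric",
  path = "matrix", frameId = "character", flags = "character"
))

setValidity("SpermTrace", function(object) {
  msg <- character()
  if (length(object@arclength) != length(object@intensity))
    msg <- c(msg, "arclength and intensity lengths differ")
  if (length(object@arclength) > 1L && any(diff(object@arclength) <= 0))
    msg <- c(msg, "arclength must be strictly increasing")
  if (any(object@intensity < 0)) msg <- c(msg, "intensities must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn SpermTrace arclength grid (um)
#' @param x a SpermTrace
#' @export
traceArclength <- function(x) x@arclength

#' @describeIn SpermTrace intensity profile
#' @export
traceIntensity <- function(x) x@intensity

#' @describeIn SpermTrace flags attached to the trace
#' @export
traceFlags <- function(x) x@flags

setMethod("show", "SpermTrace", function(object) {
  cat(sprintf("SpermTrace '%s': %d samples over %.2f um%s\n",
              object@frameId, length(object@arclength),
              max(object@arclength),
              if (length(object@flags)) paste0(" [", paste(object@flags, collapse = ","), "]")
              else ""))
})

#' CrossSection: a transversal-projection patch through the tail axis
#'
#' The image is a square, odd-sided patch in the plane orthogonal to the local
#' centerline tangent; rows index the v axis from +v (top) down, columns the u
#' axis from -u to +u, so the top-right image quadrant is (u>0, v>0).
#'
#' @slot image 2D numeric matrix, odd square.
#' @slot pixelSpacing micrometres per pixel.
#' @slot cellId source cell identifier.
#' @slot span projection span along the tail (um).
#' @slot rotation alignment rotation applied, degrees counterclockwise.
#' @slot flags character vector (e.g. "curved").
#' @export
setClass("CrossSection", representation(
  image = "matrix", pixelSpacing = "numeric", cellId = "character",
  span = "numeric", rotation = "numeric", flags = "character"
))

setValidity("CrossSection", function(object) {
  d <- dim(object@image)
  msg <- character()
  if (d[1] != d[2] || d[1] %% 2L == 0L)
    msg <- c(msg, "image must be square with odd side")
  if (length(msg)) msg else TRUE
})

#' @describeIn CrossSection the 2D patch
#' @param x a CrossSection
#' @export
sectionImage <- function(x) x@image

setMethod("show", "CrossSection", function(object) {
  cat(sprintf("CrossSection '%s': %dx%d px at %.3f um/px, rotation %g deg\n",
              object@cellId, nrow(object@image), ncol(object@image),
              object@pixelSpacing, object@rotation))
})

#' QuadProfile: 80-area angular intensity profile and its delta statistic
#'
#' @slot areas 80 mean intensities of circular sampling areas on the membrane
#'   ring, ordered counterclockwise from the +u axis (4.5 degrees apart).
#' @slot peakIdx,valleyIdx integer(4) area indices (1-based) of peaks/valleys.
#' @slot peaks,valleys numeric(4) unsmoothed area values at those indices.
#' @slot delta mean(peaks) - mean(valleys).
#' @slot deltaPairwise mean of the per-pair peak-minus-adjacent-valley
#'   differences (secondary variant).
#' @slot rotation alignment rotation inherited from the section (degrees).
#' @slot flag "" or "non_quadrilateral" when fewer than 4 smoothed maxima exist.
#' @export
setClass("QuadProfile", representation(
  areas = "numeric", peakIdx = "integer", valleyIdx = "integer",
  peaks = "numeric", valleys = "numeric", delta = "numeric",
  deltaPairwise = "numeric", rotation = "numeric", flag = "character"
))

setValidity("QuadProfile", function(object) {
  msg <- character()
  if (length(object@areas) != 80L) msg <- c(msg, "exactly 80 areas required")
  if (length(object@peaks) != 4L || length(object@valleys) != 4L)
    msg <- c(msg, "exactly 4 peaks and 4 valleys required")
  if (length(msg)) msg else TRUE
})

#' @describeIn QuadProfile the delta statistic
#' @param x a QuadProfile
#' @export
deltaValue <- function(x) x@delta

#' @describeIn QuadProfile the 80 area intensities
#' @export
profileAreas <- function(x) x@areas

setMethod("show", "QuadProfile", function(object) {
  cat(sprintf("QuadProfile: delta = %.4f (pairwise %.4f)%s\n",
              object@delta, object@deltaPairwise,
              if (nzchar(object@flag)) paste0(" [", object@flag, "]") else ""))
})
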