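# Shared fixtures. The heavy objects (trained detector, single-cell volumes)
# are built once per session and cached.

.fixtures <- new.env(parent = emptyenv())

# Standard study conditions: ~5 sperm, ~4 somatic nuclei per 30x20x20 um
# volume, noise blobs at the stated abundance (per um^3).
stdSpecs <- function(noiseAbundance = 60 / 12000,
                     spermAbundance = 5 / 12000,
                     nucleusAbundance = 4 / 12000, ...) {
  list(spermSpec(spermAbundance, ...), nucleusSpec(nucleusAbundance),
       noiseSpec(noiseAbundance))
}

stdShape <- c(60L, 100L, 100L)

# The detector used across detection and acceptance tests: trained on 30
# environments spanning four noise abundances.
testDetector <- function() {
  if (is.null(.fixtures$detector)) {
    noise <- c(30, 60, 90, 120) / 12000
    envs <- lapply(1:30, function(i)
      renderEnvironment(stdSpecs(noise[(i - 1) %% 4 + 1]), stdShape,
                        seed = 1000 + i))
    .fixtures$detector <- trainDetector(envs, nJitter = 3L, decay = 3e-3,
                                        seed = 5)
    rm(envs); gc()
  }
  .fixtures$detector
}

# Pooled held-out evaluation used by the sensitivity/specificity criteria:
# 20 fresh environments at the training-comparable noise abundance.
heldOutEvaluation <- function() {
  if (is.null(.fixtures$heldOut)) {
    det <- testDetector()
    tp <- fn <- fp <- 0L; flagged <- 0L; nonSperm <- 0L
    for (i in 1:20) {
      env <- renderEnvironment(stdSpecs(), stdShape, seed = 9000 + i)
      dets <- detectSperm(envVolume(env), det)
      r <- evaluateDetections(dets, envTruth(env))
      tp <- tp + r@tp; fn <- fn + r@fn; fp <- fp + r@fp
      ns <- sum(gtObjects(envTruth(env))$class != "sperm")
      nonSperm <- nonSperm + ns
      flagged <- flagged + as.integer(round((1 - specificity(r)) * ns))
    }
    .fixtures$heldOut <- list(
      sensitivity = tp / (tp + fn),
      specificity = 1 - flagged / nonSperm,
      tp = tp, fn = fn, fp = fp)
  }
  .fixtures$heldOut
}

# Fine-spacing environments holding exactly one (possibly clipped) sperm and
# no other signatures, for trace and cross-section work.
fineSpacing <- c(0.3, 0.1, 0.1)
fineShape <- c(40L, 120L, 120L)

singleCellEnv <- function(seed, tailLength = 6, curvatureSd = 0.01,
                          maxCurvature = 0.05, peak = 0.7, valley = 0.25,
                          blurSigma = 0.12) {
  renderEnvironment(
    list(spermSpec(1 / 2000, tailLength = tailLength, tailLengthSd = 0.01,
                   curvatureSd = curvatureSd, maxCurvature = maxCurvature,
                   peakIntensity = peak, valleyIntensity = valley)),
    fineShape, fineSpacing, blurSigma = blurSigma,
    background = list(offset = 0, sd = 0), seed = seed)
}

# First `n` seeds whose environment holds exactly one sperm whose tail lies
# essentially fully inside the volume (cells cut by the volume face are not
# valid isometry subjects).
singleCellSeeds <- function(n, from = 1, ...) {
  seeds <- integer(); s <- from
  while (length(seeds) < n && s < from + 400) {
    env <- singleCellEnv(s, ...)
    ob <- gtObjects(envTruth(env))
    if (nrow(ob) == 1L) {
      tl <- jsonlite::fromJSON(ob$params_json[1])$tailLength
      if (insideTailLength(env) >= 0.95 * tl) seeds <- c(seeds, s)
    }
    s <- s + 1
  }
  seeds
}

# Oracle: the arclength of the part of the true centerline that lies inside
# the volume (longest run of inside samples x the 0.1 um sampling step).
insideTailLength <- function(env) {
  cl <- env@centerlines[[1]]
  d <- dim(voxelData(envVolume(env)))
  inside <- cl[, 1] >= 0 & cl[, 1] <= d[1] - 1 &
            cl[, 2] >= 0 & cl[, 2] <= d[2] - 1 &
            cl[, 3] >= 0 & cl[, 3] <= d[3] - 1
  r <- rle(inside)
  if (!any(r$values)) return(0)
  (max(r$lengths[r$values]) - 1) * 0.1
}

# A ready single-cell trace/section pair used by several tests.
singleCellTrace <- function() {
  if (is.null(.fixtures$cellTrace)) {
    seeds <- singleCellSeeds(1, from = 6)
    env <- singleCellEnv(seeds[1])
    a <- voxelData(envChannels(env)$catsper)
    tr <- linearizeTail(a, fineSpacing, minLength = 4, frameId = "fixture")
    .fixtures$cellTrace <- list(env = env, crop = a, trace = tr)
  }
  .fixtures$cellTrace
}
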