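test_that("frame tiling covers the volume at the promised counts", {
  vg <- VoxelGrid(array(runif(1000), c(10, 10, 10)), c(0.5, 0.2, 0.2))
  fr1 <- extractFrames(vg, c(10L, 10L, 10L), c(3L, 3L, 3L))
  expect_identical(nFrames(fr1), 1L)
  fr8 <- extractFrames(vg, c(5L, 5L, 5L), c(5L, 5L, 5L))
  expect_identical(nFrames(fr8), 8L)
  # brute-force voxel coverage for an awkward stride
  fr <- extractFrames(vg, c(4L, 6L, 5L), c(3L, 4L, 4L))
  covered <- array(FALSE, c(10, 10, 10))
  for (i in seq_len(nFrames(fr))) {
    o <- frameOrigins(fr)[i, ]
    covered[o[1] + 1:4, o[2] + 1:6, o[3] + 1:5] <- TRUE
  }
  expect_true(all(covered))
  expect_error(extractFrames(vg, c(4L, 4L, 4L), c(0L, 1L, 1L)), "stride")
  expect_error(extractFrames(vg, c(12L, 4L, 4L)), "exceeds")
})

test_that("evaluation arithmetic matches its definitions", {
  objects <- data.frame(
    object_id = 1:12, class = c(rep("sperm", 10), "nucleus", "noise"),
    cz = c(seq(5, 50, by = 5), 55, 58), cy = 50, cx = 50,
    orientation_deg = 0, clipped = FALSE, params_json = "{}")
  truth <- new("GroundTruth", objects = objects, noiseRate = 0)
  spacing <- c(0.5, 0.2, 0.2)
  exact <- as.matrix(objects[objects$class == "sperm", c("cz", "cy", "cx")])
  r <- evaluateDetections(exact, truth, spacing, matchingRadius = 1)
  expect_identical(c(r@tp, r@fn, r@fp), c(10L, 0L, 0L))
  expect_identical(sensitivity(r), 1)
  expect_identical(specificity(r), 1)

  none <- matrix(numeric(), 0, 3)
  r0 <- evaluateDetections(none, truth, spacing, matchingRadius = 5)
  expect_identical(c(r0@tp, r0@fn), c(0L, 10L))
  expect_identical(sensitivity(r0), 0)

  nine <- rbind(exact[1:9, ], c(55, 250, 250))  # 9 matches + 1 spurious
  r9 <- evaluateDetections(nine, truth, spacing, matchingRadius = 1)
  expect_identical(c(r9@tp, r9@fn, r9@fp), c(9L, 1L, 1L))
  expect_equal(sensitivity(r9), 0.9)
  expect_error(evaluateDetections(exact, truth, spacing, matchingRadius = 0),
               "matchingRadius")
})

test_that("matching is one-to-one under random detections", {
  spacing <- c(0.5, 0.2, 0.2)
  objects <- data.frame(
    object_id = 1:6, class = "sperm",
    cz = runif(6, 0, 50), cy = runif(6, 0, 200), cx = runif(6, 0, 200),
    orientation_deg = 0, clipped = FALSE, params_json = "{}")
  truth <- new("GroundTruth", objects = objects, noiseRate = 0)
  for (s in 1:20) {
    set.seed(s)
    nDet <- sample(0:9, 1)
    dets <- cbind(runif(nDet, 0, 50), runif(nDet, 0, 200), runif(nDet, 0, 200))
    r <- evaluateDetections(dets, truth, spacing, matchingRadius = 8)
    expect_lte(r@tp, min(nDet, 6L))
    expect_identical(r@tp + r@fn, 6L)
    expect_identical(r@tp + r@fp, nDet)
    expect_true(!anyDuplicated(r@matches$detection) &&
                !anyDuplicated(r@matches$object_id))
  }
})

test_that("training requires every class and is seed-reproducible", {
  noNucleus <- lapply(1:2, function(i)
    renderEnvironment(list(spermSpec(5 / 12000), noiseSpec(40 / 12000)),
                      c(40L, 72L, 72L), seed = 50 + i))
  expect_error(trainDetector(noNucleus, maxit = 5L, seed = 1), "nucleus")

  envs <- lapply(1:3, function(i)
    renderEnvironment(stdSpecs(), c(40L, 72L, 72L), seed = 60 + i))
  d1 <- trainDetector(envs, maxit = 30L, seed = 9)
  d2 <- trainDetector(envs, maxit = 30L, seed = 9)
  expect_identical(d1@model$fits[[1]]$wts, d2@model$fits[[1]]$wts)
  expect_gt(nrow(trainingHistory(d1)), 0)
  # same seed implies identical detection reports on the same volume
  env <- renderEnvironment(stdSpecs(), c(40L, 72L, 72L), seed = 70)
  r1 <- evaluateDetections(detectSperm(envVolume(env), d1), envTruth(env))
  r2 <- evaluateDetections(detectSperm(envVolume(env), d2), envTruth(env))
  expect_identical(r1@tp, r2@tp)
  expect_identical(r1@fp, r2@fp)
})

test_that("detection returns nothing for empty volumes or infinite thresholds", {
  det <- testDetector()
  blank <- VoxelGrid(array(0, stdShape), c(0.5, 0.2, 0.2))
  expect_identical(nFrames(detectSperm(blank, det)), 0L)
  env <- renderEnvironment(stdSpecs(), stdShape, seed = 81)
  expect_identical(nFrames(detectSperm(envVolume(env), det,
                                       scoreThreshold = Inf)), 0L)
})

test_that("noiseless single-sperm volumes are recalled perfectly", {
  det <- testDetector()
  tp <- 0L; n <- 0L
  for (s in 1:8) {
    env <- renderEnvironment(list(spermSpec(3 / 12000)), stdShape,
                             seed = 300 + s)
    nSperm <- nrow(gtObjects(envTruth(env)))
    if (nSperm == 0) next
    r <- evaluateDetections(detectSperm(envVolume(env), det), envTruth(env))
    tp <- tp + r@tp; n <- n + nSperm
  }
  expect_gt(n, 0)
  expect_identical(tp, n)
})

test_that("a trained detector matches a brute-force oracle on clean volumes", {
  det <- testDetector()
  spacing <- c(0.5, 0.2, 0.2)
  tested <- 0L
  for (s in 1:20) {
    if (tested >= 3L) break
    env <- renderEnvironment(
      list(spermSpec(4 / 12000, tailLength = 8)), stdShape,
      blurSigma = 0.15, background = list(offset = 0, sd = 0), seed = 400 + s)
    truth <- envTruth(env)
    ob <- gtObjects(truth)
    # the equivalence regime: whole, non-touching cells on a clean volume
    # (cells cut by the volume face are excluded from the comparison)
    unclipped <- ob$object_id[!ob$clipped]
    if (length(unclipped) < 2) next
    sp <- voxelData(envChannels(env)$class_sperm)
    comps <- CatSperQuant:::connComp3D(sp > 1e-9)
    if (max(comps) != nrow(ob)) next
    # oracle: threshold the sperm-attributed channel (ground-truth template)
    # and report component centroids
    oracleCoords <- t(vapply(seq_len(max(comps)), function(k) {
      sel <- sp; sel[comps != k] <- 0
      CatSperQuant:::weightedCentroid(sel)
    }, numeric(3)))
    rOracle <- evaluateDetections(oracleCoords, truth, spacing)
    rTrained <- evaluateDetections(detectSperm(envVolume(env), det), truth,
                                   spacing)
    expect_identical(sort(intersect(rOracle@matches$object_id, unclipped)),
                     sort(intersect(rTrained@matches$object_id, unclipped)))
    tested <- tested + 1L
  }
  expect_gte(tested, 1L)
})

test_that("sensitivity does not increase with noise abundance", {
  det <- testDetector()
  tab <- sensitivityVsNoise(det, c(0, 120, 240) / 12000, nEnvsPerRate = 5,
                            baseSpecs = stdSpecs()[1:2], shape = stdShape,
                            seed = 77)
  expect_identical(nrow(tab), 3L)
  expect_true(all(diff(tab$noise_rate) > 0))
  # monotone trend within Monte-Carlo error
  expect_gte(tab$mean_sensitivity[1], tab$mean_sensitivity[3] - 0.1)
  expect_false(any(tab$flagged))
  # degenerate: environments without sperm give a flagged row
  tabNoSperm <- sensitivityVsNoise(det, 60 / 12000, nEnvsPerRate = 2,
                                   baseSpecs = list(spermSpec(0)),
                                   shape = c(40L, 72L, 72L), seed = 3)
  expect_true(tabNoSperm$flagged)
  expect_error(sensitivityVsNoise(det, 0.01, 1, stdSpecs()[1:2], stdShape),
               "nEnvsPerRate")
})

test_that("scrubbing removes nuclei and noise but conserves sperm signal", {
  det <- testDetector()
  spacing <- c(0.5, 0.2, 0.2)
  # frame with sperm only: output equals input (sperm components preserved)
  cellSeed <- NULL
  for (s in 1:20) {
    env <- renderEnvironment(list(spermSpec(2 / 12000)), stdShape,
                             blurSigma = 0.15,
                             background = list(offset = 0.02, sd = 0.01),
                             seed = 500 + s)
    if (nrow(gtObjects(envTruth(env))) >= 1) { cellSeed <- s; break }
  }
  dets <- detectSperm(envVolume(env), det)
  expect_gt(nFrames(dets), 0)
  crop <- dets@crops[[1]]
  scr <- scrubFrame(crop, det, spacing)
  th <- CatSperQuant:::otsuThreshold(crop)
  expect_equal(sum(scr[crop >= th]), sum(crop[crop >= th]), tolerance = 0.01)

  # sperm + nucleus: nucleus voxels removed, sperm sum conserved within 1%
  env2 <- NULL
  for (s in 1:40) {
    cand <- renderEnvironment(
      list(spermSpec(2 / 12000), nucleusSpec(2 / 12000)), stdShape,
      blurSigma = 0.15, background = list(offset = 0.02, sd = 0.01),
      seed = 600 + s)
    ob <- gtObjects(envTruth(cand))
    if (sum(ob$class == "sperm") < 1 || sum(ob$class == "nucleus") < 1) next
    sp <- ob[ob$class == "sperm", ][1, ]
    nu <- ob[ob$class == "nucleus", ][1, ]
    dist <- sqrt(sum(((c(sp$cz, sp$cy, sp$cx) - c(nu$cz, nu$cy, nu$cx)) *
                      spacing)^2))
    if (dist > 4 && dist < 9) { env2 <- cand; break }
  }
  expect_false(is.null(env2))
  dets2 <- detectSperm(envVolume(env2), det)
  if (nFrames(dets2) > 0) {
    o <- dets2@origins[1, ]; fs <- dets2@frameShape
    crop2 <- dets2@crops[[1]]
    scr2 <- scrubFrame(crop2, det, spacing)
    spCrop <- CatSperQuant:::cropPadded(
      voxelData(envChannels(env2)$class_sperm), o, fs, 0)
    nuCrop <- CatSperQuant:::cropPadded(
      voxelData(envChannels(env2)$class_nucleus), o, fs, 0)
    th2 <- CatSperQuant:::otsuThreshold(crop2)
    spMask <- spCrop > 1e-9 & crop2 >= th2
    nuMask <- nuCrop > 1e-9 & spCrop <= 1e-9 & crop2 >= th2
    if (sum(nuMask) > 50 && sum(spMask) > 50) {
      expect_lt(sum(scr2[nuMask]), 0.2 * sum(crop2[nuMask]))
      expect_equal(sum(scr2[spMask]), sum(crop2[spMask]), tolerance = 0.01)
    }
  }

  # pure-noise frame: essentially all signal removed
  env3 <- renderEnvironment(list(noiseSpec(300 / 12000)), c(16L, 40L, 40L),
                            blurSigma = 0.15,
                            background = list(offset = 0.02, sd = 0.01),
                            seed = 700)
  crop3 <- voxelData(envVolume(env3))
  scr3 <- scrubFrame(crop3, det, spacing)
  th3 <- CatSperQuant:::otsuThreshold(crop3)
  expect_lt(sum(scr3[crop3 >= th3]), 0.25 * sum(crop3[crop3 >= th3]))
})
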