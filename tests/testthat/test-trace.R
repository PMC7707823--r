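test_that("head pairing returns the rendered reference and handles edge cases", {
  fx <- singleCellTrace()
  env <- fx$env
  nuc <- voxelData(envChannels(env)$nuclei)
  tr <- fx$trace
  ends <- rbind(tr@path[1, ], tr@path[nrow(tr@path), ])
  ph <- pairHead(nuc, ends[1, ], fineSpacing, searchRadius = 6)
  if (ph$flag == "unpaired") ph <- pairHead(nuc, ends[2, ], fineSpacing,
                                            searchRadius = 6)
  expect_true(ph$flag %in% c("", "ambiguous"))
  # oracle: median of the nuclei channel within 2 sigma of the known head
  h <- as.numeric(jsonlite::fromJSON(
    gtObjects(envTruth(env))$params_json[1])$head)
  d <- dim(nuc)
  co <- arrayInd(seq_along(nuc), d)
  dist <- sqrt(((co[, 1] - 1 - h[1]) * fineSpacing[1])^2 +
               ((co[, 2] - 1 - h[2]) * fineSpacing[2])^2 +
               ((co[, 3] - 1 - h[3]) * fineSpacing[3])^2)
  oracle <- median(nuc[dist <= 1.6][nuc[dist <= 1.6] >=
                                      CatSperQuant:::otsuThreshold(nuc)])
  expect_equal(ph$reference, oracle, tolerance = 0.05)

  # no nucleus in range: unpaired flag
  expect_identical(pairHead(array(0, c(8, 8, 8)), c(4, 4, 4))$flag, "unpaired")

  # two equidistant heads: deterministic lower-id choice, flagged ambiguous
  crop <- array(0, c(9, 21, 21))
  for (dz in -2:2) for (dy in -2:2) for (dx in -2:2) {
    crop[5 + dz, 5 + dy, 11 + dx] <- 1
    crop[5 + dz, 17 + dy, 11 + dx] <- 1
  }
  ph2 <- pairHead(crop, c(4, 10, 10), spacing = c(1, 1, 1),
                  searchRadius = 50, minVoxels = 5)
  expect_identical(ph2$flag, "ambiguous")
  expect_lt(ph2$centroid[2], 10)  # first (lower-id) component wins
})

test_that("linearization is isometric for straight tails", {
  seeds <- singleCellSeeds(12, from = 1)
  expect_gte(length(seeds), 8)
  relErr <- vapply(seeds, function(s) {
    env <- singleCellEnv(s)
    a <- voxelData(envChannels(env)$catsper)
    tr <- linearizeTail(a, fineSpacing, minLength = 3, frameId = "iso")
    truth <- insideTailLength(env)
    abs(max(traceArclength(tr)) - truth) / truth
  }, numeric(1))
  # endpoint localization is limited by the 0.2 um arclength step, which on
  # these deliberately short 6 um test tails is 3% per end; the 5% isometry
  # bound therefore applies to the population mean, with a 10% per-cell guard
  expect_lt(mean(relErr), 0.05)
  expect_lt(max(relErr), 0.10)
})

test_that("curved and straight tails yield matching intensity profiles", {
  sStraight <- singleCellSeeds(1, from = 1)
  sCurved <- singleCellSeeds(1, from = 101, curvatureSd = 0.3,
                             maxCurvature = 0.3)
  envS <- singleCellEnv(sStraight)
  envC <- singleCellEnv(sCurved, curvatureSd = 0.3, maxCurvature = 0.3)
  trS <- linearizeTail(voxelData(envChannels(envS)$catsper), fineSpacing,
                       minLength = 3, frameId = "s")
  trC <- linearizeTail(voxelData(envChannels(envC)$catsper), fineSpacing,
                       minLength = 3, frameId = "c")
  # same angular intensity law: interior mean intensities agree
  mid <- function(tr) {
    arc <- traceArclength(tr)
    mean(traceIntensity(tr)[arc > 1 & arc < max(arc) - 1])
  }
  # disc-averaged intensity carries a small curvature bias (sampling disc
  # vs bend radius), so the agreement tolerance is 20%
  expect_equal(mid(trC), mid(trS), tolerance = 0.20)
})

test_that("signal-free and too-short frames are rejected with a reason", {
  expect_error(linearizeTail(array(0, c(10, 20, 20)), minLength = 1),
               class = "csq_trace_rejected")
  fx <- singleCellTrace()
  expect_error(linearizeTail(fx$crop, fineSpacing, minLength = 50),
               class = "csq_trace_rejected")
  expect_error(linearizeTail(fx$crop, fineSpacing, minLength = 50),
               "below minimum")
})

test_that("normalization is exact, guarded, and scale-equivariant", {
  tr <- new("SpermTrace", arclength = seq(0, 5, by = 0.5),
            intensity = rep(4, 11), nucleusReference = NA_real_,
            path = matrix(0, 11, 3), frameId = "t", flags = character())
  expect_identical(traceIntensity(normalizeTrace(tr, 1)), rep(4, 11))
  expect_identical(traceIntensity(normalizeTrace(tr, 2)), rep(2, 11))
  expect_error(normalizeTrace(tr, NA_real_), "unpaired")
  expect_error(normalizeTrace(tr, 0), "unpaired")

  # doubling gain and reference together leaves the normalized trace unchanged
  fx <- singleCellTrace()
  tr1 <- linearizeTail(fx$crop, fineSpacing, minLength = 3, frameId = "g1")
  tr2 <- linearizeTail(fx$crop * 2, fineSpacing, minLength = 3, frameId = "g2")
  n1 <- normalizeTrace(tr1, 0.5); n2 <- normalizeTrace(tr2, 1.0)
  expect_equal(traceIntensity(n1), traceIntensity(n2), tolerance = 1e-8)
})

test_that("overlay resamples, pads, and averages as promised", {
  mk <- function(len, val) new("SpermTrace",
    arclength = seq(0, len, by = 0.2), intensity = rep(val, len / 0.2 + 1),
    nucleusReference = 1, path = matrix(0, len / 0.2 + 1, 3),
    frameId = "o", flags = character())
  one <- overlayTraces(list(mk(4, 2)))
  expect_equal(one$mean, rep(2, 21))
  many <- overlayTraces(rep(list(mk(4, 3)), 20))
  expect_true(all(many$sd == 0))
  expect_equal(many$mean, rep(3, 21))
  ragged <- overlayTraces(list(mk(4, 1), mk(2, 3)))
  expect_identical(dim(ragged$matrix), c(2L, 21L))
  expect_true(anyNA(ragged$matrix[2, ]))
  expect_equal(ragged$mean[1], 2)            # both traces cover position 0
  expect_equal(ragged$mean[21], 1)           # only the long trace remains
  expect_error(overlayTraces(list()), "at least one")
})

test_that("continuity drop detection is exact, censored, and monotone in f", {
  flat <- new("SpermTrace", arclength = seq(0, 20, by = 0.2),
              intensity = rep(1, 101), nucleusReference = 1,
              path = matrix(0, 101, 3), frameId = "f", flags = character())
  r <- continuityFirstDrop(flat, 0.7)
  expect_true(r$censored)
  expect_equal(r$position, 20)

  step <- flat
  step@intensity[flat@arclength >= 12] <- 0
  r5 <- continuityFirstDrop(step, 0.5)
  expect_false(r5$censored)
  expect_equal(r5$position, 12)

  # synthetic degradation gradient with noise: breakpoint recovered within
  # one sustain window, and f = 0.5 drops at or after f = 0.7
  set.seed(123)
  for (rep in 1:25) {
    bp <- runif(1, 5, 15)
    arc <- seq(0, 20, by = 0.2)
    int <- ifelse(arc < bp, 1, pmax(0, 1 - (arc - bp) / 2)) +
      rnorm(length(arc), 0, 0.03)
    tr <- new("SpermTrace", arclength = arc, intensity = pmax(int, 0),
              nucleusReference = 1, path = matrix(0, length(arc), 3),
              frameId = "d", flags = character())
    d7 <- continuityFirstDrop(tr, 0.7)
    d5 <- continuityFirstDrop(tr, 0.5)
    expect_gte(d5$position, d7$position)
    expect_lt(abs(d7$position - (bp + 0.3 * 2)), 1)  # 70% crossing of the ramp
  }
})
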