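mkProfile <- function(areas) {
  new("QuadProfile", areas = areas, peakIdx = integer(4),
      valleyIdx = integer(4), peaks = rep(NA_real_, 4),
      valleys = rep(NA_real_, 4), delta = NA_real_,
      deltaPairwise = NA_real_, rotation = 0, flag = "")
}

test_that("delta is zero for homogeneous and one for ideal unit-contrast profiles", {
  flat <- quadDelta(mkProfile(rep(0.37, 80)))
  expect_identical(deltaValue(flat), 0)
  expect_identical(flat@flag, "non_quadrilateral")

  ideal <- rep(0, 80)
  ideal[c(10, 30, 50, 70)] <- 1
  qp <- quadDelta(mkProfile(ideal))
  expect_identical(deltaValue(qp), 1)
  expect_identical(qp@flag, "")
  expect_identical(qp@peakIdx, c(10L, 30L, 50L, 70L))

  # any profile with four strict maxima has positive delta
  wavy <- 0.5 + 0.2 * cos(4 * (seq_len(80) - 1) * 4.5 * pi / 180)
  expect_gt(deltaValue(quadDelta(mkProfile(wavy))), 0)
})

test_that("80-area sampling is faithful to simple geometries", {
  # homogeneous ring: 80 near-equal values
  flat <- renderQuadCrossSection(0.4, c(0, 90, 180, 270), peakHeight = 0.6,
                                 valleyHeight = 0.6)
  pr <- profileAreas(sample80Areas(flat, ringRadiusUm = 0.4))
  expect_length(pr, 80L)
  expect_lt(diff(range(pr)), 0.02 * max(pr))

  # delta-like spot at angle 0 makes area 1 the maximum
  n <- 81L
  img <- matrix(0, n, n)
  img[41, 41 + 20] <- 1  # +u axis, v = 0
  spot <- new("CrossSection", image = img, pixelSpacing = 0.02,
              cellId = "s", span = 0, rotation = 0, flags = character())
  prs <- profileAreas(sample80Areas(spot, ringRadiusUm = 0.4,
                                    areaRadiusUm = 0.03))
  expect_identical(which.max(prs), 1L)

  # 4-peak synthetic section: peaks land in the areas nearest the truth
  truth <- c(20, 110, 200, 290)
  sec <- renderQuadCrossSection(0.4, truth, peakWidthDeg = 18)
  qp <- quadDelta(sample80Areas(sec, ringRadiusUm = 0.4))
  got <- sort((qp@peakIdx - 1) * 4.5)
  expect_lt(max(abs(got - truth)), 4.6)
  expect_error(sample80Areas(sec, ringRadiusUm = 5), "exceeds")
})

test_that("quadrant alignment follows the convention and fixed rotations", {
  img <- matrix(0, 41, 41)
  img[5:15, 27:37] <- 1  # top-right block
  sec <- new("CrossSection", image = img, pixelSpacing = 0.05, cellId = "a",
             span = 0, rotation = 0, flags = character())
  al <- alignQuadrant(sec)
  expect_identical(al@rotation, 0)
  imgTL <- matrix(0, 41, 41)
  imgTL[5:15, 5:15] <- 1  # top-left block: one clockwise quarter turn needed
  secTL <- new("CrossSection", image = imgTL, pixelSpacing = 0.05,
               cellId = "b", span = 0, rotation = 0, flags = character())
  alTL <- alignQuadrant(secTL)
  expect_identical(alTL@rotation %% 360, 270)
  qs <- CatSperQuant:::quadrantSums(sectionImage(alTL))
  expect_identical(names(which.max(qs)), "TR")
})

test_that("delta is invariant to section orientation within tolerance", {
  set.seed(42)
  base <- c(20, 110, 200, 290)
  ref <- quadDelta(sample80Areas(
    renderQuadCrossSection(0.4, base, peakWidthDeg = 18, peakHeight = 1,
                           valleyHeight = 0.2), ringRadiusUm = 0.4))
  rots <- runif(60, 0, 360)
  deltas <- vapply(rots, function(th) {
    ang <- sort((base + th) %% 360)
    sec <- renderQuadCrossSection(0.4, ang, peakWidthDeg = 18,
                                  peakHeight = 1, valleyHeight = 0.2)
    deltaValue(quadDelta(sample80Areas(alignQuadrant(sec),
                                       ringRadiusUm = 0.4)))
  }, numeric(1))
  expect_lt(max(abs(deltas - deltaValue(ref))) / deltaValue(ref), 0.02)
})

test_that("superposition normalizes, preserves identical stacks, and averages jitter down", {
  sec <- renderQuadCrossSection(0.4, c(45, 135, 225, 315), peakWidthDeg = 18)
  one <- superposeSections(list(sec))
  expect_equal(sectionImage(one),
               sectionImage(sec) / sum(sectionImage(sec)), tolerance = 1e-12)
  many <- superposeSections(rep(list(sec), 7))
  expect_equal(sectionImage(many), sectionImage(one), tolerance = 1e-12)

  contrast <- function(img) {
    pr <- profileAreas(sample80Areas(
      new("CrossSection", image = img, pixelSpacing = sec@pixelSpacing,
          cellId = "x", span = 0, rotation = 0, flags = character()),
      ringRadiusUm = 0.4))
    max(pr) - min(pr)
  }
  set.seed(7)
  jittered <- lapply(1:15, function(i) {
    th <- runif(1, -30, 30)  # residual misalignment
    renderQuadCrossSection(0.4, sort((c(45, 135, 225, 315) + th) %% 360),
                           peakWidthDeg = 18)
  })
  sup <- superposeSections(jittered)
  expect_lt(contrast(sectionImage(sup)),
            contrast(sectionImage(one)))
  small <- renderQuadCrossSection(0.2, c(0, 90, 180, 270), patchRadius = 0.3)
  expect_error(superposeSections(list(sec, small)), "patch size")
})

test_that("cross-sections from 3D tails show the rendered quadrilateral", {
  fx <- singleCellTrace()
  tr <- fx$trace
  sec <- extractCrossSection(fx$crop, tr, positionUm = 3, spanUm = 1,
                             spacing = fineSpacing, pixelSpacing = 0.04,
                             cellId = "q")
  qp <- quadDelta(sample80Areas(sec))
  expect_identical(qp@flag, "")
  roll <- gtObjects(envTruth(fx$env))$orientation_deg[1]
  got <- sort(((qp@peakIdx - 1) * 4.5) %% 90)
  want <- sort((c(45, 135, 225, 315) + roll) %% 90)[1]
  expect_lt(min(abs(got - want)), 10)
  expect_error(extractCrossSection(fx$crop, tr, positionUm = 100,
                                   spacing = fineSpacing), "beyond")
})

test_that("graded region contrasts are rank-recovered in at least 95 of 100 replicates", {
  grades <- list(UTJ = c(1, 0.55), mid = c(1, 0.35), amp = c(1, 0.1))
  nCells <- 12
  ok <- 0L
  for (repl in 1:100) {
    means <- vapply(seq_along(grades), function(gi) {
      deltas <- vapply(seq_len(nCells), function(ci) {
        seed <- repl * 1000 + gi * 100 + ci
        sec <- renderQuadCrossSection(
          0.4, sort((c(45, 135, 225, 315) + (seed * 37) %% 360) %% 360),
          peakWidthDeg = 18, peakHeight = grades[[gi]][1],
          valleyHeight = grades[[gi]][2], noiseSd = 0.12, seed = seed)
        deltaValue(quadDelta(sample80Areas(alignQuadrant(sec),
                                           ringRadiusUm = 0.4)))
      }, numeric(1))
      mean(deltas)
    }, numeric(1))
    if (all(diff(means) > 0)) ok <- ok + 1L
    }
  expect_gte(ok, 95L)
})

test_that("region delta tables summarize and flag empty groups", {
  tab <- regionDeltaTable(c(rep(0.5, 4), 0.2, 0.3),
                          factor(c(rep("amp", 4), "utj", "utj"),
                                 levels = c("utj", "amp", "mid")))
  expect_identical(tab$n, c(2L, 4L, 0L))
  expect_equal(tab$sem_delta[tab$region == "amp"], 0)
  expect_true(tab$flagged[tab$region == "mid"])
  expect_error(regionDeltaTable(1:3, c("a", "b")), "length")
})
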