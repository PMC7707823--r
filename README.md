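# CatSperQuant

Quantification of CatSper1 nanodomain organization in 3D in situ sperm
imaging.

## The problem

During fertilization, sperm migrate through the female reproductive tract
(utero-tubal junction → isthmus → ampulla) while the CatSper calcium channel
on their flagellum is progressively cleaved and degraded. In intact cells
CatSper1 runs along the principal piece in four longitudinal stripes — the
*quadrilateral nanodomains* — which appear as four intensity maxima in a
transversal cross-section of the tail. Cleared-tissue (CLARITY-style) 3D
imaging of whole oviducts makes it possible to read this organization off
individual sperm *in situ*, but the volumes are large, crowded with somatic
nuclei and background noise, and the cells are arbitrarily oriented.

CatSperQuant implements the complete analysis chain for this setting, aimed
at microscopists and image analysts working with volumetric immunofluorescence
of sperm:

1. **simulate** — parametric rendering of 3D training/evaluation volumes
   containing sperm (curved flagellar tube with four angular sub-tubes plus a
   bright head), somatic nuclei (ellipsoids) and noise blobs, with exact
   per-voxel ground truth (`renderEnvironment`, `renderQuadCrossSection`,
   `writeEnvironment`).
2. **detect** — a trainable frame classifier: bright local maxima propose
   candidate locations, a small MLP ensemble classifies an analytical frame
   centred on each candidate as sperm / nucleus / noise, and detections are
   evaluated by greedy one-to-one coordinate matching, yielding
   sensitivity = TP/(TP+FN) and object-level specificity (`trainDetector`,
   `detectSperm`, `evaluateDetections`, `scrubFrame`, `sensitivityVsNoise`).
3. **trace** — tail post-processing: pair each CatSper1-positive tail with
   its head (`pairHead`), extract and linearize the centerline
   (`linearizeTail`), normalize to the nucleus reference
   (`normalizeTrace`), overlay populations (`overlayTraces`), and locate the
   first sustained 70%/50% intensity drop from the midpiece/principal-piece
   interface (`continuityFirstDrop`).
4. **quad** — the quadrilateral statistic: extract a transversal
   cross-section near the annulus (`extractCrossSection`), align it by its
   brightest quadrant (`alignQuadrant`), superpose cells
   (`superposeSections`), sample 80 circular areas on the membrane ring 4.5°
   apart (`sample80Areas`), and compute the Δ value
   (`quadDelta`):

   Δ = mean(I at the 4 angular peaks) − mean(I at the 4 intervening valleys),

   on the nucleus-normalized intensity scale. Δ = 0 is the baseline of an
   angularly homogeneous ring; an ideal unit-contrast quadrilateral gives
   Δ = 1.
5. **stats** — per-region group comparisons: Kruskal–Wallis with hand-rolled
   Dunn post-hoc tests (`kwAnova`), one-way ANOVA with Tukey HSD
   (`anovaTukey`), intact-cell classification and letter-coded count tables
   (`classifyIntact`, `classifyCounts`), and a deterministic markdown report
   (`buildReport`).
6. **pipeline** — `runPipeline(defaultConfig(), outDir)` chains
   simulate → train → detect → scrub → trace → quad → stats and writes
   hash-stamped CSV artifacts; `inst/scripts/run_pipeline.R` is a thin
   command-line wrapper.

## Worked example

```r
library(CatSperQuant)

specs <- list(spermSpec(5/12000), nucleusSpec(4/12000), noiseSpec(60/12000))
envs  <- lapply(1:6, function(i) renderEnvironment(specs, c(60,100,100), seed = 100 + i))
det   <- trainDetector(envs, seed = 1)

env   <- renderEnvironment(specs, c(60,100,100), seed = 2024)
envTruth(env)
#> GroundTruth: 98 objects (sperm=5, nucleus=8, noise=85), noise voxel occupancy 0.0073

hits <- detectSperm(envVolume(env), det)
hits
#> AnalyticalFrameSet: 9 frames of 16x40x40 voxels
#>   classes: sperm=9

evaluateDetections(hits, envTruth(env))
#> DetectionReport: TP=5 FN=0 FP=4 | sensitivity 1.000, specificity 0.806 (radius 5.0 um)

sec <- alignQuadrant(renderQuadCrossSection(0.4, c(30,120,210,300),
                                            peakWidthDeg = 18,
                                            peakHeight = 1, valleyHeight = 0.2))
quadDelta(sample80Areas(sec, ringRadiusUm = 0.4))
#> QuadProfile: delta = 0.7209 (pairwise 0.7209)
```

All five true sperm in the fresh volume are recovered (sensitivity 1.0); the
quick 6-environment model still produces a few false-positive frames
(specificity 0.81) — the full 30-environment training used by the acceptance
script reaches both rates above 0.9. The rendered cross-section with peak
height 1 and valley height 0.2 yields Δ ≈ 0.72: smaller than the nominal 0.8
contrast because the finite stripe width (18°) lifts the valleys.

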