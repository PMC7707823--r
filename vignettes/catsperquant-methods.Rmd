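---
title: "CatSperQuant: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CatSperQuant: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains what CatSperQuant computes, the assumptions behind
each stage, the parameters that matter, and where the design was genuinely
open. It states no empirical result beyond what the package's test suite and
`scripts/acceptance.R` themselves compute.

## 1. The synthetic-environment model

Real cleared-oviduct volumes are not publicly available, so training and
evaluation run on parametrically rendered stand-ins with exact ground truth.
A `SimulatedEnvironment` holds a composite volume (what the detector sees),
auxiliary channels ("nuclei" = somatic nuclei + sperm heads, "catsper" =
tails, unblurred per-class attribution channels), a per-voxel object-id
label array, tail centerlines, and a `GroundTruth` table.

**Sperm.** The flagellum is a bounded-curvature 3D curve: an AR(1) curvature
vector (SD `curvatureSd`, default 0.08 rad/µm, correlation length 3 µm) is
clipped at `maxCurvature` (0.25 rad/µm) so linearization stays well-posed.
Around the curve, 24 angular sub-tube samples at radius `tailRadius`
(0.4 µm) are splatted as tight Gaussians (σ = 0.08 µm), with the angular
intensity law

I(θ) = valley + (peak − valley) · Σₖ exp(−d(θ, θₖ)² / 2w²),

θₖ the four nanodomain angles (45°, 135°, 225°, 315° plus a per-cell uniform
random roll — section orientation is random, as in real imaging) and w the
stripe width (default 18°). The tight shell keeps the ring hollow at the
axis, which the membrane-ring fit of the 80-area sampler relies on. A
Gaussian head (σ = 1.0×0.8×0.8 µm, intensity 1 — the normalization
reference) sits at the proximal end. Default tail length is 12 µm: a
scaled-down principal piece chosen so that several whole cells fit a
desk-scale volume; real mouse flagella are several times longer, which only
makes tracing easier.

**Somatic nuclei** are Gaussian ellipsoids (σ = 1.8×1.4×1.4 µm × lognormal
size jitter, intensity 0.9): distinctly larger than sperm heads, as in
tissue. **Noise** objects are compact blobs with parabolic radial profile
I₀(1 − (d/r)²)₊; because their support is compact, the stored `noiseRate`
(voxel occupancy) is exactly recomputable from the rendered noise channel —
no arbitrary threshold is involved.

All signals are convolved with an isotropic Gaussian PSF (default σ =
0.15 µm, a typical confocal lateral width) and the composite receives a
constant background offset (0.02) plus Gaussian read noise (SD 0.01).
Default voxel spacing is 0.5×0.2×0.2 µm (z, y, x), emulating confocal
anisotropy. Objects are placed with centers uniformly inside the volume;
tails may exit and are clipped with a `clipped` flag, mirroring tissue
edges. Every random draw descends from one explicit seed through a
documented seed-splitting scheme, so environments are bit-reproducible.

What the generator does **not** emulate: realistic PSF asymmetries and
spectral bleed-through, autofluorescence texture, depth-dependent
attenuation, true head morphology (hooked, acrosome-bearing), or the organ
geometry. Passing tests therefore demonstrate the correctness and internal
consistency of the algorithms under controlled conditions — not performance
on any particular microscope's data.

## 2. Detection

Detection is candidate-centred. `findCandidates` proposes bright local
maxima (box neighborhood 0.8 µm, floor = Otsu threshold): sperm heads,
somatic nuclei and noise blobs all qualify — the classifier decides which
are sperm. For each candidate, an analytical frame (default 16×40×40 voxels
= 8×8×8 µm) is centred on it; near the volume boundary frames are padded
with the background median rather than shifted, so the candidate always sits
at the centre.

Frames are reduced to orientation-invariant features normalized to the
centre object's peak: intensity quantiles; weighted-PCA shape statistics of
three intensity bands (a bright core, a mid "tail" band, and the Otsu
foreground — an elongated mid band is the signature of a flagellum, a
blurred blob's mid band is an isotropic shell), the same statistics
restricted to a centred 2.5 µm ball; a directional shell profile (voxels
binned by radial shell and 26 direction cones; a tail gives one direction
that stays bright across all shells); and sorted coarse block means. The
classifier is a single-hidden-layer perceptron (nnet, 16 hidden units,
decay 10⁻³), trained with inverse-frequency class weights on frames centred
on ground-truth anchors (sperm heads, nucleus and noise centroids) with
±0.8 µm jitter, plus hard negatives (candidate peaks away from every anchor,
including mid-tail ridge peaks — only head-centred views count as sperm) and
random background frames. Three random restarts are fitted and their softmax
outputs averaged, damping the occasional poor optimum of a small MLP.

The representative coordinate of a sperm-positive frame is the
intensity-weighted centroid of the Otsu component containing the frame
centre, restricted to voxels within 2.5 µm of the centre: without the
restriction, two touching cells would collapse onto one shared component
centroid. Greedy non-maximum suppression uses a 1.2 µm radius — about one
head diameter — because in clustered samples two genuine cells are often
within a few micrometres of each other and matching is one-to-one; a larger
suppression radius would structurally cap sensitivity.

Evaluation (`evaluateDetections`) matches detections to true sperm
centroids greedily by increasing distance within the matching radius
(default 5 µm), one-to-one. Sensitivity is TP/(TP+FN). The paper-style
specificity is not fully defined in terms of objects, so we adopt and
document the object-level reading: the fraction of non-sperm ground-truth
objects (somatic nuclei and noise blobs) that are *not* claimed by an
unmatched sperm-positive detection within the radius; detections already
matched to a true sperm do not flag bystanders.

## 3. Tail traces and continuity

`scrubFrame` reverses environment production: Otsu components of a
sperm-positive frame are isolated, re-classified one at a time, and
components called nucleus or noise are replaced by the local background
estimate; sperm-attributed intensity is left untouched. The pipeline
additionally masks the nuclei-channel (head) signal before tracing, so the
trace covers the CatSper-positive principal piece only, and the
midpiece/principal-piece interface is operationalized as the proximal end of
that signal.

`linearizeTail` extracts the centerline as the longest geodesic path
(double breadth-first search) through the 26-connected foreground — the
Otsu mask extended to half the threshold and restricted to the component
containing the core signal, so tapered tube ends are kept. The voxel
staircase is smoothed with coordinate-wise smoothing splines, each sample is
re-centred on the intensity centroid of its transverse plane (twice), and
the path is re-parameterized by arclength (step 0.2 µm). Intensity along the
trace is a small transverse disc average (radius 0.3 µm), robust to the path
riding a bright nanodomain stripe. Tail ends are then located at the
outermost inflection (steepest descent) of the transverse-flux profile
(area-weighted disc integral, radius 0.7 µm): the half-flux point of a
finite-radius tube lies measurably beyond the physical end, whereas the
inflection tracks it closely. With this chain, recovered arclengths of
unclipped straight cells agree with the generated lengths to a few percent;
the residual is dominated by the 0.2 µm sampling step, which matters only
for the deliberately short test tails. Paths shorter than `minLength`
(default 10 µm, configured to match the simulated tail lengths) raise a
classed condition.

`normalizeTrace` divides by the paired nucleus's median intensity
(`pairHead`: nearest nucleus-channel component to the tail's proximal end
within 5 µm; equidistant candidates resolve to the lower component id and
are flagged). Normalization makes traces invariant to illumination gain;
unpaired traces are excluded from normalized statistics.

`continuityFirstDrop` reports the smallest arclength at which intensity
falls below f × reference and stays below for at least the sustain window.
Open choices, fixed as: reference = mean intensity over the first 2 µm of
the principal piece; sustain window = 1 µm (suppresses single-sample dips;
window 0 gives the pointwise variant, also reportable); traces that never
drop are censored at the tail length. Because the f = 0.5 threshold is below
the f = 0.7 threshold, the 50% drop position is never earlier than the 70%
one — a property the tests exercise.

## 4. The quadrilateral Δ statistic

`extractCrossSection` resamples the volume into the plane orthogonal to the
local tangent, averaged over a 1 µm span, by default 2 µm distal to the
proximal trace end ("close to the annulus" is qualitative; the CatSper
signal is brightest there). The patch is iteratively re-centred on its
intensity centroid because the extracted skeleton rides the bright shell
rather than the geometric axis; sections whose local radius of curvature is
smaller than the span are flagged "curved".

`alignQuadrant` rotates by multiples of 90° only (counterclockwise
positive), placing the brightest Cartesian quadrant top-right: this
preserves the four-fold structure and needs no interpolation beyond the
original patch. `superposeSections` averages total-intensity-normalized
patches.

`sample80Areas` places 80 circular areas on a single ring (open choice:
single ring vs filled disc; the membrane ring is where nanodomains live) at
4.5° spacing, ordered counterclockwise from +u. The ring radius is fitted
per section by maximizing the mean ring intensity — well-posed because the
rendered (and real) ring is hollow at the axis; the area radius defaults to
half the inter-centre arc, at least one pixel.

`quadDelta` smooths the 80-area profile with a circular moving average
(window 5 areas = 22.5°, separating the 90°-spaced peaks from noise), takes
the four highest smoothed local maxima as peaks and the smoothed minima
strictly between consecutive peaks as valleys, then refines each location to
the raw extremum within half a smoothing window (smoothing turns isolated
peaks into plateaus whose edges would otherwise win) and reads the **values
from the unsmoothed profile**. Thus an ideal unit-contrast profile gives
Δ = 1 exactly and the statistic carries no smoothing attenuation. Δ =
mean(peaks) − mean(valleys); since the Δ definition could also be read as a
per-pair average, that variant is computed alongside (`deltaPairwise`; the
two coincide up to pairing). Profiles with fewer than four smoothed maxima
are flagged `non_quadrilateral` and fall back to top-4/bottom-4 smoothed
values, so an angularly homogeneous section yields Δ = 0 — the baseline.
Because alignment is by quadrant and the areas are resampled from the
aligned patch, Δ is rotation-invariant up to interpolation error (tested at
2%).

## 5. Group statistics

`kwAnova` wraps `stats::kruskal.test` (tie-corrected H) and adds pairwise
Dunn z tests (pooled-rank differences with the tie correction, Holm-adjusted
by default) — no installed package provides Dunn's test, so it is
implemented directly and checked against rank-formula oracles in the tests.
`anovaTukey` wraps `aov` + `TukeyHSD`. Both are exercised on the Δ-by-region
comparison; the two tests agreeing is the expected behaviour for these
effect sizes. `classifyCounts` aggregates intact/non-intact flags per region
and replicate, reports mean proportion ± SEM across replicates, and
letter-codes pairwise Tukey differences (insert–absorb compact letter
display). The automatic intact-CatSper1 rule — Δ above a configurable
threshold AND censored 70% continuity — is an operationalization of what was
originally a manual call, and is labelled as such in reports.

## 6. Problem sizes and numerical choices

The package's own reference experiment (tests and `scripts/acceptance.R`)
uses 100×100×60-voxel volumes (20×20×30 µm) with on average 5 sperm, 4
somatic nuclei and 60 noise blobs (≈0.7% voxel occupancy); 30 training
environments spanning four noise abundances (30–120 blobs per volume); 20
held-out evaluation environments; matching radius 5 µm. Property suites use
smaller volumes and finer (0.3×0.1×0.1 µm) single-cell renders for tracing
and cross-section work, and 2D rendered sections for Δ calibration and
region-ranking replicates. These sizes keep a full run in minutes on one
CPU while leaving every quantity estimable.

Numerical conventions: axis order (z, y, x), 0-based voxel coordinates in
all emitted tables, physical quantities in µm (every CSV carries a comment
line saying so); Otsu thresholds on 256-bin histograms; trilinear
interpolation everywhere a fractional coordinate is read; exact ties in
class scores resolve sperm > nucleus > noise (conservative toward recall);
quadrant-alignment ties resolve to the smallest rotation; equidistant head
candidates resolve to the lower object id. Degenerate inputs (empty volumes,
signal-free frames, empty regions, all-noise environments) return empty or
flagged results rather than errors wherever the contract allows.

## 7. Known limitations

* The detector is validated on the generator's own distribution; applying it
  to real stacks requires retraining on environments rendered to match the
  instrument (spacing, PSF, intensity statistics) or on annotated real
  frames.
* Object-level specificity depends on the adopted definition of "claimed";
  the frame-level variant can be computed from the emitted frame tables.
* Δ at the default confocal-like settings is attenuated relative to the
  generative peak−valley contrast (finite stripe width and PSF); comparisons
  across regions are therefore made within a common imaging configuration,
  where the monotone relation between generated and recovered contrast is
  what the rank-recovery tests establish.
* Tracing assumes one dominant tubular component per scrubbed frame;
  overlapping tails in very dense clusters are not disentangled.
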