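# FAProtrusion

Measures how far individual focal-adhesion (FA) proteins protrude beyond a
partner protein at the two ends of each adhesion, from dual-colour
(red = mCherry, green = GFP) super-resolution fluorescence images, and
compares the resulting population distributions against a same-protein
reference. It is written for cell biologists quantifying the nanoscale
longitudinal organisation of FA proteins (paxillin, vinculin, zyxin, VASP
and the like) in structured-illumination or comparable data with a known
pixel pitch (40 nm by default).

## The measurement

For each segmented adhesion a line is fitted along the long axis
(intensity-weighted moments, refined by perpendicular Gaussian ridge
fits), rasterized to an 8-connected pixel chain, and terminated where the
3×3-box mean of **both** channels drops below 30% of its per-channel
maximum along the line. The end nearer the rectangle around the cell is
the *head* (distal), the other the *tail*. Along the path, a position is
positive for a channel when its median-filtered intensity (window 5) is at
least 40% of that channel's filtered maximum. The longest dual-positive
stretch tolerating internal gaps of at most 4 px (160 nm) is the *main
stretch*; the pixel bordering it at each end names the protruding channel,
and the protrusion length is the path distance to the outermost positive
pixel of that channel's gap-tolerant run, with straight steps of 40 nm and
diagonal steps of √3200 ≈ 57 nm. A bordering pixel negative for both
channels means a protrusion of exactly 0.

Signed lengths (green positive, red negative) are histogrammed in 80-nm
bins centred on zero, bias-corrected by the per-end median of a
same-protein reference set, and compared with two-tailed Mann–Whitney U
tests (exact permutation distribution for small samples, tie- and
continuity-corrected normal approximation otherwise). 2D head/tail
difference histograms are rendered through a cyan–white–magenta lookup
table (`level = round(255(Δ + 3.45)/6.90)`, levels 124–132 white).

Because real two-colour imaging data come without ground truth, the
package includes a first-class synthetic scene generator with ground truth
(elongated two-channel plateaus with known per-end extensions,
reconstruction-like noise including low-intensity holes in bright patches,
and time-lapse cell masks with programmed edge motion) against which every
stage is tested.

## Worked example

A synthetic population in which the red protein protrudes at the head and
the green protein at the tail (the paxillin-head / zyxin-tail pattern):

```r
library(FAProtrusion)

set.seed(7)
fas <- lapply(1:24, function(i) {
  centre <- c(60 + 45 * ((i - 1) %/% 6), 60 + 65 * ((i - 1) %% 6)) +
    runif(2, -8, 8)
  FASpec(centre = centre, angle = runif(1, 0, 180),
         coreLength = runif(1, 22, 36), width = runif(1, 8, 11),
         headChannel = "red", headExtra = sample(3:6, 1),
         tailChannel = "green", tailExtra = sample(4:8, 1),
         peakRed = runif(1, 0.5, 0.8), peakGreen = runif(1, 0.5, 0.8))
})
poly <- cbind(c(15, 15, 485, 485), c(15, 485, 485, 15))
spec <- SceneSpec(imageShape = c(500L, 500L), faSpecs = fas,
                  cellPolygon = poly, seed = 7L)
images <- addNoise(renderScene(spec)$images, spec@noise, seed = 7L)

measurements <- measureScene(images, segmentFAs(images),
                             computeCellFrame(images))
experimental <- toSigned(measurements, "pax/zyx-like")
reference <- simulateNullSet(500, seed = 8L)
bias <- referenceBias(reference)
expC <- applyBias(experimental, bias)
refC <- applyBias(reference, bias)
compareHistograms(expC, refC, "head")
compareHistograms(expC, refC, "tail")
```

prints

```
HistogramComparison (head): n=24 vs reference n=500
  U = 4500.0, two-sided p = 0.000502
  median protrusion length: -136.6 nm
HistogramComparison (tail): n=24 vs reference n=500
  U = 7500.0, two-sided p = 0.000724
  median protrusion length: +209.7 nm
```

i.e. the red channel protrudes a median 137 nm at the head (negative =
red) and the green channel 210 nm at the tail, both highly significant
against the identical-channel reference — matching the geometry the scene
was built with.

The same chain runs as file-based stages (`simulate`, `segment`,
`measure`, `stats`, `motility`, `all`) via `runPipeline()` or the thin
wrapper `inst/scripts/fa-pipeline.R`, with every tunable in one YAML
config that is echoed beside the outputs.

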