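---
title: "Measuring differential longitudinal distributions of focal adhesion proteins"
author: "FAProtrusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring differential longitudinal distributions of focal adhesion proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FAProtrusion)
```

## The measurement

Focal adhesions (FAs) are elongated multiprotein complexes, typically
1–2 µm long and 300–500 nm wide, that couple the actin cytoskeleton to the
extracellular matrix. When two FA proteins are imaged in two colours
(mCherry = red, GFP = green) at super-resolution, their longitudinal
distributions along the FA long axis often differ: one protein may stick
out at the end of the FA pointing toward the adherent membrane edge (the
*head*), the other at the opposite end (the *tail*). FAProtrusion measures
these *protrusion lengths* per FA and compares their population
distributions against a same-protein reference.

The per-FA measurement chain is:

1. **Segmentation.** A difference-of-Gaussians band pass (default
   σ = 1 px and 5 px) is applied to the mean of the two channels and
   thresholded with Otsu's method on a 256-bin histogram of the response
   range (foreground strictly above threshold). 8-connected components are
   filtered by area (default 50–5000 px at 40 nm pitch). Touching FAs can
   be separated with a declarative ROI-edits file (delete / split
   operations), the reproducible replacement for interactive outline
   correction.
2. **Axis fitting.** The region's intensity-weighted second-order moments
   give the FA centre and major-axis angle (the classic "fit ellipse").
   The axis is refined by fitting a 1D Gaussian (baseline + amplitude) to
   the perpendicular green-channel profile at 1 px spacing along the axis
   and passing a total-least-squares line through the accepted fitted
   centres; if fewer than 3 centres are usable, the moment axis is kept
   and flagged.
3. **Termination.** The axis is rasterized to an 8-connected pixel chain
   and cut, walking outward from the centre, at the last pixel before the
   3×3-box mean intensities of *both* channels fall below 30% of their
   per-channel maxima along the chain.
4. **Orientation.** The end of the path closer to the rectangle drawn
   around the cell becomes the head (index 1); exact ties break toward the
   smaller row, then column.
5. **Profiles and positivity.** Both channels are sampled along the path
   and median-filtered (window 5, edge-truncated). A position is positive
   for a channel when its filtered value is at least 40% of that channel's
   filtered maximum (thresholds per FA, per channel; the ≥ convention is
   used at the boundary).
6. **Main stretch and protrusions.** The longest interval that starts and
   ends dual-positive and contains no not-both-positive run longer than
   4 px (160 nm) is the main stretch. The pixel bordering it at each end
   determines the protruding channel; the protrusion length is the path
   distance from the last main-stretch pixel to the outermost pixel of the
   gap-tolerant single-channel run. A straight pixel step is 40 nm, a
   diagonal step √3200 ≈ 57 nm. A bordering pixel negative for both
   channels gives length exactly 0.

Signed values (green positive, red negative, none zero) feed the
statistics: 80-nm signed histograms centred on 0, two-tailed Mann–Whitney
tests against the reference set, per-end bias correction by the reference
median, 80 × 80 nm 2D head/tail histograms, and a cyan–white–magenta
difference rendering with `level = round(255 (Δ + 3.45)/6.90)`, levels
124–132 kept white.

## Design choices in ambiguous places

Several details are genuinely open; the package fixes one convention each
and keeps it configurable where sensible:

* **Positivity boundary** uses ≥ (a value exactly at 40% of the maximum is
  positive).
* **Protrusion length counts steps, not pixels**: N protruding pixels span
  N steps from the main-stretch boundary, so an absent protrusion is
  exactly 0 nm and lengths are additive along the path.
* **Gap pixels inside a protruding run** contribute path distance but not
  identity; the run ends at the outermost positive pixel.
* **Median filter edges** use truncated windows (sizes 3 and 4 at the
  ends), not reflection.
* **Termination maxima** are maxima of the 3×3-box mean (not the raw pixel
  maximum), applied consistently to both channels.
* **Tie between equal-length candidate main stretches** goes to the one
  nearer the head.
* **Bias correction** subtracts the reference set's per-end median from
  every experimental signed value. Estimating the bias per end is strictly
  more general than a single global figure and collapses to it when the
  two ends agree.
* **Mann–Whitney p values** come from the exact permutation distribution
  (shift algorithm on doubled midranks, exact under ties) whenever
  `n_x n_y ≤ 400`, otherwise from the normal approximation with tie and
  continuity corrections. Signed values are compared, which reproduces the
  histogram-shift logic; the median is reported as a population protrusion
  length only when p < 0.05. No multiple-testing correction is applied.
* **Segmentation source** defaults to the mean of both channels; the
  σ values (1/5 px) pass structures at the FA cross-section scale. Both
  are configurable because the original macro does not name them.
* **Axis search range**: the chain extends up to 50 px beyond the
  segmented region before termination must fire.
* **Edge motility criteria** (200 nm motion threshold between the two
  time points, 2 µm near-edge distance, 15-px smoothing window along the
  edge) are declared defaults — the underlying study states no numbers —
  and protrusion/retraction are merged into "moving" for the two-way
  comparison.

## The synthetic-data generator

Real two-colour imaging data come without ground truth, so the package
ships a first-class generator that every stage is validated against. A scene is a
set of `FASpec`s inside an irregular convex cell outline: each FA is an
anisotropic plateau (Gaussian cross profile with the requested FWHM;
half-Gaussian longitudinal end falloff with SD 1 px, which keeps the
40%-threshold crossing within about a pixel of the nominal end) whose two
channels are identical except for single-channel, same-width,
same-intensity extensions at the head and/or tail. Defaults emulate the
study conditions: 1024 × 1024 px at 40 nm pitch, 20–60 FAs per cell of
total length 25–50 px and width 8–12 px, approximately radial orientation
so the head (the end nearer the cell frame) is unambiguous, and protrusion
lengths of 2–8 px. Candidate FAs whose axis corridors come within 22 px of
another FA are rejected: adhesions are distinct objects, matching the
source workflow in which touching FAs were separated before measurement.

Noise emulates camera read noise (additive Gaussian), shot-like
signal-dependent noise, and the reconstruction artefacts of structured
illumination, modelled phenomenologically as small low-intensity holes
punched only inside bright patches — the failure mode the 4-px gap
tolerance exists to absorb. Intensities are digitized to a 16-bit grid, so
TIFF round trips are exact. Time-lapse cell masks displace programmed
polygon segments along their outward normals, giving per-segment
ground-truth motion classes for the edge-motility classifier.

What the generator does *not* emulate: the optical PSF and the structured
correlations of a real SIM reconstruction, chromatic aberration,
photobleaching, drift, FA turnover, and curved adhesions. Passing tests
therefore demonstrate that the measurement implements its rules correctly
and recovers known geometry under plausible noise — not that the
biological conclusions of any particular experiment would reproduce.

## Validation choices and problem sizes

The test suite checks every operation against independent oracles:
exhaustive enumeration for the gap-tolerant run rules (all boolean profile
pairs up to length 7, i.e. 21 844 pairs, plus 10 000 random longer pairs up
to length 40), full `combn()` permutation enumeration for the Mann–Whitney
p values (all sample-size pairs with `n_x n_y ≤ 100`), a brute-force Otsu
search, and ground-truth recovery on rendered scenes (two conditions of
200 FAs each across 10 scenes of 512 × 512 px — sizes chosen to keep the
full suite fast while preserving the default FA geometry and noise).
Null calibration draws disjoint 500-FA samples from a 20 000-measurement
pool simulated at the intensity-profile level with the package's own
measurement operators, and checks the 5% nominal rejection rate of the
comparison over 1000 repetitions.

## Known limitations

* **Resolution limit at one bin.** A 2-px (80 nm) protrusion is at the
  edge of what the measurement rules can resolve: with a window-5 median
  filter truncated at the path end and a path that terminates at the
  protrusion tip, the lagging channel's filtered profile can stay above
  its 40% threshold across the whole protrusion, absorbing it into the
  main stretch. On noiseless synthetic scenes, channel identity is correct
  for 100% of protrusions of 3 px and longer but only ~94% of 2-px
  protrusions (most often on diagonal axes, where steps are 57 nm). This
  mirrors the scale of the measurement bias the reference set exists to
  correct, and is a property of the published measurement rules, not of
  noise.
* FAs are treated as straight; strongly curved adhesions will be
  terminated early or discarded.
* The classifier of membrane-edge motility uses declared numeric defaults
  for "close to" and "moving"; they are configuration, not inference.
* The Otsu threshold assumes a bimodal band-pass response; scenes that are
  nearly empty or nearly full raise the degenerate-histogram error rather
  than guessing.

## A worked example

```{r example, eval = FALSE}
library(FAProtrusion)

spec <- randomSceneSpec(nFAs = 30, imageShape = c(512L, 512L), seed = 7L)
scene <- renderScene(spec)
images <- addNoise(scene$images, spec@noise, seed = 7L)

regions <- segmentFAs(images)
frame <- computeCellFrame(images)
measurements <- measureScene(images, regions, frame)

experimental <- toSigned(measurements, "experiment")
reference <- simulateNullSet(500, seed = 8L)
bias <- referenceBias(reference)
expC <- applyBias(experimental, bias)
refC <- applyBias(reference, bias)

compareHistograms(expC, refC, "tail")
```

The same chain is available as file-based stages through
`runPipeline()` (subcommands `simulate`, `segment`, `measure`, `stats`,
`motility`, `all`) with every tunable in a single YAML configuration that
is echoed next to the outputs of every run.
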