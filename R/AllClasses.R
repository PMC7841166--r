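#' @import methods
#' @importFrom stats median rank pnorm rnorm runif rpois sd cov quantile
#' @importFrom utils read.csv write.csv modifyList
NULL

.CHANNELS <- c("red", "green")
.CHANNELS_NONE <- c("red", "green", "none")

## ---------------------------------------------------------------------------
## Image containers
## ---------------------------------------------------------------------------

#' Aligned two-channel projected image
#'
#' Holds the red (mCherry) and green (GFP) intensity grids of one field of
#' view after z-projection, together with the physical pixel pitch. This is
#' the unit every analysis stage consumes.
#'
#' @slot red,green numeric matrices of identical dimension, intensities >= 0.
#' @slot pixelPitchNm physical pixel pitch in nm (40 for the reconstructed
#'   SIM data this package targets).
#' @slot provenance free-form list (source file, z-slices used).
#' @export
setClass("ProjectedImagePair",
  slots = c(red = "matrix", green = "matrix",
            pixelPitchNm = "numeric", provenance = "list"))

setValidity("ProjectedImagePair", function(object) {
  if (!all(dim(object@red) == dim(object@green)))
    return("red and green grids must have identical dimensions")
  if (min(object@red) < 0 || min(object@green) < 0)
    return("intensities must be >= 0")
  if (length(object@pixelPitchNm) != 1 || object@pixelPitchNm <= 0)
    return("pixelPitchNm must be a single positive number")
  TRUE
})

#' Construct a ProjectedImagePair
#' @param red,green numeric intensity matrices (same dimension).
#' @param pixelPitchNm pixel pitch in nm, default 40.
#' @param provenance optional list of provenance metadata.
#' @return A \linkS4class{ProjectedImagePair}.
#' @export
ProjectedImagePair <- function(red, green, pixelPitchNm = 40,
                               provenance = list()) {
  new("ProjectedImagePair", red = red, green = green,
      pixelPitchNm = pixelPitchNm, provenance = provenance)
}

#' Multi-z two-channel stack
#'
#' Raw intensity data as read from a TIFF, prior to z-projection.
#' Storage is a 4D array indexed \code{[row, col, channel, z]}; the
#' \code{channels} slot maps the roles \code{"red"}/\code{"green"} onto the
#' third index.
#'
#' @slot data 4D numeric array \code{[row, col, channel, z]}.
#' @slot channels character vector naming the channel roles in storage order.
#' @slot pixelPitchNm pixel pitch (nm).
#' @slot zStepNm z interval between slices (nm); metadata only.
#' @export
setClass("ChannelStack",
  slots = c(data = "array", channels = "character",
            pixelPitchNm = "numeric", zStepNm = "numeric"))

setValidity("ChannelStack", function(object) {
  if (length(dim(object@data)) != 4) return("data must be a 4D array")
  if (dim(object@data)[3] != 2 || !setequal(object@channels, .CHANNELS))
    return("exactly two channel roles ('red','green') must be assigned")
  if (object@pixelPitchNm <= 0) return("pixelPitchNm must be > 0")
  TRUE
})

## ---------------------------------------------------------------------------
## Segmentation
## ---------------------------------------------------------------------------

#' One segmented focal adhesion region
#'
#' @slot id integer region id (deterministic: regions are numbered by the
#'   top row, then left column, of their bounding boxes).
#' @slot pixels n x 2 integer matrix of (row, col) member pixels
#'   (8-connected).
#' @slot centroid numeric (row, col) unweighted centroid.
#' @slot area integer pixel count.
#' @slot bbox integer c(rowMin, rowMax, colMin, colMax).
#' @export
setClass("FARegion",
  slots = c(id = "integer", pixels = "matrix", centroid = "numeric",
            area = "integer", bbox = "integer"))

#' @rdname FARegion-class
#' @param id region id.
#' @param pixels n x 2 (row, col) pixel matrix.
#' @export
FARegion <- function(id, pixels) {
  pixels <- matrix(as.integer(pixels), ncol = 2,
                   dimnames = list(NULL, c("row", "col")))
  new("FARegion", id = as.integer(id), pixels = pixels,
      centroid = colMeans(pixels), area = nrow(pixels),
      bbox = c(range(pixels[, 1]), range(pixels[, 2]))[c(1, 2, 3, 4)])
}

#' Segmentation parameters
#'
#' @slot sigmaLow,sigmaHigh Gaussian SDs (px) of the band-pass
#'   (difference-of-Gaussians) filter; sigmaHigh > sigmaLow > 0.
#' @slot minArea,maxArea region area bounds in px.
#' @slot source which image is thresholded: "green", "red" or "mean".
#' @export
setClass("SegmentationParams",
  slots = c(sigmaLow = "numeric", sigmaHigh = "numeric",
            minArea = "numeric", maxArea = "numeric", source = "character"))

setValidity("SegmentationParams", function(object) {
  if (!(object@sigmaHigh > object@sigmaLow && object@sigmaLow > 0))
    return("need sigmaHigh > sigmaLow > 0")
  if (!(object@maxArea > object@minArea && object@minArea > 0))
    return("need maxArea > minArea > 0")
  if (!object@source %in% c("green", "red", "mean"))
    return("source must be 'green', 'red' or 'mean'")
  TRUE
})

#' @rdname SegmentationParams-class
#' @param sigmaLow,sigmaHigh,minArea,maxArea,source see slot documentation.
#' @export
SegmentationParams <- function(sigmaLow = 1, sigmaHigh = 5, minArea = 50,
                               maxArea = 5000, source = "mean") {
  new("SegmentationParams", sigmaLow = sigmaLow, sigmaHigh = sigmaHigh,
      minArea = minArea, maxArea = maxArea, source = source)
}

## ---------------------------------------------------------------------------
## Axis fitting
## ---------------------------------------------------------------------------

#' Fitted longitudinal axis of one adhesion
#'
#' @slot centre numeric (row, col), continuous coordinates.
#' @slot angle degrees in [0, 180) between the image horizontal axis and the
#'   long axis.
#' @slot majorAxisPx,minorAxisPx full ellipse axis lengths (4 sqrt(lambda))
#'   from the intensity-weighted second moments.
#' @slot ridgePoints m x 2 matrix of fitted perpendicular-Gaussian centres
#'   (empty until ridge refinement).
#' @slot refined TRUE when the ridge refinement replaced the moment axis.
#' @slot isotropic TRUE when the region was too round for a reliable moment
#'   axis (eccentricity < 0.05) and the bounding-box diagonal tie-break was
#'   used.
#' @export
setClass("AxisLine",
  slots = c(centre = "numeric", angle = "numeric",
            majorAxisPx = "numeric", minorAxisPx = "numeric",
            ridgePoints = "matrix", refined = "logical",
            isotropic = "logical"))

#' @rdname AxisLine-class
#' @param centre,angle,majorAxisPx,minorAxisPx,ridgePoints,refined,isotropic
#'   see slot documentation.
#' @export
AxisLine <- function(centre, angle, majorAxisPx, minorAxisPx,
                     ridgePoints = matrix(numeric(0), 0, 2),
                     refined = FALSE, isotropic = FALSE) {
  new("AxisLine", centre = centre, angle = angle %% 180,
      majorAxisPx = majorAxisPx, minorAxisPx = minorAxisPx,
      ridgePoints = ridgePoints, refined = refined, isotropic = isotropic)
}

#' Rasterized axis path
#'
#' Ordered 8-connected pixel chain along an adhesion long axis. When
#' oriented, index 1 is the head (distal) end. Each step between consecutive
#' pixels is either straight (40 nm at 40 nm pitch) or diagonal
#' (sqrt(3200) nm, about 57 nm).
#'
#' @slot coords n x 2 integer (row, col) chain.
#' @slot diagonal logical of length n-1; TRUE for diagonal steps.
#' @slot cumNm cumulative path distance in nm from the first pixel (length n,
#'   starts at 0).
#' @slot pixelPitchNm pixel pitch (nm).
#' @slot oriented TRUE once head/tail orientation is applied.
#' @export
setClass("AxisPath",
  slots = c(coords = "matrix", diagonal = "logical", cumNm = "numeric",
            pixelPitchNm = "numeric", oriented = "logical"))

setValidity("AxisPath", function(object) {
  n <- nrow(object@coords)
  if (n >= 2) {
    d <- abs(diff(object@coords))
    if (any(d > 1) || any(rowSums(d) == 0))
      return("consecutive pixels must be 8-adjacent and distinct")
  }
  if (any(diff(object@cumNm) <= 0)) return("cumNm must be strictly increasing")
  TRUE
})

#' @rdname AxisPath-class
#' @param coords n x 2 integer (row, col) pixel chain.
#' @param pixelPitchNm pixel pitch in nm.
#' @param oriented logical; is index 1 the head end?
#' @export
AxisPath <- function(coords, pixelPitchNm = 40, oriented = FALSE) {
  coords <- matrix(as.integer(coords), ncol = 2,
                   dimnames = list(NULL, c("row", "col")))
  if (nrow(coords) >= 2) {
    d <- abs(diff(coords))
    diagonal <- d[, 1] == 1 & d[, 2] == 1
  } else diagonal <- logical(0)
  stepNm <- ifelse(diagonal, sqrt(2), 1) * pixelPitchNm
  new("AxisPath", coords = coords, diagonal = unname(diagonal),
      cumNm = unname(c(0, cumsum(stepNm))), pixelPitchNm = pixelPitchNm,
      oriented = oriented)
}

#' Rectangle drawn around the cell
#'
#' The distal ("head") end of each adhesion is the axis end closest to this
#' rectangle's perimeter.
#'
#' @slot rowRange,colRange numeric length-2 bounds (inclusive).
#' @export
setClass("CellFrame", slots = c(rowRange = "numeric", colRange = "numeric"))

#' @rdname CellFrame-class
#' @param rowRange,colRange numeric length-2 inclusive bounds.
#' @export
CellFrame <- function(rowRange, colRange) {
  new("CellFrame", rowRange = as.numeric(rowRange),
      colRange = as.numeric(colRange))
}

## ---------------------------------------------------------------------------
## Synthetic scenes
## ---------------------------------------------------------------------------

#' Specification of one synthetic focal adhesion
#'
#' Geometry of an elongated two-channel intensity plateau: a dual-positive
#' core flanked, optionally, by a single-channel extension at the head
#' (distal) and/or tail (proximal) end. The head end is the axis end closer
#' to the cell frame, matching the orientation rule of the measurement.
#'
#' @slot centre numeric (row, col) in px.
#' @slot angle long-axis orientation, degrees in [0, 180).
#' @slot coreLength length of the dual-positive core stretch (px, >= 1).
#' @slot width full width at half maximum across the axis (px, >= 1).
#' @slot headChannel,tailChannel protruding channel at each end:
#'   "red", "green" or "none".
#' @slot headExtra,tailExtra protrusion length at each end (px >= 0); must be
#'   0 exactly when the corresponding channel is "none".
#' @slot peakRed,peakGreen plateau peak intensity per channel (arbitrary
#'   units in [0, 1]).
#' @export
setClass("FASpec",
  slots = c(centre = "numeric", angle = "numeric", coreLength = "numeric",
            width = "numeric", headChannel = "character",
            headExtra = "numeric", tailChannel = "character",
            tailExtra = "numeric", peakRed = "numeric",
            peakGreen = "numeric"))

setValidity("FASpec", function(object) {
  if (!object@headChannel %in% .CHANNELS_NONE ||
      !object@tailChannel %in% .CHANNELS_NONE)
    return("channels must be 'red', 'green' or 'none'")
  if ((object@headExtra == 0) != (object@headChannel == "none"))
    return("headExtra must be 0 exactly when headChannel is 'none'")
  if ((object@tailExtra == 0) != (object@tailChannel == "none"))
    return("tailExtra must be 0 exactly when tailChannel is 'none'")
  if (object@headExtra < 0 || object@tailExtra < 0)
    return("protrusion lengths must be >= 0")
  if (object@coreLength < 1) return("coreLength must be >= 1")
  if (object@width < 1) return("width must be >= 1")
  TRUE
})

#' @rdname FASpec-class
#' @param centre,angle,coreLength,width,headChannel,headExtra,tailChannel,tailExtra,peakRed,peakGreen
#'   see slot documentation.
#' @export
FASpec <- function(centre, angle, coreLength, width,
                   headChannel = "none", headExtra = 0,
                   tailChannel = "none", tailExtra = 0,
                   peakRed = 0.6, peakGreen = 0.6) {
  new("FASpec", centre = centre, angle = angle %% 180,
      coreLength = coreLength, width = width, headChannel = headChannel,
      headExtra = headExtra, tailChannel = tailChannel,
      tailExtra = tailExtra, peakRed = peakRed, peakGreen = peakGreen)
}

#' Noise model for synthetic scenes
#'
#' Emulates camera read noise, signal-dependent (shot-like) noise, and the
#' correlated reconstruction noise of structured-illumination data, in which
#' small clusters of low-intensity pixels ("holes") appear inside bright
#' patches.
#'
#' @slot gaussianSd additive read-noise SD (intensity units).
#' @slot shotScaling signal-dependent noise factor; per-pixel SD is
#'   \code{shotScaling * sqrt(intensity)}.
#' @slot speckleHoleRate expected number of low-intensity holes per bright
#'   patch.
#' @slot speckleHoleSize hole diameter (px).
#' @slot speckleHoleDepth fractional intensity drop at hole centres, in
#'   [0, 1].
#' @export
setClass("NoiseSpec",
  slots = c(gaussianSd = "numeric", shotScaling = "numeric",
            speckleHoleRate = "numeric", speckleHoleSize = "numeric",
            speckleHoleDepth = "numeric"))

setValidity("NoiseSpec", function(object) {
  v <- c(object@gaussianSd, object@shotScaling, object@speckleHoleRate,
         object@speckleHoleSize)
  if (any(v < 0)) return("all rates/SDs must be >= 0")
  if (object@speckleHoleDepth < 0 || object@speckleHoleDepth > 1)
    return("speckleHoleDepth must be in [0, 1]")
  TRUE
})

#' @rdname NoiseSpec-class
#' @param gaussianSd,shotScaling,speckleHoleRate,speckleHoleSize,speckleHoleDepth
#'   see slot documentation.
#' @export
NoiseSpec <- function(gaussianSd = 0.01, shotScaling = 0.05,
                      speckleHoleRate = 2, speckleHoleSize = 3,
                      speckleHoleDepth = 0.6) {
  new("NoiseSpec", gaussianSd = gaussianSd, shotScaling = shotScaling,
      speckleHoleRate = speckleHoleRate, speckleHoleSize = speckleHoleSize,
      speckleHoleDepth = speckleHoleDepth)
}

#' Specification of a full synthetic scene
#'
#' @slot imageShape integer c(rows, cols).
#' @slot pixelPitchNm pixel pitch (nm), default 40.
#' @slot faSpecs list of \linkS4class{FASpec}.
#' @slot cellPolygon m x 2 (row, col) vertices of the simulated cell outline.
#' @slot backgroundRed,backgroundGreen background level per channel.
#' @slot noise a \linkS4class{NoiseSpec}.
#' @slot seed integer RNG seed for the noise stage.
#' @export
setClass("SceneSpec",
  slots = c(imageShape = "integer", pixelPitchNm = "numeric",
            faSpecs = "list", cellPolygon = "matrix",
            backgroundRed = "numeric", backgroundGreen = "numeric",
            noise = "NoiseSpec", seed = "integer"))

setValidity("SceneSpec", function(object) {
  for (fa in object@faSpecs) {
    if (!is(fa, "FASpec")) return("faSpecs must contain FASpec objects")
    if (!pointInPolygon(fa@centre, object@cellPolygon))
      return("all FA centres must lie inside cellPolygon")
  }
  TRUE
})

#' @rdname SceneSpec-class
#' @param imageShape,pixelPitchNm,faSpecs,cellPolygon,backgroundRed,backgroundGreen,noise,seed
#'   see slot documentation.
#' @export
SceneSpec <- function(imageShape = c(512L, 512L), pixelPitchNm = 40,
                      faSpecs = list(), cellPolygon,
                      backgroundRed = 0.03, backgroundGreen = 0.03,
                      noise = NoiseSpec(), seed = 1L) {
  new("SceneSpec", imageShape = as.integer(imageShape),
      pixelPitchNm = pixelPitchNm, faSpecs = faSpecs,
      cellPolygon = cellPolygon, backgroundRed = backgroundRed,
      backgroundGreen = backgroundGreen, noise = noise,
      seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## Statistics containers
## ---------------------------------------------------------------------------

#' Signed protrusion lengths of a population of adhesions
#'
#' Per adhesion, the head and tail protrusion lengths carry the sign of the
#' protruding channel: green positive, red negative, none exactly zero.
#' This is the quantity histogrammed and tested.
#'
#' @slot head,tail numeric signed lengths (nm), one value per adhesion.
#' @slot label free-text population label.
#' @slot biasCorrected TRUE once the reference bias was subtracted.
#' @slot biasHead,biasTail the bias values (nm) that were subtracted.
#' @export
setClass("SignedProtrusionSet",
  slots = c(head = "numeric", tail = "numeric", label = "character",
            biasCorrected = "logical", biasHead = "numeric",
            biasTail = "numeric"))

setValidity("SignedProtrusionSet", function(object) {
  if (length(object@head) != length(object@tail))
    return("head and tail must have one value per adhesion")
  TRUE
})

#' @rdname SignedProtrusionSet-class
#' @param head,tail,label,biasCorrected,biasHead,biasTail see slots.
#' @export
SignedProtrusionSet <- function(head, tail, label = "",
                                biasCorrected = FALSE,
                                biasHead = 0, biasTail = 0) {
  new("SignedProtrusionSet", head = head, tail = tail, label = label,
      biasCorrected = biasCorrected, biasHead = biasHead,
      biasTail = biasTail)
}

#' Comparison of an experimental and a reference signed histogram
#'
#' @slot binEdges histogram bin edges (nm); 80 nm bins with the central bin
#'   centred at 0.
#' @slot countsExp,countsRef bin counts.
#' @slot medianExp median experimental signed value (nm).
#' @slot significant TRUE when the two-sided Mann-Whitney p is below alpha;
#'   the median is reported as a protrusion length only then.
#' @slot U,pValue Mann-Whitney statistic and two-sided p.
#' @slot nExp,nRef sample sizes.
#' @slot end "head" or "tail".
#' @slot alpha significance level used for the reporting gate.
#' @export
setClass("HistogramComparison",
  slots = c(binEdges = "numeric", countsExp = "integer",
            countsRef = "integer", medianExp = "numeric",
            significant = "logical", U = "numeric", pValue = "numeric",
            nExp = "integer", nRef = "integer", end = "character",
            alpha = "numeric"))

#' 2D head/tail difference histogram
#'
#' 80 x 80 nm binned relative-frequency grids for an experimental and a
#' reference population, and their difference in percentage points.
#'
#' @slot binEdges common bin edges (nm) for both axes.
#' @slot expPct,refPct relative frequency grids (percent; each sums to 100).
#'   Rows index head bins, columns tail bins.
#' @slot diffPp difference grid, percentage points (sums to 0).
#' @export
setClass("Diff2DHistogram",
  slots = c(binEdges = "numeric", expPct = "matrix", refPct = "matrix",
            diffPp = "matrix"))

## ---------------------------------------------------------------------------
## Edge motility
## ---------------------------------------------------------------------------

#' Membrane edge displacement map
#'
#' @slot coords n x 2 (row, col) ordered edge pixel chain at the later time
#'   point (closed contour).
#' @slot displacementNm signed, edge-smoothed displacement per edge pixel
#'   relative to the earlier time point (positive = protrusion).
#' @slot motionClass "moving" or "static" per edge pixel.
#' @slot pixelPitchNm pixel pitch (nm).
#' @export
setClass("EdgeMotionMap",
  slots = c(coords = "matrix", displacementNm = "numeric",
            motionClass = "character", pixelPitchNm = "numeric"))

#' Edge motility classification parameters
#'
#' @slot motionThresholdNm minimum |displacement| between the two time
#'   points for an edge pixel to count as moving (default 200 nm).
#' @slot nearEdgeThresholdNm maximum adhesion-to-edge distance for the
#'   adhesion to enter the stratified analysis (default 2000 nm).
#' @slot smoothingWindowPx moving-average window along the edge chain
#'   (default 15 px).
#' @export
setClass("MotilityParams",
  slots = c(motionThresholdNm = "numeric", nearEdgeThresholdNm = "numeric",
            smoothingWindowPx = "numeric"))

setValidity("MotilityParams", function(object) {
  if (object@motionThresholdNm <= 0 || object@nearEdgeThresholdNm <= 0 ||
      object@smoothingWindowPx <= 0)
    return("all thresholds must be > 0")
  TRUE
})

#' @rdname MotilityParams-class
#' @param motionThresholdNm,nearEdgeThresholdNm,smoothingWindowPx see slots.
#' @export
MotilityParams <- function(motionThresholdNm = 200,
                           nearEdgeThresholdNm = 2000,
                           smoothingWindowPx = 15) {
  new("MotilityParams", motionThresholdNm = motionThresholdNm,
      nearEdgeThresholdNm = nearEdgeThresholdNm,
      smoothingWindowPx = smoothingWindowPx)
}

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "ProjectedImagePair", function(object) {
  cat("ProjectedImagePair:", nrow(object@red), "x", ncol(object@red),
      "px,", object@pixelPitchNm, "nm/px\n")
  cat("  red  range:", signif(range(object@red), 4), "\n")
  cat("  green range:", signif(range(object@green), 4), "\n")
})

setMethod("show", "FARegion", function(object) {
  cat(sprintf("FARegion #%d: %d px, centroid (%.1f, %.1f)\n",
              object@id, object@area, object@centroid[1],
              object@centroid[2]))
})

setMethod("show", "AxisPath", function(object) {
  cat(sprintf("AxisPath: %d px, %.1f nm total, %s\n", nrow(object@coords),
              if (length(object@cumNm)) max(object@cumNm) else 0,
              if (object@oriented) "oriented (index 1 = head)"
              else "unoriented"))
})

setMethod("show", "SignedProtrusionSet", function(object) {
  cat(sprintf("SignedProtrusionSet '%s': %d adhesions%s\n", object@label,
              length(object@head),
              if (object@biasCorrected)
                sprintf(", bias-corrected (head %.1f, tail %.1f nm)",
                        object@biasHead, object@biasTail) else ""))
  cat(sprintf("  median head %+.1f nm, median tail %+.1f nm\n",
              median(object@head), median(object@tail)))
})

setMethod("show", "HistogramComparison", function(object) {
  cat(sprintf("HistogramComparison (%s): n=%d vs reference n=%d\n",
              object@end, object@nExp, object@nRef))
  cat(sprintf("  U = %.1f, two-sided p = %.4g\n", object@U, object@pValue))
  if (object@significant)
    cat(sprintf("  median protrusion length: %+.1f nm\n", object@medianExp))
  else
    cat("  not significantly different from reference\n")
})

## ---------------------------------------------------------------------------
## Accessors
## ---------------------------------------------------------------------------

#' @rdname ProjectedImagePair
#' @param object a ProjectedImagePair.
#' @export
setGeneric("redChannel", function(object) standardGeneric("redChannel"))
#' @rdname ProjectedImagePair
#' @export
setGeneric("greenChannel", function(object) standardGeneric("greenChannel"))
#' @rdname ProjectedImagePair
#' @export
setGeneric("pixelPitch", function(object) standardGeneric("pixelPitch"))

#' @rdname ProjectedImagePair
setMethod("redChannel", "ProjectedImagePair", function(object) object@red)
#' @rdname ProjectedImagePair
setMethod("greenChannel", "ProjectedImagePair", function(object) object@green)
#' @rdname ProjectedImagePair
setMethod("pixelPitch", "ProjectedImagePair",
          function(object) object@pixelPitchNm)
#' @rdname ProjectedImagePair
setMethod("pixelPitch", "ChannelStack", function(object) object@pixelPitchNm)
#' @rdname ProjectedImagePair
setMethod("pixelPitch", "AxisPath", function(object) object@pixelPitchNm)

#' Signed head/tail values of a protrusion set
#' @param object a \linkS4class{SignedProtrusionSet}.
#' @return numeric vector of signed nm values.
#' @export
setGeneric("signedHead", function(object) standardGeneric("signedHead"))
#' @rdname signedHead
#' @export
setGeneric("signedTail", function(object) standardGeneric("signedTail"))
#' @rdname signedHead
setMethod("signedHead", "SignedProtrusionSet", function(object) object@head)
#' @rdname signedHead
setMethod("signedTail", "SignedProtrusionSet", function(object) object@tail)

#' Path coordinates of an AxisPath
#' @param object an \linkS4class{AxisPath}.
#' @export
setGeneric("pathCoords", function(object) standardGeneric("pathCoords"))
#' @rdname pathCoords
setMethod("pathCoords", "AxisPath", function(object) object@coords)
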