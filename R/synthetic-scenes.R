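## Synthetic dual-channel scene generator with ground truth.
##
## Every downstream stage of the pipeline is validated against scenes built
## here: elongated adhesion-shaped plateaus (1-2 um long, 300-500 nm wide at
## 40 nm pitch) whose two channels are identical except for specified
## single-channel extensions at the head and/or tail end.

.faGeometry <- function(fa, frame) {
  th <- fa@angle * pi / 180
  dir <- c(sin(th), cos(th))          # (drow, dcol); angle from horizontal
  h <- fa@coreLength / 2
  endA <- fa@centre + h * dir
  endB <- fa@centre - h * dir
  dA <- distToFramePerimeter(endA, frame)
  dB <- distToFramePerimeter(endB, frame)
  headSign <- if (dA < dB) 1 else if (dB < dA) -1 else {
    # deterministic tie-break: head is the end with smaller row, then col
    if (endA[1] < endB[1] || (endA[1] == endB[1] && endA[2] <= endB[2]))
      1 else -1
  }
  headDir <- headSign * dir
  list(dir = dir, headDir = headDir, h = h,
       headEnd = fa@centre + h * headDir,
       tailEnd = fa@centre - h * headDir,
       headOuter = fa@centre + (h + fa@headExtra) * headDir,
       tailOuter = fa@centre - (h + fa@tailExtra) * headDir)
}

.polygonFrame <- function(poly) {
  CellFrame(range(poly[, 1]), range(poly[, 2]))
}

## render one FA into the two channel matrices (modified in place and
## returned); longitudinal end falloff is a half-Gaussian with SD 1 px,
## cross profile a Gaussian with the requested FWHM.
.renderFA <- function(red, green, fa, geom, id) {
  shape <- dim(red)
  sw <- fa@width / (2 * sqrt(2 * log(2)))   # FWHM -> SD
  margin <- ceiling(geom$h + max(fa@headExtra, fa@tailExtra) + 3 * sw + 4)
  r0 <- floor(fa@centre[1] - margin); r1 <- ceiling(fa@centre[1] + margin)
  c0 <- floor(fa@centre[2] - margin); c1 <- ceiling(fa@centre[2] + margin)
  outer <- rbind(geom$headOuter, geom$tailOuter)
  if (any(outer[, 1] < 2) || any(outer[, 1] > shape[1] - 1) ||
      any(outer[, 2] < 2) || any(outer[, 2] > shape[2] - 1))
    stop("FA ", id, " extends outside the image")
  r0 <- max(1, r0); r1 <- min(shape[1], r1)
  c0 <- max(1, c0); c1 <- min(shape[2], c1)
  rr <- r0:r1; cc <- c0:c1
  # u: signed position along headDir (positive toward the head),
  # v: transverse offset
  dR <- outer(rr - fa@centre[1], rep(1, length(cc)))
  dC <- outer(rep(1, length(rr)), cc - fa@centre[2])
  u <- dR * geom$headDir[1] + dC * geom$headDir[2]
  v <- -dR * geom$headDir[2] + dC * geom$headDir[1]
  cross <- exp(-v^2 / (2 * sw^2))
  longProfile <- function(uHead, uTail) {
    over <- pmax(u - uHead, 0) + pmax(-uTail - u, 0)
    exp(-over^2 / 2)          # half-Gaussian falloff, SD 1 px
  }
  for (ch in c("red", "green")) {
    uHead <- geom$h + if (fa@headChannel == ch) fa@headExtra else 0
    uTail <- geom$h + if (fa@tailChannel == ch) fa@tailExtra else 0
    contrib <- (if (ch == "red") fa@peakRed else fa@peakGreen) *
      longProfile(uHead, uTail) * cross
    if (ch == "red") red[rr, cc] <- red[rr, cc] + contrib
    else green[rr, cc] <- green[rr, cc] + contrib
  }
  list(red = red, green = green)
}

## ground-truth nm lengths follow the step-geometry rule along the
## rasterized true axis: a protrusion of k px spans the k outermost steps.
.faTruth <- function(fa, geom, id, pitch) {
  chain <- rasterizeLine8(geom$headOuter, geom$tailOuter)
  path <- AxisPath(chain, pixelPitchNm = pitch, oriented = TRUE)
  n <- nrow(chain)
  hk <- round(fa@headExtra); tk <- round(fa@tailExtra)
  headNm <- if (hk > 0) path@cumNm[min(hk + 1, n)] - path@cumNm[1] else 0
  tailNm <- if (tk > 0) path@cumNm[n] - path@cumNm[max(n - tk, 1)] else 0
  data.frame(id = id, centreRow = fa@centre[1], centreCol = fa@centre[2],
             angle = fa@angle, corePx = fa@coreLength,
             headChannel = fa@headChannel, headPx = fa@headExtra,
             headNm = headNm, tailChannel = fa@tailChannel,
             tailPx = fa@tailExtra, tailNm = tailNm,
             headRow = geom$headOuter[1], headCol = geom$headOuter[2],
             tailRow = geom$tailOuter[1], tailCol = geom$tailOuter[2],
             edgeClass = NA_character_, stringsAsFactors = FALSE)
}

#' Render a synthetic two-channel scene with ground truth
#'
#' Produces a noiseless image in which each adhesion is an anisotropic
#' plateau (half-Gaussian longitudinal end falloff with SD 1 px, Gaussian
#' cross profile) and the two channels are identical except for the
#' specified per-end single-channel extensions. Intensities are digitized
#' to a 16-bit grid, as camera data would be. Ground truth (channels,
#' protrusion lengths in px and nm via the step-geometry rule, true axis
#' endpoints) is recorded before any noise is applied.
#'
#' @param spec a \linkS4class{SceneSpec}.
#' @return list with elements \code{images} (a
#'   \linkS4class{ProjectedImagePair}) and \code{truth} (a data.frame, one
#'   row per adhesion).
#' @export
renderScene <- function(spec) {
  validObject(spec)
  shape <- spec@imageShape
  red <- matrix(spec@backgroundRed, shape[1], shape[2])
  green <- matrix(spec@backgroundGreen, shape[1], shape[2])
  frame <- .polygonFrame(spec@cellPolygon)
  truth <- list()
  for (i in seq_along(spec@faSpecs)) {
    fa <- spec@faSpecs[[i]]
    validObject(fa)
    geom <- .faGeometry(fa, frame)
    rendered <- .renderFA(red, green, fa, geom, i)
    red <- rendered$red; green <- rendered$green
    truth[[i]] <- .faTruth(fa, geom, i, spec@pixelPitchNm)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame()
  images <- ProjectedImagePair(quantize16(red), quantize16(green),
                               pixelPitchNm = spec@pixelPitchNm,
                               provenance = list(source = "synthetic"))
  list(images = images, truth = truth)
}

.addChannelNoise <- function(img, noise) {
  out <- img
  if (noise@gaussianSd > 0)
    out <- out + rnorm(length(img), 0, noise@gaussianSd)
  if (noise@shotScaling > 0)
    out <- out + rnorm(length(img)) * noise@shotScaling * sqrt(pmax(img, 0))
  if (noise@speckleHoleRate > 0 && noise@speckleHoleDepth > 0) {
    # holes only inside above-background regions
    bg <- median(img)
    mask <- img > bg + 0.15 * (max(img) - bg)
    if (any(mask)) {
      lab <- labelConnected8(mask)
      nPatch <- max(lab)
      nHoles <- rpois(1, noise@speckleHoleRate * nPatch)
      if (nHoles > 0) {
        idx <- which(mask)
        at <- idx[sample.int(length(idx), min(nHoles, length(idx)))]
        rs <- (at - 1) %% nrow(img) + 1
        cs <- (at - 1) %/% nrow(img) + 1
        hs <- noise@speckleHoleSize / (2 * sqrt(2 * log(2)))
        rad <- ceiling(noise@speckleHoleSize)
        for (k in seq_along(at)) {
          rr <- max(1, rs[k] - rad):min(nrow(img), rs[k] + rad)
          cc <- max(1, cs[k] - rad):min(ncol(img), cs[k] + rad)
          d2 <- outer((rr - rs[k])^2, (cc - cs[k])^2, "+")
          out[rr, cc] <- out[rr, cc] *
            (1 - noise@speckleHoleDepth * exp(-d2 / (2 * hs^2)))
        }
      }
    }
  }
  pmax(out, 0)
}

#' Add reconstruction-like noise to a two-channel image
#'
#' Applies, per channel and independently: additive Gaussian read noise,
#' signal-dependent shot-like noise, and "coloured" reconstruction noise in
#' the form of small low-intensity holes punched only inside bright
#' patches. Output is clipped at 0 and digitized to the same 16-bit grid as
#' \code{\link{renderScene}}. Fully reproducible for a fixed seed; a
#' \linkS4class{NoiseSpec} of all zeros returns the input unchanged.
#'
#' @param images a \linkS4class{ProjectedImagePair}.
#' @param noise a \linkS4class{NoiseSpec}.
#' @param seed integer seed.
#' @return a noisy \linkS4class{ProjectedImagePair}.
#' @export
addNoise <- function(images, noise, seed = 1L) {
  validObject(noise)
  if (noise@gaussianSd == 0 && noise@shotScaling == 0 &&
      (noise@speckleHoleRate == 0 || noise@speckleHoleDepth == 0))
    return(images)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  ProjectedImagePair(quantize16(.addChannelNoise(images@red, noise)),
                     quantize16(.addChannelNoise(images@green, noise)),
                     pixelPitchNm = images@pixelPitchNm,
                     provenance = c(images@provenance, list(noiseSeed = seed)))
}

#' Render a pair of time-lapse cell masks with programmed edge motion
#'
#' The cell outline at the first time point is the scene's polygon. Each
#' polygon edge segment can be displaced along its outward normal by a
#' programmed amount (nm; positive = protrusion, negative = retraction),
#' producing the outline at the second time point as a rectangular bump on
#' that segment while every other segment stays exactly in place.
#'
#' @param spec a \linkS4class{SceneSpec}.
#' @param edgeProgramNm numeric vector, one displacement (nm) per polygon
#'   segment (segment i joins vertex i to vertex i+1, wrapping).
#' @param nearEdgeThresholdNm adhesions farther than this from every segment
#'   are labelled "disregarded" in the returned ground truth.
#' @return list with \code{maskT0}, \code{maskT1} (0/1 integer matrices),
#'   \code{segmentClass} (per segment: "static", "moving-protruding" or
#'   "moving-retracting") and \code{faClasses} (data.frame: id, class,
#'   distanceNm, segment).
#' @export
renderTimelapseMasks <- function(spec, edgeProgramNm,
                                 nearEdgeThresholdNm = 2000) {
  poly <- spec@cellPolygon
  n <- nrow(poly)
  stopifnot(length(edgeProgramNm) == n)
  pitch <- spec@pixelPitchNm
  centroidP <- colMeans(poly)
  newPoly <- list()
  segClass <- character(n)
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1 else i + 1, ]
    d <- edgeProgramNm[i]
    segClass[i] <- if (d == 0) "static" else if (d > 0)
      "moving-protruding" else "moving-retracting"
    newPoly[[length(newPoly) + 1]] <- a
    if (d != 0) {
      seg <- b - a
      nrm <- c(-seg[2], seg[1]) / sqrt(sum(seg^2))
      mid <- (a + b) / 2
      if (sum(nrm * (mid - centroidP)) < 0) nrm <- -nrm
      shift <- nrm * d / pitch
      newPoly[[length(newPoly) + 1]] <- a + shift
      newPoly[[length(newPoly) + 1]] <- b + shift
    }
  }
  newPoly <- do.call(rbind, newPoly)
  if (polygonSelfIntersects(newPoly))
    stop("displaced cell outline self-intersects")
  maskT0 <- fillPolygon(poly, spec@imageShape)
  maskT1 <- fillPolygon(newPoly, spec@imageShape)
  faClasses <- NULL
  if (length(spec@faSpecs)) {
    rows <- lapply(seq_along(spec@faSpecs), function(k) {
      p <- spec@faSpecs[[k]]@centre
      dseg <- vapply(seq_len(n), function(i)
        pointSegmentDistance(p, poly[i, ], poly[if (i == n) 1 else i + 1, ]),
        numeric(1))
      i <- which.min(dseg)
      dnm <- dseg[i] * pitch
      cls <- if (dnm > nearEdgeThresholdNm) "disregarded" else
        if (segClass[i] == "static") "static" else "moving"
      data.frame(id = k, class = cls, distanceNm = dnm, segment = i)
    })
    faClasses <- do.call(rbind, rows)
  }
  list(maskT0 = maskT0, maskT1 = maskT1, segmentClass = segClass,
       faClasses = faClasses)
}

#' Match measured adhesions to scene ground truth by centroid proximity
#'
#' Each measurement row is paired with the nearest ground-truth adhesion
#' centre; rows farther than \code{maxDistPx} from every truth centre are
#' dropped (unmatched detections), as are truth entries claimed by a closer
#' measurement.
#'
#' @param measurements data.frame from \code{\link{measureScene}}.
#' @param truth ground-truth data.frame from \code{\link{renderScene}}.
#' @param maxDistPx maximum centroid distance for a match (px).
#' @return merged data.frame with measurement columns and truth columns
#'   prefixed \code{true}.
#' @export
matchGroundTruth <- function(measurements, truth, maxDistPx = 6) {
  if (!nrow(measurements) || !nrow(truth)) return(data.frame())
  rows <- list()
  for (i in seq_len(nrow(measurements))) {
    d <- sqrt((truth$centreRow - measurements$centroidRow[i])^2 +
              (truth$centreCol - measurements$centroidCol[i])^2)
    k <- which.min(d)
    if (d[k] > maxDistPx) next
    tr <- truth[k, c("id", "headChannel", "headPx", "headNm",
                     "tailChannel", "tailPx", "tailNm")]
    names(tr) <- paste0("true",
                        toupper(substring(names(tr), 1, 1)),
                        substring(names(tr), 2))
    rows[[length(rows) + 1]] <- cbind(measurements[i, ], tr,
                                      matchDistPx = d[k])
  }
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Draw a randomized default scene specification
#'
#' The defaults emulate the study conditions: 1024 x 1024 px at 40 nm
#' pitch, 20-60 adhesions per cell of total length 25-50 px (1-2 um) and
#' width 8-12 px FWHM (roughly 300-500 nm), oriented approximately radially
#' so the distal (head) end is unambiguous, inside an irregular convex cell
#' outline. Protrusion channels and lengths are drawn uniformly.
#'
#' @param nFAs number of adhesions; default drawn uniformly from 20-60.
#' @param imageShape integer c(rows, cols), default c(1024, 1024).
#' @param seed integer seed for the draw (also stored in the SceneSpec for
#'   the noise stage).
#' @param protrusionPxRange integer range of nonzero protrusion lengths.
#' @param noise a \linkS4class{NoiseSpec}.
#' @param pNone probability that an end has no protruding channel.
#' @return a \linkS4class{SceneSpec}.
#' @export
randomSceneSpec <- function(nFAs = NULL, imageShape = c(1024L, 1024L),
                            seed = 1L, protrusionPxRange = c(2L, 8L),
                            noise = NoiseSpec(), pNone = 0.25) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  if (is.null(nFAs)) nFAs <- sample(20:60, 1)
  ctr <- imageShape / 2
  R <- 0.44 * min(imageShape)
  phi <- seq(0, 2 * pi, length.out = 13)[-13]
  rad <- R * runif(12, 0.75, 1)
  poly <- cbind(ctr[1] + rad * sin(phi), ctr[2] + rad * cos(phi))
  centres <- matrix(numeric(0), 0, 2)
  axisPts <- matrix(numeric(0), 0, 2)  # sampled axis corridors of accepted FAs
  fas <- list()
  tries <- 0
  while (length(fas) < nFAs && tries < nFAs * 200) {
    tries <- tries + 1
    a <- runif(1, 0, 2 * pi)
    rho <- runif(1, 0.55, 0.88)
    # local polygon radius in direction a (approximate by nearest vertex)
    rloc <- rad[which.min(abs(((phi - a + pi) %% (2 * pi)) - pi))]
    p <- ctr + rho * rloc * c(sin(a), cos(a))
    if (!pointInPolygon(p, poly)) next
    if (nrow(centres) && min(sqrt(rowSums((t(t(centres) - p))^2))) < 34)
      next
    total <- runif(1, 25, 50)
    drawEnd <- function() {
      if (runif(1) < pNone) list(ch = "none", px = 0)
      else list(ch = sample(c("red", "green"), 1),
                px = sample(protrusionPxRange[1]:protrusionPxRange[2], 1))
    }
    hd <- drawEnd(); tl <- drawEnd()
    core <- max(12, total - hd$px - tl$px)
    ang <- (a * 180 / pi + runif(1, -15, 15)) %% 180  # roughly radial axis
    fa <- FASpec(centre = p, angle = ang, coreLength = core,
                 width = runif(1, 8, 12), headChannel = hd$ch,
                 headExtra = hd$px, tailChannel = tl$ch, tailExtra = tl$px,
                 peakRed = runif(1, 0.45, 0.8),
                 peakGreen = runif(1, 0.45, 0.8))
    # keep the whole FA (with margins) inside image and polygon
    geom <- .faGeometry(fa, .polygonFrame(poly))
    ends <- rbind(geom$headOuter, geom$tailOuter)
    if (any(ends < 12) || any(ends[, 1] > imageShape[1] - 12) ||
        any(ends[, 2] > imageShape[2] - 12)) next
    if (!pointInPolygon(geom$headOuter, poly) ||
        !pointInPolygon(geom$tailOuter, poly)) next
    # adhesions are distinct objects: reject candidates whose axis corridor
    # approaches another adhesion's axis (centre distance alone does not
    # prevent collinear overlap of elongated objects)
    tt <- seq(-1, 1, by = 0.1)
    cand <- cbind(geom$headOuter[1] * (1 + tt) / 2 +
                    geom$tailOuter[1] * (1 - tt) / 2,
                  geom$headOuter[2] * (1 + tt) / 2 +
                    geom$tailOuter[2] * (1 - tt) / 2)
    if (nrow(axisPts)) {
      dmin <- min(vapply(seq_len(nrow(cand)), function(i)
        min((axisPts[, 1] - cand[i, 1])^2 + (axisPts[, 2] - cand[i, 2])^2),
        numeric(1)))
      if (sqrt(dmin) < 22) next
    }
    centres <- rbind(centres, p)
    axisPts <- rbind(axisPts, cand)
    fas[[length(fas) + 1]] <- fa
  }
  SceneSpec(imageShape = imageShape, faSpecs = fas, cellPolygon = poly,
            noise = noise, seed = seed)
}
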