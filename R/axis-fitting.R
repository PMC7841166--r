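## Fitting, refining, terminating and orienting the line along each
## adhesion's longitudinal axis.

.angleToDir <- function(angleDeg) {
  th <- angleDeg * pi / 180
  c(sin(th), cos(th))   # (drow, dcol); angle from the image horizontal axis
}

.dirToAngle <- function(dir) {
  (atan2(dir[1], dir[2]) * 180 / pi) %% 180
}

#' Moment-based (fit-ellipse) axis of a region
#'
#' Intensity-weighted centroid and major-axis angle from the second-order
#' moments of the region pixels, as the ellipse-fit of the original
#' workflow provides. Nearly isotropic regions (eccentricity < 0.05) are
#' flagged and fall back to the unweighted bounding-box diagonal.
#'
#' @param region a \linkS4class{FARegion}.
#' @param img intensity matrix used for weighting (the green channel in the
#'   standard chain).
#' @return an \linkS4class{AxisLine} (unrefined).
#' @export
momentAxis <- function(region, img) {
  px <- region@pixels
  w <- img[px]
  if (sum(w) <= 0) w <- rep(1, nrow(px))
  w <- w / sum(w)
  cr <- sum(w * px[, 1]); cc <- sum(w * px[, 2])
  y <- px[, 1] - cr; x <- px[, 2] - cc
  mxx <- sum(w * x^2); myy <- sum(w * y^2); mxy <- sum(w * x * y)
  tr <- mxx + myy
  det2 <- sqrt(((mxx - myy) / 2)^2 + mxy^2)
  l1 <- tr / 2 + det2; l2 <- max(tr / 2 - det2, 0)
  ecc <- if (l1 > 0) sqrt(1 - l2 / l1) else 0
  isotropic <- ecc < 0.05
  if (isotropic) {
    bb <- region@bbox
    ang <- .dirToAngle(c(bb[2] - bb[1], bb[4] - bb[3]))
  } else {
    ang <- (0.5 * atan2(2 * mxy, mxx - myy) * 180 / pi) %% 180
  }
  AxisLine(centre = c(cr, cc), angle = ang,
           majorAxisPx = 4 * sqrt(l1), minorAxisPx = max(4 * sqrt(l2), 2),
           isotropic = isotropic)
}

## least-squares 1D Gaussian (baseline + amplitude) fit; returns the centre
## or NA when the fit fails/diverges
.fitGaussianCentre <- function(t, y, sInit) {
  if (all(y == y[1])) return(NA_real_)
  st <- list(b = min(y), A = max(y) - min(y), c0 = t[which.max(y)],
             s0 = sInit)
  fit <- try(suppressWarnings(minpack.lm::nlsLM(
    y ~ b + A * exp(-(t - c0)^2 / (2 * s0^2)), start = st,
    control = minpack.lm::nls.lm.control(maxiter = 60))), silent = TRUE)
  if (inherits(fit, "try-error")) return(NA_real_)
  cf <- stats::coef(fit)
  if (cf[["A"]] <= 0 || abs(cf[["s0"]]) < 0.3) return(NA_real_)
  cf[["c0"]]
}

#' Refine an axis by perpendicular-Gaussian ridge fitting
#'
#' At 1 px spacing along the initial axis, a 1D Gaussian (baseline plus
#' amplitude) is least-squares fitted to the perpendicular green-channel
#' profile (profile length 3x the region minor axis, bilinear sampling).
#' Fitted centres with amplitude above baseline and centre shift below half
#' the minor axis are kept; a total-least-squares line through the kept
#' centres replaces the initial axis. With fewer than 3 usable centres the
#' initial axis is retained and flagged.
#'
#' @param region a \linkS4class{FARegion}.
#' @param green green-channel intensity matrix.
#' @param axis initial \linkS4class{AxisLine} from \code{\link{momentAxis}}.
#' @return a refined \linkS4class{AxisLine} (slot \code{refined} records
#'   whether refinement succeeded).
#' @export
refineAxisByRidge <- function(region, green, axis) {
  dir <- .angleToDir(axis@angle)
  perp <- c(-dir[2], dir[1])
  px <- region@pixels
  u <- (px[, 1] - axis@centre[1]) * dir[1] +
       (px[, 2] - axis@centre[2]) * dir[2]
  useq <- seq(floor(min(u)), ceiling(max(u)), by = 1)
  half <- max(3, 1.5 * axis@minorAxisPx)
  tseq <- seq(-half, half, by = 1)
  kept <- matrix(numeric(0), 0, 2)
  for (ui in useq) {
    base <- axis@centre + ui * dir
    prof <- bilinearSample(green, base[1] + tseq * perp[1],
                           base[2] + tseq * perp[2])
    c0 <- .fitGaussianCentre(tseq, prof, sInit = axis@minorAxisPx / 4)
    if (is.na(c0) || abs(c0) >= axis@minorAxisPx / 2) next
    kept <- rbind(kept, base + c0 * perp)
  }
  if (nrow(kept) < 3) {
    axis@refined <- FALSE
    return(axis)
  }
  ctr <- colMeans(kept)
  ev <- eigen(stats::cov(kept))$vectors[, 1]
  AxisLine(centre = ctr, angle = .dirToAngle(ev),
           majorAxisPx = axis@majorAxisPx, minorAxisPx = axis@minorAxisPx,
           ridgePoints = kept, refined = TRUE, isotropic = axis@isotropic)
}

#' Terminate an axis line where both channels fade out
#'
#' The axis is rasterized to an 8-connected pixel chain extending beyond
#' the region in both directions (up to \code{maxExtendPx}). For each
#' channel the maximum along the chain of the 3x3-box mean intensity is
#' taken; walking outward from the centre, the chain is cut at the last
#' pixel before the box means of \emph{both} channels fall below
#' \code{terminationFrac} (30 percent) of their respective maxima. Both ends
#' are processed independently.
#'
#' @param axis a (refined) \linkS4class{AxisLine}.
#' @param images a \linkS4class{ProjectedImagePair}.
#' @param region the \linkS4class{FARegion} the axis belongs to.
#' @param terminationFrac intensity fraction for termination (default 0.30).
#' @param maxExtendPx how far beyond the region the chain may extend.
#' @param minPathPx paths shorter than this are discarded (returns NULL).
#' @return an unoriented \linkS4class{AxisPath}, or \code{NULL} when the
#'   terminated path is shorter than \code{minPathPx}.
#' @export
terminateAxis <- function(axis, images, region, terminationFrac = 0.30,
                          maxExtendPx = 50, minPathPx = 3) {
  dir <- .angleToDir(axis@angle)
  px <- region@pixels
  u <- (px[, 1] - axis@centre[1]) * dir[1] +
       (px[, 2] - axis@centre[2]) * dir[2]
  tlo <- min(u) - maxExtendPx
  thi <- max(u) + maxExtendPx
  nr <- nrow(images@red); nc <- ncol(images@red)
  clampT <- function(t) {
    # shrink extension so the endpoint stays inside the image
    p <- axis@centre + t * dir
    while ((p[1] < 1 || p[1] > nr || p[2] < 1 || p[2] > nc) &&
           abs(t) > 1) {
      t <- t - sign(t)
      p <- axis@centre + t * dir
    }
    t
  }
  tlo <- clampT(tlo); thi <- clampT(thi)
  chain <- rasterizeLine8(axis@centre + tlo * dir, axis@centre + thi * dir)
  inside <- chain[, 1] >= 1 & chain[, 1] <= nr &
            chain[, 2] >= 1 & chain[, 2] <= nc
  chain <- chain[inside, , drop = FALSE]
  n <- nrow(chain)
  if (n < minPathPx) return(NULL)
  bmR <- vapply(seq_len(n), function(i)
    boxMean3(images@red, chain[i, 1], chain[i, 2]), numeric(1))
  bmG <- vapply(seq_len(n), function(i)
    boxMean3(images@green, chain[i, 1], chain[i, 2]), numeric(1))
  thrR <- terminationFrac * max(bmR)
  thrG <- terminationFrac * max(bmG)
  d2 <- rowSums((sweep(chain, 2, axis@centre))^2)
  i0 <- which.min(d2)
  below <- bmR < thrR & bmG < thrG
  # forward end
  fw <- which(below & seq_len(n) > i0)
  hiCut <- if (length(fw)) min(fw) - 1L else n
  bw <- which(below & seq_len(n) < i0)
  loCut <- if (length(bw)) max(bw) + 1L else 1L
  if (hiCut - loCut + 1 < minPathPx) return(NULL)
  AxisPath(chain[loCut:hiCut, , drop = FALSE],
           pixelPitchNm = images@pixelPitchNm, oriented = FALSE)
}

#' Orient a path so index 1 is the head (distal) end
#'
#' The head is the path end whose minimum distance to the perimeter of the
#' rectangle drawn around the cell is smaller; exact ties break toward the
#' end with the smaller row, then the smaller column.
#'
#' @param path an \linkS4class{AxisPath}.
#' @param cellFrame a \linkS4class{CellFrame} enclosing the path.
#' @return the oriented \linkS4class{AxisPath}.
#' @export
orientHeadTail <- function(path, cellFrame) {
  co <- path@coords
  n <- nrow(co)
  dFirst <- distToFramePerimeter(co[1, ], cellFrame)
  dLast <- distToFramePerimeter(co[n, ], cellFrame)
  headFirst <- if (dFirst < dLast) TRUE else if (dLast < dFirst) FALSE else {
    a <- co[1, ]; b <- co[n, ]
    a[1] < b[1] || (a[1] == b[1] && a[2] <= b[2])
  }
  co2 <- if (headFirst) co else co[n:1, , drop = FALSE]
  AxisPath(co2, pixelPitchNm = path@pixelPitchNm, oriented = TRUE)
}

#' Compute the rectangle drawn around the cell
#'
#' Bounding rectangle of the cell mask. When no mask is supplied, the mask
#' is computed by Otsu-thresholding the heavily blurred (sigma 20 px) sum
#' of the two channels.
#'
#' @param images a \linkS4class{ProjectedImagePair}.
#' @param mask optional binary cell mask; overrides the automatic rule.
#' @param sigma blur SD (px) for the automatic mask.
#' @return a \linkS4class{CellFrame}.
#' @export
computeCellFrame <- function(images, mask = NULL, sigma = 20) {
  if (is.null(mask)) {
    s <- images@red + images@green
    b <- as.matrix(EBImage::gblur(s, sigma = sigma))
    mask <- otsuBinarize(b)
  }
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  if (!length(rows)) stop("empty cell mask")
  CellFrame(range(rows), range(cols))
}
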