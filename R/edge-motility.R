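## Classification of adhesions by the motility of the nearest ventral
## membrane edge, from two time-point cell masks.

## boundary pixels: foreground with at least one 4-neighbour of background
.maskBoundary <- function(mask) {
  m <- mask > 0
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  nb <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
        pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  m & !nb
}

## circular moving average
.circularSmooth <- function(x, window) {
  if (window <= 1 || length(x) < window) return(x)
  h <- floor(window / 2)
  xx <- c(x[(length(x) - h + 1):length(x)], x, x[1:h])
  as.numeric(stats::filter(xx, rep(1 / (2 * h + 1), 2 * h + 1)))[
    (h + 1):(h + length(x))]
}

#' Signed edge displacement between two time points
#'
#' For each edge pixel of the later mask, the displacement is the distance
#' to the nearest edge pixel of the earlier mask, signed positive when the
#' pixel lies outside the earlier cell (protrusion) and negative when
#' inside (retraction), converted to nm and smoothed along the ordered edge
#' chain with a circular moving average. Pixels move or are static
#' according to \code{motionThresholdNm}.
#'
#' @param maskT0,maskT1 binary cell masks (same shape, one cell each).
#' @param params a \linkS4class{MotilityParams}.
#' @param pixelPitchNm pixel pitch in nm (default 40).
#' @return an \linkS4class{EdgeMotionMap}.
#' @export
edgeDisplacement <- function(maskT0, maskT1, params = MotilityParams(),
                             pixelPitchNm = 40) {
  if (!any(maskT0 > 0) || !any(maskT1 > 0)) stop("empty cell mask")
  stopifnot(all(dim(maskT0) == dim(maskT1)))
  edge0 <- .maskBoundary(maskT0)
  # distance of every pixel to the nearest t0 edge pixel
  dmap <- as.matrix(EBImage::distmap(matrix(as.numeric(!edge0),
                                            nrow(edge0))))
  oc <- EBImage::ocontour(EBImage::Image(matrix(as.numeric(maskT1 > 0),
                                                nrow(maskT1))))[[1]]
  chain <- cbind(row = oc[, 1] + 1L, col = oc[, 2] + 1L)
  d <- dmap[chain]
  sgn <- ifelse(maskT0[chain] > 0, -1, 1)
  # pixels on the old edge itself have zero displacement
  sgn[edge0[chain]] <- 0
  dispNm <- .circularSmooth(sgn * d * pixelPitchNm,
                            params@smoothingWindowPx)
  cls <- ifelse(abs(dispNm) >= params@motionThresholdNm, "moving",
                "static")
  new("EdgeMotionMap", coords = chain, displacementNm = dispNm,
      motionClass = cls, pixelPitchNm = pixelPitchNm)
}

#' Classify one adhesion by its nearest membrane edge
#'
#' Adhesions farther from the edge than \code{nearEdgeThresholdNm} are
#' disregarded (inward cellular position); otherwise the majority motion
#' class of the edge pixels within the smoothing window around the nearest
#' edge pixel is returned.
#'
#' @param centroid numeric (row, col) adhesion centroid (px).
#' @param motionMap an \linkS4class{EdgeMotionMap}.
#' @param params a \linkS4class{MotilityParams}.
#' @return "moving", "static" or "disregarded".
#' @export
classifyFAEdge <- function(centroid, motionMap,
                           params = MotilityParams()) {
  co <- motionMap@coords
  d2 <- (co[, 1] - centroid[1])^2 + (co[, 2] - centroid[2])^2
  i <- which.min(d2)
  if (sqrt(d2[i]) * motionMap@pixelPitchNm > params@nearEdgeThresholdNm)
    return("disregarded")
  n <- nrow(co)
  h <- floor(params@smoothingWindowPx / 2)
  idx <- ((i - h - 1):(i + h - 1)) %% n + 1
  cls <- motionMap@motionClass[idx]
  names(which.max(table(cls)))
}

#' Append edge-motility classes to a measurement table
#'
#' @param measurements data.frame from \code{\link{measureScene}}.
#' @param motionMap an \linkS4class{EdgeMotionMap}.
#' @param params a \linkS4class{MotilityParams}.
#' @return the measurements with an added \code{edgeClass} column.
#' @export
classifyMeasurements <- function(measurements, motionMap,
                                 params = MotilityParams()) {
  measurements$edgeClass <- vapply(seq_len(nrow(measurements)),
    function(i) classifyFAEdge(c(measurements$centroidRow[i],
                                 measurements$centroidCol[i]),
                               motionMap, params), character(1))
  measurements
}
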