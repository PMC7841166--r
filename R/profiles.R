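## Core measurement: dual-channel intensity profiles along the oriented
## axis path, gap-tolerant run detection, and head/tail protrusion lengths
## in nm via the pixel step-geometry rule.

#' Edge-truncated running median
#'
#' Median filter whose window is truncated (not reflected) at the profile
#' ends, so the first and last positions use windows of size 3 and 4.
#'
#' @param x numeric vector.
#' @param window odd window size, default 5.
#' @return filtered numeric vector of the same length.
#' @export
medianFilterProfile <- function(x, window = 5) {
  n <- length(x)
  h <- window %/% 2
  vapply(seq_len(n), function(i)
    median(x[max(1, i - h):min(n, i + h)]), numeric(1))
}

#' Extract raw and median-filtered channel profiles along a path
#'
#' @param path an oriented \linkS4class{AxisPath}.
#' @param images a \linkS4class{ProjectedImagePair}.
#' @param medianWindow window of the median filter (default 5 px).
#' @return data.frame with columns rawRed, rawGreen, filtRed, filtGreen,
#'   one row per path pixel (row 1 = head end).
#' @export
extractProfiles <- function(path, images, medianWindow = 5) {
  co <- path@coords
  rawRed <- images@red[co]
  rawGreen <- images@green[co]
  data.frame(rawRed = rawRed, rawGreen = rawGreen,
             filtRed = medianFilterProfile(rawRed, medianWindow),
             filtGreen = medianFilterProfile(rawGreen, medianWindow))
}

#' Mark profile positions positive per channel
#'
#' A position is positive for a channel when its median-filtered intensity
#' is at least \code{thresholdFrac} (40 percent) of the maximum of that
#' channel's filtered profile. Thresholds are computed per adhesion and per
#' channel, so the marking is invariant to rescaling either channel.
#'
#' @param profiles data.frame from \code{\link{extractProfiles}}.
#' @param thresholdFrac fraction of the filtered maximum (default 0.40).
#' @return list with logical vectors \code{red} and \code{green} and a
#'   character vector \code{qc} of quality flags (flags any all-zero
#'   channel, which yields an all-negative marking).
#' @export
markPositive <- function(profiles, thresholdFrac = 0.40) {
  qc <- character(0)
  markOne <- function(v, nm) {
    mx <- max(v)
    if (mx <= 0) {
      qc <<- c(qc, paste0("zero_channel_", nm))
      return(rep(FALSE, length(v)))
    }
    v >= thresholdFrac * mx
  }
  list(red = markOne(profiles$filtRed, "red"),
       green = markOne(profiles$filtGreen, "green"), qc = qc)
}

#' Longest gap-tolerant dual-positive stretch
#'
#' Finds the longest interval whose two endpoints are positive in both
#' channels and inside which every maximal run of not-both-positive
#' positions is at most \code{maxGap} (4 px, i.e. 160 nm at 40 nm pitch)
#' long. Length is counted in pixels; ties break toward the head (lower
#' index).
#'
#' @param posRed,posGreen logical vectors of equal length.
#' @param maxGap maximum tolerated gap (px), default 4.
#' @return integer c(start, end) path indices (inclusive), or
#'   \code{integer(0)} when no position is positive in both channels.
#' @export
findMainStretch <- function(posRed, posGreen, maxGap = 4) {
  stopifnot(length(posRed) == length(posGreen))
  both <- which(posRed & posGreen)
  if (!length(both)) return(integer(0))
  breaks <- which(diff(both) > maxGap + 1L)
  starts <- both[c(1L, breaks + 1L)]
  ends <- both[c(breaks, length(both))]
  len <- ends - starts + 1L
  k <- which.max(len)          # first maximum = nearest the head
  unname(c(starts[k], ends[k]))
}

#' Path length of a contiguous chain segment in nm
#'
#' Sum over steps of the straight (one pixel pitch, 40 nm) or diagonal
#' (sqrt(2) pitch, sqrt(3200) which is about 57 nm) step length, scaled
#' proportionally when the pitch differs from 40 nm.
#'
#' @param path an \linkS4class{AxisPath}.
#' @param from,to path indices delimiting the segment (order-free).
#' @return distance in nm (0 for an empty or single-pixel segment).
#' @export
pathLengthNm <- function(path, from, to) {
  if (length(from) == 0 || length(to) == 0) return(0)
  abs(path@cumNm[to] - path@cumNm[from])
}

#' Straight/diagonal step lengths in nm
#'
#' @param diagonal logical vector of step flags.
#' @param pixelPitchNm pixel pitch, default 40 nm.
#' @return total nm over the steps.
#' @export
stepLengthNm <- function(diagonal, pixelPitchNm = 40) {
  sum(ifelse(diagonal, sqrt(2), 1) * pixelPitchNm)
}

#' Measure the protruding channel and length at one end of the main stretch
#'
#' The pixel just outside the main stretch at the given end is inspected.
#' Negative for both channels: no protrusion (length exactly 0). Positive
#' for exactly one channel: that channel's gap-tolerant consecutive
#' positive run outward from the boundary is found, and the protrusion
#' length is the nm path distance from the last main-stretch pixel to the
#' outermost positive pixel of the run. Positive for both (possible when an
#' internal gap capped the stretch): the stretch is first extended over the
#' adjoining both-positive pixels and the rule is re-applied.
#'
#' @param posRed,posGreen logical positivity vectors.
#' @param interval integer c(start, end) from \code{\link{findMainStretch}}.
#' @param end "head" (toward index 1) or "tail".
#' @param path the oriented \linkS4class{AxisPath} (for nm distances).
#' @param maxGap maximum tolerated gap in the protruding run (default 4).
#' @return list(channel = "red"/"green"/"none", nm = length,
#'   px = number of positive pixels in the run,
#'   boundary = possibly extended stretch boundary index).
#' @export
measureProtrusionAtEnd <- function(posRed, posGreen, interval,
                                   end = c("head", "tail"), path,
                                   maxGap = 4) {
  end <- match.arg(end)
  stopifnot(length(interval) == 2)
  n <- length(posRed)
  stepDir <- if (end == "head") -1L else 1L
  boundary <- if (end == "head") interval[1] else interval[2]
  both <- posRed & posGreen
  j <- boundary + stepDir
  while (j >= 1 && j <= n && both[j]) {   # absorb adjoining both-positive
    boundary <- j
    j <- j + stepDir
  }
  none <- list(channel = "none", nm = 0, px = 0L, boundary = boundary)
  if (j < 1 || j > n) return(none)
  if (!posRed[j] && !posGreen[j]) return(none)
  channel <- if (posRed[j]) "red" else "green"
  pos <- if (channel == "red") posRed else posGreen
  outermost <- j
  gap <- 0L
  npos <- 1L
  k <- j + stepDir
  while (k >= 1 && k <= n) {
    if (pos[k]) {
      outermost <- k
      npos <- npos + 1L
      gap <- 0L
    } else {
      gap <- gap + 1L
      if (gap > maxGap) break
    }
    k <- k + stepDir
  }
  list(channel = channel, nm = pathLengthNm(path, boundary, outermost),
       px = npos, boundary = boundary)
}

#' Measure one adhesion end to end
#'
#' Chains the full per-adhesion measurement: moment axis, ridge refinement,
#' 30-percent termination, head/tail orientation against the cell frame,
#' profile extraction with the window-5 median filter, 40-percent
#' positivity marking, gap-tolerant main-stretch detection, and protrusion
#' measurement at both ends. Every fallback taken is recorded in the
#' \code{qc} field; discarded adhesions yield a row with
#' \code{discarded = TRUE} and no lengths.
#'
#' @param images a \linkS4class{ProjectedImagePair}.
#' @param region a \linkS4class{FARegion}.
#' @param cellFrame a \linkS4class{CellFrame}.
#' @param params named list of tunables; recognised entries (with defaults)
#'   are thresholdFrac (0.40), maxGap (4), terminationFrac (0.30),
#'   medianWindow (5), maxExtendPx (50), minPathPx (3).
#' @param cellId identifier copied into the output row.
#' @return one-row data.frame: faId, cellId, headChannel, headNm, headPx,
#'   tailChannel, tailNm, tailPx, mainStretchPx, mainStretchNm,
#'   axisAngle, centroidRow, centroidCol, qc, discarded.
#' @export
measureFA <- function(images, region, cellFrame, params = list(),
                      cellId = 1L) {
  p <- modifyList(list(thresholdFrac = 0.40, maxGap = 4,
                       terminationFrac = 0.30, medianWindow = 5,
                       maxExtendPx = 50, minPathPx = 3), params)
  qc <- character(0)
  rowOut <- function(discarded, head = NULL, tail = NULL, ms = NULL,
                     angle = NA_real_) {
    data.frame(
      faId = region@id, cellId = cellId,
      headChannel = if (is.null(head)) NA_character_ else head$channel,
      headNm = if (is.null(head)) NA_real_ else head$nm,
      headPx = if (is.null(head)) NA_integer_ else head$px,
      tailChannel = if (is.null(tail)) NA_character_ else tail$channel,
      tailNm = if (is.null(tail)) NA_real_ else tail$nm,
      tailPx = if (is.null(tail)) NA_integer_ else tail$px,
      mainStretchPx = if (is.null(ms)) NA_integer_ else
        ms[2] - ms[1] + 1L,
      mainStretchNm = if (is.null(ms)) NA_real_ else msNm,
      axisAngle = angle,
      centroidRow = region@centroid[1], centroidCol = region@centroid[2],
      qc = paste(qc, collapse = ";"), discarded = discarded,
      stringsAsFactors = FALSE)
  }
  axis0 <- momentAxis(region, images@green)
  if (axis0@isotropic) qc <- c(qc, "isotropic")
  axis <- refineAxisByRidge(region, images@green, axis0)
  if (!axis@refined) qc <- c(qc, "axis_fallback")
  path <- terminateAxis(axis, images, region,
                        terminationFrac = p$terminationFrac,
                        maxExtendPx = p$maxExtendPx,
                        minPathPx = p$minPathPx)
  if (is.null(path)) {
    qc <- c(qc, "discarded_short_path")
    return(rowOut(TRUE, angle = axis@angle))
  }
  path <- orientHeadTail(path, cellFrame)
  prof <- extractProfiles(path, images, medianWindow = p$medianWindow)
  pos <- markPositive(prof, thresholdFrac = p$thresholdFrac)
  qc <- c(qc, pos$qc)
  ms <- findMainStretch(pos$red, pos$green, maxGap = p$maxGap)
  if (!length(ms)) {
    qc <- c(qc, "no_main_stretch")
    return(rowOut(TRUE, angle = axis@angle))
  }
  msNm <- pathLengthNm(path, ms[1], ms[2])
  head <- measureProtrusionAtEnd(pos$red, pos$green, ms, "head", path,
                                 maxGap = p$maxGap)
  tail <- measureProtrusionAtEnd(pos$red, pos$green, ms, "tail", path,
                                 maxGap = p$maxGap)
  rowOut(FALSE, head, tail, ms, axis@angle)
}

#' Measure every region of a scene
#'
#' @param images a \linkS4class{ProjectedImagePair}.
#' @param regions list of \linkS4class{FARegion}.
#' @param cellFrame a \linkS4class{CellFrame}; computed automatically when
#'   NULL.
#' @param params tunables, see \code{\link{measureFA}}.
#' @param cellId identifier for all rows.
#' @return data.frame with one row per region.
#' @export
measureScene <- function(images, regions, cellFrame = NULL, params = list(),
                         cellId = 1L) {
  if (is.null(cellFrame)) cellFrame <- computeCellFrame(images)
  if (!length(regions))
    return(data.frame())
  do.call(rbind, lapply(regions, function(rg)
    measureFA(images, rg, cellFrame, params, cellId)))
}
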