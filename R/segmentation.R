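## Candidate adhesion detection: band-pass filtering, automatic
## thresholding, connected components, and declarative region edits
## replacing the interactive outline corrections of the original workflow.

#' Difference-of-Gaussians band-pass filter
#'
#' The image blurred with the high sigma is subtracted from the image
#' blurred with the low sigma, enhancing structures at the adhesion scale.
#' The response may be negative.
#'
#' @param img numeric matrix.
#' @param sigmaLow,sigmaHigh Gaussian SDs in px, sigmaHigh > sigmaLow.
#' @return numeric matrix of band-pass response.
#' @export
dogFilter <- function(img, sigmaLow = 1, sigmaHigh = 5) {
  if (sigmaHigh <= sigmaLow) stop("need sigmaHigh > sigmaLow")
  blur <- function(s) {
    # kernel must fit inside the image
    rad <- min(2 * ceiling(3 * s) + 1, min(dim(img)))
    if (rad %% 2 == 0) rad <- rad - 1
    as.matrix(EBImage::gblur(img, sigma = s, radius = rad))
  }
  blur(sigmaLow) - blur(sigmaHigh)
}

#' Otsu threshold with dark-background convention
#'
#' The threshold is computed on a 256-bin histogram spanning the image
#' range; foreground is strictly above the threshold. Because the binning
#' is taken over the image's own range, the mask is invariant to affine
#' intensity rescaling.
#'
#' @param img numeric matrix with at least two distinct values.
#' @return logical matrix (TRUE = foreground).
#' @export
otsuBinarize <- function(img) {
  rng <- range(img)
  if (diff(rng) == 0)
    stop("constant image: Otsu threshold is undefined")
  xn <- (img - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(xn), range = c(0, 1), levels = 256)
  xn > thr
}

#' 8-connected labeling of a binary mask
#'
#' EBImage's component labeling is 4-connected; diagonally adjacent labels
#' are merged afterwards with a union-find pass so that components are
#' 8-connected, as required for diagonal pixel chains.
#'
#' @param mask logical or 0/1 matrix.
#' @return integer label matrix (0 = background).
#' @export
labelConnected8 <- function(mask) {
  m <- matrix(as.numeric(mask > 0), nrow(mask))
  lab <- as.matrix(EBImage::bwlabel(m))
  nl <- max(lab)
  if (nl == 0) return(matrix(0L, nrow(m), ncol(m)))
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs (down-right and down-left shifts)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]
  keep <- a > 0 & b > 0 & a != b
  if (any(keep)) for (k in which(keep)) union(a[k], b[k])
  a <- lab[-nr, -1]; b <- lab[-1, -nc]
  keep <- a > 0 & b > 0 & a != b
  if (any(keep)) for (k in which(keep)) union(a[k], b[k])
  roots <- vapply(seq_len(nl), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  matrix(as.integer(out), nr, nc)
}

#' Extract area-filtered adhesion regions from a binary mask
#'
#' 8-connected components are filtered by area and numbered
#' deterministically by the top row, then left column, of their bounding
#' boxes.
#'
#' @param mask logical matrix.
#' @param params a \linkS4class{SegmentationParams}.
#' @return list of \linkS4class{FARegion} (possibly empty).
#' @export
extractFARegions <- function(mask, params = SegmentationParams()) {
  lab <- labelConnected8(mask)
  nl <- max(lab)
  if (nl == 0) return(list())
  idx <- which(lab > 0)
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  labs <- lab[idx]
  regs <- list()
  for (l in seq_len(nl)) {
    sel <- labs == l
    area <- sum(sel)
    if (area < params@minArea || area > params@maxArea) next
    regs[[length(regs) + 1]] <- cbind(rows[sel], cols[sel])
  }
  .orderAndNumber(regs)
}

## deterministic numbering by bounding-box (top row, left col)
.orderAndNumber <- function(pixelSets) {
  if (!length(pixelSets)) return(list())
  key <- t(vapply(pixelSets, function(px) c(min(px[, 1]), min(px[, 2])),
                  numeric(2)))
  ord <- order(key[, 1], key[, 2])
  lapply(seq_along(ord), function(i) FARegion(i, pixelSets[[ord[i]]]))
}

#' Apply a declarative region-edits file
#'
#' A plain-text CSV replaces the interactive outline corrections: each row
#' is an operation \code{delete} (remove a region) or \code{split} (cut a
#' region along a polyline; the line pixels are removed and the remaining
#' parts become separate regions). After all edits, regions are renumbered
#' deterministically.
#'
#' Format: columns \code{op}, \code{id}, \code{coords}; \code{coords} is a
#' semicolon-separated list of \code{row col} pairs (empty for deletes).
#'
#' @param regions list of \linkS4class{FARegion}.
#' @param editsFile path to the edits CSV; \code{NULL} or a nonexistent
#'   file leaves regions unchanged.
#' @return edited, renumbered list of \linkS4class{FARegion}.
#' @export
applyRoiEdits <- function(regions, editsFile = NULL) {
  if (is.null(editsFile) || !file.exists(editsFile)) return(regions)
  ed <- read.csv(editsFile, stringsAsFactors = FALSE)
  if (nrow(ed) == 0) return(regions)
  ids <- vapply(regions, function(r) r@id, integer(1))
  sets <- lapply(regions, function(r) r@pixels)
  names(sets) <- ids
  for (i in seq_len(nrow(ed))) {
    op <- ed$op[i]; id <- as.character(ed$id[i])
    if (!id %in% names(sets))
      stop("ROI edit references unknown region id ", id)
    if (op == "delete") {
      sets[[id]] <- NULL
    } else if (op == "split") {
      px <- sets[[id]]
      line <- .parsePolyline(ed$coords[i])
      cut <- do.call(rbind, lapply(seq_len(nrow(line) - 1), function(k)
        rasterizeLine8(line[k, ], line[k + 1, ])))
      keep <- !(paste(px[, 1], px[, 2]) %in% paste(cut[, 1], cut[, 2]))
      sets[[id]] <- NULL
      parts <- .splitPixelSet(px[keep, , drop = FALSE])
      for (p in parts) sets[[paste0("part", length(sets), "_", id)]] <- p
    } else stop("unknown ROI edit op '", op, "'")
  }
  .orderAndNumber(unname(sets))
}

.parsePolyline <- function(s) {
  pts <- strsplit(trimws(strsplit(s, ";")[[1]]), "[ ]+")
  do.call(rbind, lapply(pts, function(p) as.numeric(p)))
}

## split a pixel set into 8-connected components (local labeling)
.splitPixelSet <- function(px) {
  if (nrow(px) == 0) return(list())
  r0 <- min(px[, 1]) - 1L; c0 <- min(px[, 2]) - 1L
  m <- matrix(FALSE, max(px[, 1]) - r0 + 1, max(px[, 2]) - c0 + 1)
  m[cbind(px[, 1] - r0, px[, 2] - c0)] <- TRUE
  lab <- labelConnected8(m)
  lapply(seq_len(max(lab)), function(l) {
    w <- which(lab == l)
    cbind((w - 1L) %% nrow(lab) + 1L + r0,
          (w - 1L) %/% nrow(lab) + 1L + c0)
  })
}

#' Segment adhesions in a two-channel image
#'
#' Convenience chain: choose the segmentation source image (mean of both
#' channels by default), band-pass filter, Otsu-threshold, extract
#' area-filtered regions and apply optional region edits.
#'
#' @param images a \linkS4class{ProjectedImagePair}.
#' @param params a \linkS4class{SegmentationParams}.
#' @param editsFile optional ROI edits CSV (see
#'   \code{\link{applyRoiEdits}}).
#' @return list of \linkS4class{FARegion}.
#' @export
segmentFAs <- function(images, params = SegmentationParams(),
                       editsFile = NULL) {
  src <- switch(params@source,
                green = images@green,
                red = images@red,
                mean = (images@red + images@green) / 2)
  filt <- dogFilter(src, params@sigmaLow, params@sigmaHigh)
  mask <- otsuBinarize(filt)
  applyRoiEdits(extractFARegions(mask, params), editsFile)
}
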