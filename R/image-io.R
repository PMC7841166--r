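## Reading and writing of image and tabular artefacts.
##
## Multi-channel z-stacks are stored as multi-page TIFFs with pages ordered
## channel-fastest within z (z1/ch1, z1/ch2, z2/ch1, ...). Intensities are
## 16-bit samples mapped to [0, 1]; the generator digitizes to the same
## grid, so write/load round-trips are exact.

#' Load a two-channel (optionally multi-z) TIFF stack
#'
#' @param path TIFF file path.
#' @param channelOrder character of length 2 mapping page order within each
#'   z-slice to channel roles, e.g. \code{c("red","green")} means the first
#'   page of each slice is the red channel. The declared role map is
#'   honoured irrespective of storage order.
#' @param pixelPitchNm pixel pitch (nm). This declared value takes
#'   precedence over any file metadata (a message is emitted if the file
#'   carries a conflicting resolution tag).
#' @param zStepNm z-slice interval (nm), metadata only.
#' @param nZ number of z-slices; by default inferred as pages/2. Supply it
#'   explicitly when the page count is ambiguous.
#' @return a \linkS4class{ChannelStack}.
#' @export
loadStack <- function(path, channelOrder = c("red", "green"),
                      pixelPitchNm = 40, zStepNm = 110, nZ = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (length(pages) < 2)
    stop("need at least 2 channels; file has ", length(pages), " page(s)")
  if (!setequal(channelOrder, c("red", "green")) || length(channelOrder) != 2)
    stop("channelOrder must name 'red' and 'green'")
  if (length(pages) %% 2 != 0)
    stop("odd page count: axis order is ambiguous, supply a 2-channel file")
  inferredZ <- length(pages) / 2
  if (is.null(nZ)) nZ <- inferredZ
  if (nZ * 2 != length(pages))
    stop("page count ", length(pages), " does not match 2 channels x ",
         nZ, " z-slices")
  xres <- attr(pages[[1]], "x.resolution")
  if (!is.null(xres) && is.finite(xres) && xres > 0) {
    filePitch <- 1e7 / xres   # resolution stored as px/cm
    if (abs(filePitch - pixelPitchNm) > 1e-6)
      message("declared pixel pitch ", pixelPitchNm,
              " nm overrides file metadata (", signif(filePitch, 6), " nm)")
  }
  d <- dim(pages[[1]])
  arr <- array(0, c(d[1], d[2], 2, nZ))
  for (z in seq_len(nZ)) for (ch in 1:2)
    arr[, , ch, z] <- pages[[(z - 1) * 2 + ch]]
  new("ChannelStack", data = arr, channels = channelOrder,
      pixelPitchNm = pixelPitchNm, zStepNm = zStepNm)
}

#' Average-project selected z-slices of a stack
#'
#' Per-pixel arithmetic mean over the selected slices, per channel
#' (matching the average projection of the z-slices with clearly visible
#' adhesions used upstream of all measurements).
#'
#' @param stack a \linkS4class{ChannelStack}.
#' @param zIndices integer z-slices to average; default all.
#' @return a \linkS4class{ProjectedImagePair}.
#' @export
projectZ <- function(stack, zIndices = NULL) {
  nz <- dim(stack@data)[4]
  if (is.null(zIndices)) zIndices <- seq_len(nz)
  if (length(zIndices) == 0) stop("empty z-slice selection")
  if (any(zIndices < 1 | zIndices > nz))
    stop("z indices out of range 1..", nz)
  proj <- function(role) {
    ch <- match(role, stack@channels)
    sl <- stack@data[, , ch, zIndices, drop = FALSE]
    apply(sl, c(1, 2), mean)
  }
  ProjectedImagePair(proj("red"), proj("green"),
                     pixelPitchNm = stack@pixelPitchNm,
                     provenance = list(zIndices = zIndices))
}

#' Write a two-channel image (or multi-z stack) as a 16-bit TIFF
#'
#' @param images a \linkS4class{ProjectedImagePair}, or a list of them
#'   (treated as z-slices).
#' @param path output TIFF path.
#' @param channelOrder page order within each slice.
#' @return \code{path}, invisibly.
#' @export
writeImagePair <- function(images, path, channelOrder = c("red", "green")) {
  if (is(images, "ProjectedImagePair")) images <- list(images)
  pages <- list()
  for (sl in images) {
    chans <- list(red = sl@red, green = sl@green)
    for (role in channelOrder)
      pages[[length(pages) + 1]] <- chans[[role]]
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Write / read a binary mask TIFF
#' @param mask 0/1 matrix.
#' @param path file path.
#' @export
writeMask <- function(mask, path) {
  tiff::writeTIFF(matrix(as.numeric(mask > 0), nrow(mask)), path,
                  bits.per.sample = 8)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(m > 0.5), nrow(m))
}

#' Write regions as a label image TIFF
#'
#' Pixel values are region ids scaled into 16-bit range.
#' @param regions list of \linkS4class{FARegion}.
#' @param shape image dimensions c(rows, cols).
#' @param path output path.
#' @export
writeLabelImage <- function(regions, shape, path) {
  lab <- matrix(0L, shape[1], shape[2])
  for (rg in regions) lab[rg@pixels] <- rg@id
  tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' Write / read a scene ground-truth table
#' @param truth ground-truth data.frame from \code{\link{renderScene}}.
#' @param path CSV path.
#' @export
writeGroundTruth <- function(truth, path) {
  write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
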