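## Population statistics: signed protrusion sets, reference-bias
## correction, Mann-Whitney comparisons, 1D and 2D difference histograms
## and the cyan-white-magenta lookup table.

#' Convert per-adhesion measurements to signed values
#'
#' Green protrusions become positive lengths, red protrusions negative,
#' absent protrusions exactly zero, independently for head and tail. Only
#' QC-passing (non-discarded) rows are used.
#'
#' @param measurements data.frame from \code{\link{measureScene}}.
#' @param label population label.
#' @return a \linkS4class{SignedProtrusionSet}.
#' @export
toSigned <- function(measurements, label = "") {
  m <- measurements[!measurements$discarded, , drop = FALSE]
  signOne <- function(channel, nm) {
    s <- ifelse(channel == "green", 1, ifelse(channel == "red", -1, 0))
    s * nm
  }
  SignedProtrusionSet(head = signOne(m$headChannel, m$headNm),
                      tail = signOne(m$tailChannel, m$tailNm),
                      label = label)
}

#' Estimate the measurement bias from a reference set
#'
#' The reference population expresses the same protein in both colours, so
#' its true protrusions are zero everywhere; its median signed head and
#' tail values estimate the systematic bias of the measurement (real
#' same-protein references typically show a small bias toward one colour),
#' which is then subtracted from all further measurements.
#'
#' @param reference a \linkS4class{SignedProtrusionSet} built from
#'   same-protein dual-colour data.
#' @return named numeric c(head = , tail = ) bias in nm.
#' @export
referenceBias <- function(reference) {
  n <- length(reference@head)
  if (n == 0) stop("empty reference set")
  if (n < 30)
    warning("reference set has fewer than 30 adhesions; bias is unstable")
  c(head = median(reference@head), tail = median(reference@tail))
}

#' Subtract the reference bias from a signed set
#'
#' Every signed value is shifted by minus the per-end bias; the correction
#' is recorded in the object and applying it twice is an error.
#'
#' @param set a \linkS4class{SignedProtrusionSet}.
#' @param biases named numeric c(head = , tail = ) from
#'   \code{\link{referenceBias}} (or fixed values).
#' @return the corrected \linkS4class{SignedProtrusionSet}.
#' @export
applyBias <- function(set, biases) {
  if (set@biasCorrected)
    stop("set '", set@label, "' is already bias-corrected")
  if (!all(is.finite(biases))) stop("biases must be finite")
  SignedProtrusionSet(head = set@head - biases[["head"]],
                      tail = set@tail - biases[["tail"]],
                      label = set@label, biasCorrected = TRUE,
                      biasHead = biases[["head"]],
                      biasTail = biases[["tail"]])
}

## ---------------------------------------------------------------------------
## Mann-Whitney U
## ---------------------------------------------------------------------------

## exact permutation distribution of the rank sum via the shift algorithm
## on doubled midranks (integers even with ties); returns two-sided p
.mwExactP <- function(r2, nx, U, mu) {
  N <- length(r2)
  S <- sum(r2)
  f <- matrix(0, nx + 1, S + 1)
  f[1, 1] <- 1
  for (s in r2) {
    kmax <- nx
    for (k in kmax:1) {
      nzrow <- f[k, ]
      if (any(nzrow > 0))
        f[k + 1, (s + 1):(S + 1)] <- f[k + 1, (s + 1):(S + 1)] +
          nzrow[1:(S + 1 - s)]
    }
  }
  counts <- f[nx + 1, ]
  tot <- sum(counts)
  totals <- which(counts > 0) - 1
  Uvals <- totals / 2 - nx * (nx + 1) / 2
  sum(counts[totals + 1][abs(Uvals - mu) >= abs(U - mu) - 1e-9]) / tot
}

#' Two-tailed Mann-Whitney U test
#'
#' U is computed with midrank tie handling. The two-sided p value comes
#' from exact enumeration of the permutation distribution (shift algorithm
#' on doubled midranks, exact also under ties) when
#' \code{length(x) * length(y) <= exactLimit}, and otherwise from the
#' normal approximation with tie and continuity corrections. Samples in
#' which every value is tied give p = 1.
#'
#' @param x,y numeric samples (each nonempty).
#' @param exactLimit product-of-sizes bound below which the exact
#'   distribution is enumerated (default 400).
#' @return list(U, p, method).
#' @export
mannWhitneyU <- function(x, y, exactLimit = 400) {
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1) stop("both samples must be nonempty")
  v <- c(x, y)
  N <- nx + ny
  r <- rank(v)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  if (max(v) == min(v))
    return(list(U = U, p = 1, method = "degenerate"))
  if (nx * ny <= exactLimit) {
    p <- .mwExactP(as.integer(round(2 * r)), nx, U, mu)
    return(list(U = U, p = min(1, p), method = "exact"))
  }
  tiecnt <- table(r)
  sigma2 <- nx * ny / 12 *
    ((N + 1) - sum(tiecnt^3 - tiecnt) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
  z <- U - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

## ---------------------------------------------------------------------------
## Histograms
## ---------------------------------------------------------------------------

## symmetric 80-nm bin edges centred at 0, covering all values
.signedBinEdges <- function(values, binNm = 80) {
  mx <- max(abs(values), binNm / 2)
  k <- ceiling((mx - binNm / 2) / binNm + 1e-9)
  seq(-(k * binNm + binNm / 2), k * binNm + binNm / 2, by = binNm)
}

.binCounts <- function(values, edges) {
  # left-closed bins [e_i, e_{i+1})
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  tabulate(idx, nbins = length(edges) - 1)
}

#' Compare an experimental signed histogram with the reference
#'
#' Builds 80-nm binned counts (bins centred on 0) for the experimental and
#' reference signed values of one end, runs the two-tailed Mann-Whitney
#' test on the signed values, and reports the experimental median as the
#' population protrusion length when the difference is significant at
#' \code{alpha}.
#'
#' @param experimental,reference \linkS4class{SignedProtrusionSet}s with
#'   consistent bias correction.
#' @param end "head" or "tail".
#' @param binNm bin width (default 80 nm).
#' @param alpha significance gate for reporting the median (default 0.05).
#' @return a \linkS4class{HistogramComparison}.
#' @export
compareHistograms <- function(experimental, reference,
                              end = c("head", "tail"), binNm = 80,
                              alpha = 0.05) {
  end <- match.arg(end)
  if (experimental@biasCorrected != reference@biasCorrected)
    warning("experimental and reference sets differ in bias correction")
  ve <- slot(experimental, end)
  vr <- slot(reference, end)
  if (!length(ve) || !length(vr)) stop("both sets must be nonempty")
  edges <- .signedBinEdges(c(ve, vr), binNm)
  mw <- mannWhitneyU(ve, vr)
  new("HistogramComparison", binEdges = edges,
      countsExp = as.integer(.binCounts(ve, edges)),
      countsRef = as.integer(.binCounts(vr, edges)),
      medianExp = median(ve), significant = mw$p < alpha,
      U = mw$U, pValue = mw$p, nExp = length(ve), nRef = length(vr),
      end = end, alpha = alpha)
}

#' 2D head/tail difference histogram
#'
#' Bins the (signed head, signed tail) pairs of both populations into a
#' common symmetric 80 x 80 nm grid, converts each to relative frequencies
#' (percent of its n), and subtracts reference from experimental
#' (percentage points).
#'
#' @param experimental,reference \linkS4class{SignedProtrusionSet}s with
#'   consistent bias correction.
#' @param binNm bin width, default 80 nm.
#' @return a \linkS4class{Diff2DHistogram}.
#' @export
diff2DHistogram <- function(experimental, reference, binNm = 80) {
  if (experimental@biasCorrected != reference@biasCorrected)
    warning("experimental and reference sets differ in bias correction")
  all <- c(experimental@head, experimental@tail, reference@head,
           reference@tail)
  edges <- .signedBinEdges(all, binNm)
  nb <- length(edges) - 1
  grid2 <- function(set) {
    hi <- findInterval(set@head, edges, rightmost.closed = TRUE)
    ti <- findInterval(set@tail, edges, rightmost.closed = TRUE)
    g <- matrix(0, nb, nb)
    for (k in seq_along(hi)) g[hi[k], ti[k]] <- g[hi[k], ti[k]] + 1
    100 * g / length(set@head)
  }
  e <- grid2(experimental)
  r <- grid2(reference)
  new("Diff2DHistogram", binEdges = edges, expPct = e, refPct = r,
      diffPp = e - r)
}

## ---------------------------------------------------------------------------
## LUT rendering
## ---------------------------------------------------------------------------

#' Map percentage-point differences to 8-bit LUT levels
#'
#' Linear map \code{level = round(255 * (delta + 3.45) / 6.90)} clamped to
#' [0, 255]: level 0 corresponds to a decrease of 3.45 percentage points,
#' level 123 to -0.13, level 133 to +0.14, and level 255 to an increase of
#' +3.44; levels 124-132 (differences within about 0.11 pp of zero) render
#' white.
#'
#' @param diffPp numeric matrix (or vector) of differences in percentage
#'   points.
#' @return integer matrix of levels in [0, 255].
#' @export
lutLevel <- function(diffPp) {
  lv <- round(255 * (diffPp + 3.45) / 6.90)
  storage.mode(lv) <- "integer"
  pmin(pmax(lv, 0L), 255L)
}

#' Render a difference grid through the cyan-white-magenta LUT
#'
#' Levels 0-123 interpolate linearly from cyan toward white (level 123 is
#' the last faintly cyan shade), levels 124-132 are exactly white, and
#' levels 133-255 interpolate from the first faint magenta shade to full
#' magenta.
#'
#' @param diffPp numeric matrix of percentage-point differences.
#' @return numeric array [rows, cols, 3] of RGB values in [0, 1].
#' @export
renderLut <- function(diffPp) {
  lv <- lutLevel(diffPp)
  d <- dim(lv)
  rgb <- array(1, c(d[1], d[2], 3))
  cy <- lv <= 123L
  rgb[, , 1][cy] <- lv[cy] / 124          # cyan (0,1,1) -> near-white
  mg <- lv >= 133L
  frac <- (lv[mg] - 132) / 123            # near-white -> magenta (1,0,1)
  rgb[, , 2][mg] <- 1 - frac
  rgb
}

## ---------------------------------------------------------------------------
## Output writers / plots
## ---------------------------------------------------------------------------

#' Write a histogram comparison as CSV
#' @param hc a \linkS4class{HistogramComparison}.
#' @param path output CSV.
#' @export
writeHistogramCsv <- function(hc, path) {
  write.csv(data.frame(binLeftNm = hc@binEdges[-length(hc@binEdges)],
                       countExp = hc@countsExp, countRef = hc@countsRef),
            path, row.names = FALSE)
  invisible(path)
}

#' Write a 2D difference histogram as CSV (long format)
#' @param d2 a \linkS4class{Diff2DHistogram}.
#' @param path output CSV.
#' @export
writeDiff2DCsv <- function(d2, path) {
  nb <- nrow(d2@diffPp)
  left <- d2@binEdges[-length(d2@binEdges)]
  df <- expand.grid(headBinNm = left, tailBinNm = left)
  df$diffPp <- as.vector(d2@diffPp)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Plot a signed histogram comparison to PNG
#'
#' Experimental counts as a black step line over the grey reference
#' distribution.
#'
#' @param hc a \linkS4class{HistogramComparison}.
#' @param path PNG path.
#' @export
plotComparison <- function(hc, path) {
  grDevices::png(path, width = 700, height = 450)
  on.exit(grDevices::dev.off())
  mid <- hc@binEdges[-length(hc@binEdges)] + diff(hc@binEdges) / 2
  refFrac <- hc@countsRef / sum(hc@countsRef)
  expFrac <- hc@countsExp / sum(hc@countsExp)
  graphics::barplot(refFrac, names.arg = round(mid), col = "grey80",
                    border = NA, ylim = c(0, max(refFrac, expFrac) * 1.1),
                    xlab = "signed protrusion length (nm)",
                    ylab = "relative frequency",
                    main = sprintf("%s: p = %.3g%s", hc@end, hc@pValue,
                                   if (hc@significant)
                                     sprintf(", median %+.0f nm",
                                             hc@medianExp) else ""))
  graphics::lines(seq_along(mid) * 1.2 - 0.5, expFrac, type = "s",
                  lwd = 2)
  invisible(path)
}

#' Render a 2D difference histogram to PNG via the LUT
#' @param d2 a \linkS4class{Diff2DHistogram}.
#' @param path PNG path.
#' @export
plotDiff2D <- function(d2, path) {
  rgb <- renderLut(d2@diffPp)
  grDevices::png(path, width = 500, height = 500)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, 1, 1))
  graphics::plot(NA, xlim = range(d2@binEdges), ylim = range(d2@binEdges),
                 xlab = "signed tail (nm)", ylab = "signed head (nm)",
                 asp = 1)
  graphics::rasterImage(grDevices::as.raster(rgb),
                        min(d2@binEdges), min(d2@binEdges),
                        max(d2@binEdges), max(d2@binEdges),
                        interpolate = FALSE)
  invisible(path)
}
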