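## Profile-level simulation of the same-protein (reference-style) null:
## one underlying adhesion intensity profile observed through two
## independently noisy channels, measured with the package's own
## measurement operators. Used for bias estimation, null calibration and
## the reference distribution in the synthetic analyses.

## one plateau profile with half-Gaussian ends (SD 1 px)
.plateauProfile <- function(n, coreStart, coreEnd) {
  i <- seq_len(n)
  over <- pmax(coreStart - i, 0) + pmax(i - coreEnd, 0)
  exp(-over^2 / 2)
}

#' Simulate identical-channel null measurements
#'
#' Draws \code{n} adhesions whose red and green channels share the same
#' underlying longitudinal profile (plateau of 15-35 px with sub-resolution
#' end falloff) but carry independent per-channel noise (additive Gaussian
#' plus shot-like), then measures each with the real measurement chain
#' (window-5 median filter, 40-percent positivity, gap-tolerant main
#' stretch, protrusion at both ends) on a straight 40-nm-per-step path.
#' The resulting signed head/tail values form the apparent-protrusion null
#' of a same-protein reference experiment.
#'
#' @param n number of adhesions.
#' @param seed integer seed.
#' @param gaussianSd additive noise SD relative to a unit plateau.
#' @param shotScaling signal-dependent noise factor.
#' @param peakRange per-channel peak intensity range (uniform draw).
#' @param thresholdFrac,maxGap,medianWindow measurement tunables.
#' @param pixelPitchNm pixel pitch (nm).
#' @return a \linkS4class{SignedProtrusionSet} labelled "null".
#' @export
simulateNullSet <- function(n, seed = 1L, gaussianSd = 0.04,
                            shotScaling = 0.08,
                            peakRange = c(0.45, 0.8),
                            thresholdFrac = 0.40, maxGap = 4,
                            medianWindow = 5, pixelPitchNm = 40) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  head <- numeric(n); tail <- numeric(n)
  k <- 0
  while (k < n) {
    core <- sample(15:35, 1)
    margin <- 8
    len <- core + 2 * margin
    shape <- .plateauProfile(len, margin + 1, margin + core)
    path <- AxisPath(cbind(seq_len(len), 1L), pixelPitchNm = pixelPitchNm,
                     oriented = TRUE)
    noisy <- function() {
      pk <- runif(1, peakRange[1], peakRange[2])
      v <- pk * shape
      pmax(v + rnorm(len, 0, gaussianSd) +
             rnorm(len) * shotScaling * sqrt(v), 0)
    }
    prof <- data.frame(rawRed = noisy(), rawGreen = noisy())
    prof$filtRed <- medianFilterProfile(prof$rawRed, medianWindow)
    prof$filtGreen <- medianFilterProfile(prof$rawGreen, medianWindow)
    pos <- markPositive(prof, thresholdFrac)
    ms <- findMainStretch(pos$red, pos$green, maxGap)
    if (!length(ms)) next
    hd <- measureProtrusionAtEnd(pos$red, pos$green, ms, "head", path,
                                 maxGap)
    tl <- measureProtrusionAtEnd(pos$red, pos$green, ms, "tail", path,
                                 maxGap)
    k <- k + 1
    sgn <- function(m) if (m$channel == "green") m$nm else
      if (m$channel == "red") -m$nm else 0
    head[k] <- sgn(hd)
    tail[k] <- sgn(tl)
  }
  SignedProtrusionSet(head = head, tail = tail, label = "null")
}
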