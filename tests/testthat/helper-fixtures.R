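# Shared fixtures and independent brute-force oracles.

# rectangular cell polygon inset by `inset` px in a square image
rectPolygon <- function(shape, inset = 20) {
  cbind(c(inset, inset, shape[1] - inset, shape[1] - inset),
        c(inset, shape[2] - inset, shape[2] - inset, inset))
}

# small scene around a list of FASpec objects
smallScene <- function(faSpecs, shape = c(250L, 250L), inset = 20,
                       seed = 1L, noise = NoiseSpec()) {
  SceneSpec(imageShape = shape, faSpecs = faSpecs,
            cellPolygon = rectPolygon(shape, inset), seed = seed,
            noise = noise)
}

rectFrame <- function(shape = c(250L, 250L), inset = 20) {
  CellFrame(c(inset, shape[1] - inset), c(inset, shape[2] - inset))
}

# straight axis path of length n (all 40-nm steps)
straightPath <- function(n, pitch = 40) {
  AxisPath(cbind(seq_len(n), 1L), pixelPitchNm = pitch, oriented = TRUE)
}

# ---------------------------------------------------------------------------
# Brute-force oracle for the gap-tolerant main stretch: enumerate every
# candidate interval and check the rule directly.
bruteMainStretch <- function(posRed, posGreen, maxGap = 4) {
  n <- length(posRed)
  both <- posRed & posGreen
  best <- integer(0)
  bestLen <- 0
  for (i0 in seq_len(n)) {
    if (!both[i0]) next
    for (i1 in i0:n) {
      if (!both[i1]) next
      runs <- rle(both[i0:i1])
      gapOk <- all(runs$lengths[!runs$values] <= maxGap)
      if (gapOk && (i1 - i0 + 1) > bestLen) {
        best <- c(i0, i1)
        bestLen <- i1 - i0 + 1
      }
    }
  }
  best
}

# Brute-force oracle for the protrusion at one end: literal re-derivation.
# After absorbing adjoining both-positive pixels, the protruding channel is
# read off the bordering pixel; the outermost pixel of the run is the
# farthest positive pixel reachable without ever crossing a gap longer than
# maxGap.
bruteProtrusion <- function(posRed, posGreen, interval, end, path,
                            maxGap = 4) {
  n <- length(posRed)
  dir <- if (end == "head") -1L else 1L
  b <- if (end == "head") interval[1] else interval[2]
  both <- posRed & posGreen
  repeat {
    j <- b + dir
    if (j < 1 || j > n || !both[j]) break
    b <- j
  }
  j <- b + dir
  if (j < 1 || j > n || (!posRed[j] && !posGreen[j]))
    return(list(channel = "none", nm = 0))
  channel <- if (posRed[j]) "red" else "green"
  pos <- if (channel == "red") posRed else posGreen
  # candidate outermost pixels: every positive position outward of j whose
  # intervening negative runs are all <= maxGap
  outermost <- j
  for (k in seq(j, if (dir < 0) 1 else n, by = dir)) {
    if (!pos[k]) next
    seg <- pos[seq(j, k, by = dir)]
    runs <- rle(seg)
    if (all(runs$lengths[!runs$values] <= maxGap)) outermost <- k
  }
  list(channel = channel,
       nm = abs(path@cumNm[outermost] - path@cumNm[b]))
}

# Brute-force two-sided Mann-Whitney p by full enumeration of group
# assignments (midranks for ties).
bruteMannWhitneyP <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  combos <- utils::combn(nx + ny, nx)
  Us <- colSums(matrix(r[combos], nrow = nx)) - nx * (nx + 1) / 2
  mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
}

# random boolean profile pair with clumpy structure
randomProfilePair <- function(n, p = 0.6) {
  clump <- function() {
    v <- logical(n)
    i <- 1
    while (i <= n) {
      len <- sample(1:5, 1)
      v[i:min(n, i + len - 1)] <- runif(1) < p
      i <- i + len
    }
    v
  }
  list(red = clump(), green = clump())
}

# rotate a matrix 90 degrees clockwise: (r, c) -> (c, nrow + 1 - r)
rot90mat <- function(m) t(m[nrow(m):1, , drop = FALSE])

# rotate a SceneSpec 90 degrees clockwise (image, polygon and FA specs)
rot90scene <- function(spec) {
  nr <- spec@imageShape[1]
  rotPt <- function(p) c(p[2], nr + 1 - p[1])
  poly <- t(apply(spec@cellPolygon, 1, rotPt))
  fas <- lapply(spec@faSpecs, function(fa) {
    FASpec(centre = rotPt(fa@centre), angle = (fa@angle + 90) %% 180,
           coreLength = fa@coreLength, width = fa@width,
           headChannel = fa@headChannel, headExtra = fa@headExtra,
           tailChannel = fa@tailChannel, tailExtra = fa@tailExtra,
           peakRed = fa@peakRed, peakGreen = fa@peakGreen)
  })
  SceneSpec(imageShape = spec@imageShape[2:1],
            pixelPitchNm = spec@pixelPitchNm, faSpecs = fas,
            cellPolygon = poly, backgroundRed = spec@backgroundRed,
            backgroundGreen = spec@backgroundGreen, noise = spec@noise,
            seed = spec@seed)
}
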