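# Profile extraction, positivity, gap-tolerant runs, protrusion lengths.

test_that("the edge-truncated median filter matches a brute-force oracle", {
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    x <- round(runif(n, 0, 100))
    got <- medianFilterProfile(x, 5)
    want <- vapply(seq_len(n), function(i)
      median(x[max(1, i - 2):min(n, i + 2)]), numeric(1))
    expect_equal(got, want)
  }
  # the end windows have sizes 3 and 4
  x <- c(100, 0, 0, 0, 0, 0)
  expect_equal(medianFilterProfile(x, 5)[1], 0)   # median(100,0,0)
  # constant input is unchanged, a lone spike is removed
  expect_equal(medianFilterProfile(rep(7, 10), 5), rep(7, 10))
  spike <- rep(0, 11); spike[6] <- 100
  expect_equal(medianFilterProfile(spike, 5), rep(0, 11))
})

test_that("profiles are sampled along the path with filtering applied", {
  img <- matrix(0, 20, 20)
  img[10, ] <- seq(0, 1, length.out = 20)
  pair <- ProjectedImagePair(img, img * 0.5)
  path <- AxisPath(cbind(10, 1:20), oriented = TRUE)
  prof <- extractProfiles(path, pair)
  expect_equal(prof$rawRed, img[10, ])
  expect_equal(prof$rawGreen, img[10, ] * 0.5)
  expect_equal(prof$filtRed, medianFilterProfile(img[10, ], 5))
})

test_that("positivity marking uses 40 percent of the per-channel filtered maximum", {
  filt <- c(1000, 400, 399, 0, 1000)
  prof <- data.frame(rawRed = filt, rawGreen = filt * 10,
                     filtRed = filt, filtGreen = filt * 10)
  pos <- markPositive(prof)
  expect_equal(pos$red, c(TRUE, TRUE, FALSE, FALSE, TRUE))
  # identical channels give identical markings; scaling is immaterial
  expect_equal(pos$green, pos$red)
  # all-zero channel: everything negative plus a QC flag
  prof0 <- data.frame(rawRed = filt, rawGreen = 0, filtRed = filt,
                      filtGreen = rep(0, 5))
  pos0 <- markPositive(prof0)
  expect_false(any(pos0$green))
  expect_true("zero_channel_green" %in% pos0$qc)
})

test_that("the main stretch tolerates 4-px gaps but not 5-px gaps", {
  r10 <- rep(TRUE, 10); r6 <- rep(TRUE, 6)
  gap4 <- rep(FALSE, 4); gap5 <- rep(FALSE, 5)
  both <- c(r10, gap4, r6)
  ms <- findMainStretch(both, both)
  expect_equal(ms, c(1L, 20L))
  both5 <- c(r10, gap5, r6)
  expect_equal(findMainStretch(both5, both5), c(1L, 10L))
  # no dual-positive pixel: empty result
  expect_length(findMainStretch(rep(TRUE, 5), rep(FALSE, 5)), 0)
  # tie broken toward the head
  tie <- c(rep(TRUE, 5), rep(FALSE, 6), rep(TRUE, 5))
  expect_equal(findMainStretch(tie, tie), c(1L, 5L))
})

test_that("main stretch equals the exhaustive oracle on random profile pairs", {
  set.seed(11)
  for (rep in 1:200) {
    n <- sample(3:20, 1)
    pp <- randomProfilePair(n)
    expect_identical(findMainStretch(pp$red, pp$green),
                     bruteMainStretch(pp$red, pp$green))
  }
})

test_that("step-geometry lengths are exact", {
  p <- AxisPath(rbind(c(1, 1), c(1, 2), c(2, 3), c(2, 4)), oriented = TRUE)
  expect_equal(p@diagonal, c(FALSE, TRUE, FALSE))
  expect_equal(pathLengthNm(p, 1, 1), 0)                     # empty segment
  expect_equal(pathLengthNm(p, 2, 3), sqrt(3200))            # one diagonal
  expect_equal(pathLengthNm(p, 1, 4), 80 + sqrt(3200))       # 2 straight + 1 diagonal
  # proportional scaling for non-40 nm pitch
  p2 <- AxisPath(rbind(c(1, 1), c(2, 2)), pixelPitchNm = 80,
                 oriented = TRUE)
  expect_equal(pathLengthNm(p2, 1, 2), sqrt(3200) * 2)
  expect_equal(stepLengthNm(c(FALSE, FALSE, TRUE)), 80 + sqrt(3200))
})

test_that("protrusions at an end follow the bordering-pixel rule", {
  n <- 20
  path <- straightPath(n)
  # bordering pixel negative for both -> zero protrusion
  red <- c(rep(FALSE, 5), rep(TRUE, 10), rep(FALSE, 5))
  ms <- findMainStretch(red, red)
  z <- measureProtrusionAtEnd(red, red, ms, "head", path)
  expect_equal(z$channel, "none")
  expect_identical(z$nm, 0)
  # 3 green-positive pixels outward at the tail: 3 straight steps = 120 nm
  green <- c(rep(FALSE, 5), rep(TRUE, 13), rep(FALSE, 2))
  ms <- findMainStretch(red, green)
  expect_equal(ms, c(6L, 15L))
  tl <- measureProtrusionAtEnd(red, green, ms, "tail", path)
  expect_equal(tl$channel, "green")
  expect_equal(tl$nm, 120)
  hd <- measureProtrusionAtEnd(red, green, ms, "head", path)
  expect_equal(hd$channel, "none")
  # diagonal geometry: 2 protruding pixels via 1 straight + 1 diagonal
  dpath <- AxisPath(rbind(c(5, 1), c(6, 2), c(6, 3), c(6, 4), c(6, 5),
                          c(6, 6)), oriented = TRUE)
  pr <- c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
  pg <- c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)
  ms2 <- findMainStretch(pr, pg)
  hd2 <- measureProtrusionAtEnd(pr, pg, ms2, "head", dpath)
  expect_equal(hd2$channel, "red")
  expect_equal(hd2$nm, 40 + sqrt(3200))
})

test_that("a both-positive bordering pixel extends the stretch before re-applying the rule", {
  # stretch capped by an internal 5-px gap, but pixels beyond the gap are
  # both-positive again and adjoin the chosen interval at one side
  both <- c(rep(TRUE, 8), rep(TRUE, 4))
  red <- c(rep(TRUE, 8), rep(TRUE, 4))
  green <- c(rep(TRUE, 12))
  path <- straightPath(12)
  ms <- c(3L, 8L)   # artificial sub-interval with both-positive neighbours
  hd <- measureProtrusionAtEnd(red, green, ms, "head", path)
  # pixels 1..2 are both-positive: absorbed, then no pixel remains
  expect_equal(hd$channel, "none")
  expect_equal(hd$boundary, 1L)
  red2 <- c(FALSE, TRUE, rep(TRUE, 6), rep(FALSE, 4))
  green2 <- rep(TRUE, 12)
  ms2 <- c(3L, 8L)
  hd2 <- measureProtrusionAtEnd(red2, green2, ms2, "head", path)
  expect_equal(hd2$boundary, 2L)   # absorbed the both-positive pixel 2
  expect_equal(hd2$channel, "green")
  expect_equal(hd2$nm, 40)
})

test_that("protrusion measurement matches the brute-force oracle on random pairs", {
  set.seed(23)
  for (rep in 1:300) {
    n <- sample(4:25, 1)
    pp <- randomProfilePair(n)
    ms <- findMainStretch(pp$red, pp$green)
    if (!length(ms)) next
    path <- straightPath(n)
    for (end in c("head", "tail")) {
      got <- measureProtrusionAtEnd(pp$red, pp$green, ms, end, path)
      want <- bruteProtrusion(pp$red, pp$green, ms, end, path)
      expect_equal(got$channel, want$channel)
      expect_equal(got$nm, want$nm)
    }
  }
})

test_that("channel swap exchanges identities and preserves lengths exactly", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(6:25, 1)
    pp <- randomProfilePair(n)
    path <- straightPath(n)
    ms1 <- findMainStretch(pp$red, pp$green)
    ms2 <- findMainStretch(pp$green, pp$red)
    expect_identical(ms1, ms2)
    if (!length(ms1)) next
    for (end in c("head", "tail")) {
      a <- measureProtrusionAtEnd(pp$red, pp$green, ms1, end, path)
      b <- measureProtrusionAtEnd(pp$green, pp$red, ms2, end, path)
      swap <- c(red = "green", green = "red", none = "none")
      expect_identical(b$channel, unname(swap[a$channel]))
      expect_identical(b$nm, a$nm)
    }
  }
})

test_that("punching any 4-px hole inside the main stretch changes nothing", {
  n <- 30
  red <- c(rep(FALSE, 3), rep(TRUE, 22), rep(FALSE, 5))
  green <- c(rep(FALSE, 3), rep(TRUE, 25), rep(FALSE, 2))
  path <- straightPath(n)
  ms0 <- findMainStretch(red, green)
  tail0 <- measureProtrusionAtEnd(red, green, ms0, "tail", path)
  for (at in 8:18) for (len in 1:4) for (chan in c("red", "green", "both")) {
    r <- red; g <- green
    idx <- at:(at + len - 1)
    if (chan %in% c("red", "both")) r[idx] <- FALSE
    if (chan %in% c("green", "both")) g[idx] <- FALSE
    ms <- findMainStretch(r, g)
    expect_identical(ms, ms0)
    tl <- measureProtrusionAtEnd(r, g, ms, "tail", path)
    expect_identical(tl$nm, tail0$nm)
    expect_identical(tl$channel, tail0$channel)
  }
})

test_that("measuring whole adhesions recovers constructed protrusions", {
  # green tail extension of 3 px on a grid-aligned axis
  fa <- FASpec(centre = c(80, 125), angle = 90, coreLength = 24, width = 8,
               tailChannel = "green", tailExtra = 3)
  sc <- renderScene(smallScene(list(fa)))
  regs <- segmentFAs(sc$images)
  m <- measureFA(sc$images, regs[[1]], rectFrame())
  expect_false(m$discarded)
  expect_equal(m$tailChannel, "green")
  expect_equal(m$tailNm, 120, tolerance = 40 / 120 + 1e-6)
  expect_equal(m$headChannel, "none")
  # red head extension keeps its identity
  fa2 <- FASpec(centre = c(80, 125), angle = 90, coreLength = 24,
                width = 8, headChannel = "red", headExtra = 5)
  sc2 <- renderScene(smallScene(list(fa2)))
  m2 <- measureFA(sc2$images, segmentFAs(sc2$images)[[1]], rectFrame())
  expect_equal(m2$headChannel, "red")
})

test_that("noiseless tail growth is monotone in the measured length", {
  prev <- -1
  for (extra in 1:6) {
    fa <- FASpec(centre = c(80, 125), angle = 90, coreLength = 24,
                 width = 8, tailChannel = "green", tailExtra = extra)
    sc <- renderScene(smallScene(list(fa)))
    m <- measureFA(sc$images, segmentFAs(sc$images)[[1]], rectFrame())
    expect_gte(m$tailNm, prev)
    prev <- m$tailNm
  }
})

test_that("identical-channel adhesions with independent noise rarely show protrusions", {
  set.seed(5)
  nulls <- simulateNullSet(80, seed = 77)
  small <- abs(signedHead(nulls)) <= 2 * 40 & abs(signedTail(nulls)) <= 2 * 40
  expect_gte(mean(small), 0.9)
})
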