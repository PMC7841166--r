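# Signed sets, bias correction, Mann-Whitney, histograms, LUT.

fakeMeasurements <- function(headCh, headNm, tailCh, tailNm) {
  n <- length(headCh)
  data.frame(faId = seq_len(n), cellId = 1, headChannel = headCh,
             headNm = headNm, headPx = NA, tailChannel = tailCh,
             tailNm = tailNm, tailPx = NA, mainStretchPx = 20,
             mainStretchNm = 800, axisAngle = 0, centroidRow = 1,
             centroidCol = 1, qc = "", discarded = FALSE,
             stringsAsFactors = FALSE)
}

test_that("signing follows the green-positive red-negative convention", {
  m <- fakeMeasurements(c("green", "red", "none"), c(120, 96.6, 0),
                        c("red", "none", "green"), c(96.6, 0, 57))
  s <- toSigned(m, "demo")
  expect_equal(signedHead(s), c(120, -96.6, 0))
  expect_equal(signedTail(s), c(-96.6, 0, 57))
  # discarded rows are excluded
  m$discarded[2] <- TRUE
  expect_length(signedHead(toSigned(m)), 2)
})

test_that("reference bias estimation and subtraction behave as documented", {
  set.seed(9)
  base <- simulateNullSet(120, seed = 12)
  # symmetric noise: bias within one pixel of zero
  b0 <- referenceBias(base)
  expect_lt(abs(b0[["head"]]), 40 + 1e-9)
  expect_lt(abs(b0[["tail"]]), 40 + 1e-9)
  # injecting a constant +57 shift into the signed values moves the bias
  shifted <- SignedProtrusionSet(head = signedHead(base) + 57,
                                 tail = signedTail(base) + 57,
                                 label = "shifted")
  b <- referenceBias(shifted)
  expect_equal(b[["head"]], b0[["head"]] + 57)
  # empty set errors; small set warns
  expect_error(referenceBias(SignedProtrusionSet(numeric(0), numeric(0))),
               "empty")
  expect_warning(referenceBias(SignedProtrusionSet(rnorm(10), rnorm(10))),
                 "fewer than 30")
  # identity, exact correction, median shift, double-correction guard
  expect_equal(signedHead(applyBias(base, c(head = 0, tail = 0))),
               signedHead(base))
  corr <- applyBias(shifted, c(head = 57, tail = 57))
  expect_equal(median(signedHead(corr)), median(signedHead(shifted)) - 57)
  expect_error(applyBias(corr, b), "already bias-corrected")
})

test_that("the Mann-Whitney test matches hand-derived exact cases", {
  r <- mannWhitneyU(1:3, 4:6)
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)     # 2 of the 20 assignments are as extreme
  expect_equal(r$method, "exact")
  # identical samples: U = n^2/2 and p = 1
  x <- c(1, 5, 9, 13)
  same <- mannWhitneyU(x, x)
  expect_equal(same$U, length(x)^2 / 2)
  expect_equal(same$p, 1)
  # fully tied data
  expect_equal(mannWhitneyU(rep(2, 5), rep(2, 7))$p, 1)
})

test_that("exact p values match full permutation enumeration, with and without ties", {
  set.seed(17)
  for (rep in 1:25) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- sample(0:8, nx, replace = TRUE)   # heavy ties
    y <- sample(0:8, ny, replace = TRUE)
    got <- mannWhitneyU(x, y)
    expect_equal(got$method, "exact")
    expect_equal(got$p, bruteMannWhitneyP(x, y), tolerance = 1e-12)
    xc <- rnorm(nx); yc <- rnorm(ny)       # continuous, tie-free
    expect_equal(mannWhitneyU(xc, yc)$p, bruteMannWhitneyP(xc, yc),
                 tolerance = 1e-12)
  }
})

test_that("the large-sample branch agrees with the tie-corrected normal approximation", {
  set.seed(19)
  x <- round(rnorm(40, 0, 3)); y <- round(rnorm(35, 1, 3))
  got <- mannWhitneyU(x, y)
  expect_equal(got$method, "normal")
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE,
                                             exact = FALSE))
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-9)
})

test_that("histogram comparisons report medians only when significant", {
  set.seed(41)
  ref <- simulateNullSet(300, seed = 51)
  # experimental identical to reference: p = 1, nothing significant
  hcSame <- compareHistograms(ref, ref, "head")
  expect_equal(hcSame@pValue, 1)
  expect_false(hcSame@significant)
  expect_equal(sum(hcSame@countsExp), 300)
  expect_equal(sum(hcSame@countsRef), 300)
  # bins are symmetric about zero with an 80-nm central bin
  expect_equal(hcSame@binEdges, -rev(hcSame@binEdges))
  expect_true(any(abs(hcSame@binEdges - (-40)) < 1e-9))
  # a true +120 nm green tail shift at n = 500 is detected near +120
  exp500 <- simulateNullSet(500, seed = 52)
  shifted <- SignedProtrusionSet(head = signedHead(exp500),
                                 tail = signedTail(exp500) + 120,
                                 label = "shifted")
  ref500 <- simulateNullSet(500, seed = 53)
  hc <- compareHistograms(shifted, ref500, "tail")
  expect_true(hc@significant)
  expect_lt(abs(hc@medianExp - 120), 80)
})

test_that("2D difference histograms conserve mass and localize shifts", {
  set.seed(43)
  a <- simulateNullSet(400, seed = 61)
  d0 <- diff2DHistogram(a, a)
  expect_equal(max(abs(d0@diffPp)), 0)
  expect_equal(sum(d0@expPct), 100, tolerance = 1e-9)
  b <- simulateNullSet(400, seed = 62)
  # paxillin-head / zyxin-tail style population: red (negative) heads,
  # green (positive) tails
  shifted <- SignedProtrusionSet(head = signedHead(b) - 160,
                                 tail = signedTail(b) + 160, label = "s")
  d <- diff2DHistogram(shifted, a)
  expect_equal(sum(d@diffPp), 0, tolerance = 1e-9)
  edges <- d@binEdges
  mid <- edges[-length(edges)] + 40
  quad <- outer(mid < 0, mid > 0, "&")     # head < 0 and tail > 0
  oppQuad <- outer(mid > 0, mid < 0, "&")
  expect_gt(sum(d@diffPp[quad]), 0)
  expect_gt(sum(d@diffPp[quad]), sum(d@diffPp[oppQuad]))
})

test_that("the LUT reproduces the printed anchor correspondences", {
  expect_equal(lutLevel(-3.45)[1], 0L)
  expect_equal(lutLevel(-0.13)[1], 123L)
  expect_equal(lutLevel(0.14)[1], 133L)
  expect_equal(lutLevel(3.44)[1], 255L)
  expect_equal(lutLevel(0)[1], 128L)
  # clamping
  expect_equal(lutLevel(-99)[1], 0L)
  expect_equal(lutLevel(99)[1], 255L)
  # colours: dead zone white, first shades off-white, extremes saturated
  g <- renderLut(matrix(c(-3.45, -0.13, 0, 0.14, 3.44, -0.09, 0.09, 0, 0),
                        3, 3))
  expect_equal(g[1, 1, ], c(0, 1, 1))        # full cyan
  expect_equal(g[3, 1, ], c(1, 1, 1))        # zero difference: white
  expect_lt(g[2, 1, 1], 1)                   # level 123: last cyan shade
  expect_lt(g[1, 2, 2], 1)                   # level 133: first magenta shade
  expect_equal(g[2, 2, ], c(1, 0, 1))        # full magenta
  expect_equal(g[3, 2, ], c(1, 1, 1))        # -0.09 pp inside dead zone
  expect_equal(g[1, 3, ], c(1, 1, 1))        # +0.09 pp inside dead zone
})

test_that("channel swap negates signed sets and leaves p values unchanged", {
  set.seed(47)
  # nudge values off the bin edges so mirroring the half-open bins is exact
  nudge <- function(s) SignedProtrusionSet(head = signedHead(s) * 1.0001,
                                           tail = signedTail(s) * 1.0001,
                                           label = s@label)
  a <- nudge(simulateNullSet(150, seed = 71))
  b <- nudge(simulateNullSet(150, seed = 72))
  neg <- function(s) SignedProtrusionSet(head = -signedHead(s),
                                         tail = -signedTail(s),
                                         label = s@label)
  for (end in c("head", "tail")) {
    h1 <- compareHistograms(a, b, end)
    h2 <- compareHistograms(neg(a), neg(b), end)
    expect_equal(h2@pValue, h1@pValue)
    expect_equal(h2@medianExp, -h1@medianExp)
    expect_equal(h2@countsExp, rev(h1@countsExp))  # mirrored histogram
  }
})

test_that("CSV and PNG writers emit their artefacts", {
  a <- simulateNullSet(60, seed = 81)
  b <- simulateNullSet(60, seed = 82)
  hc <- compareHistograms(a, b, "head")
  csv <- withr::local_tempfile(fileext = ".csv")
  writeHistogramCsv(hc, csv)
  back <- read.csv(csv)
  expect_equal(sum(back$countExp), 60)
  png <- withr::local_tempfile(fileext = ".png")
  plotComparison(hc, png)
  expect_true(file.size(png) > 0)
  d2 <- diff2DHistogram(a, b)
  csv2 <- withr::local_tempfile(fileext = ".csv")
  writeDiff2DCsv(d2, csv2)
  expect_equal(sum(read.csv(csv2)$diffPp), 0, tolerance = 1e-9)
  png2 <- withr::local_tempfile(fileext = ".png")
  plotDiff2D(d2, png2)
  expect_true(file.size(png2) > 0)
})
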