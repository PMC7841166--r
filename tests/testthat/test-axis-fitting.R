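# Moment axis, ridge refinement, 30-percent termination, orientation.

# rectangle region fixture
rectRegion <- function(rows, cols) {
  px <- as.matrix(expand.grid(rows, cols))
  new("FARegion", id = 1L, pixels = cbind(px[, 1], px[, 2]),
      centroid = c(mean(rows), mean(cols)), area = nrow(px),
      bbox = c(range(rows), range(cols)))
}

test_that("the moment axis recovers centre and angle of simple shapes", {
  img <- matrix(1, 60, 60)
  reg <- rectRegion(26:33, 15:44)     # 30 x 8, horizontal
  ax <- momentAxis(reg, img)
  expect_equal(ax@angle, 0, tolerance = 0.5)
  expect_equal(ax@centre, c(29.5, 29.5), tolerance = 1e-6)
  expect_false(ax@isotropic)

  # rendered FA at 30 degrees: angle recovered within 1 degree
  fa <- FASpec(centre = c(125, 125), angle = 30, coreLength = 34, width = 8)
  sc <- renderScene(smallScene(list(fa)))
  regs <- segmentFAs(sc$images)
  ax30 <- momentAxis(regs[[1]], greenChannel(sc$images))
  expect_equal(ax30@angle, 30, tolerance = 1)

  # a disc is flagged isotropic
  d <- as.matrix(expand.grid(1:21, 1:21))
  d <- d[(d[, 1] - 11)^2 + (d[, 2] - 11)^2 <= 100, ]
  disc <- new("FARegion", id = 1L, pixels = d, centroid = c(11, 11),
              area = nrow(d), bbox = c(range(d[, 1]), range(d[, 2])))
  expect_true(momentAxis(disc, img)@isotropic)
})

test_that("ridge refinement follows the intensity ridge and falls back safely", {
  fa <- FASpec(centre = c(125, 125), angle = 20, coreLength = 34, width = 9)
  sc <- renderScene(smallScene(list(fa)))
  regs <- segmentFAs(sc$images)
  ax0 <- momentAxis(regs[[1]], greenChannel(sc$images))
  ax <- refineAxisByRidge(regs[[1]], greenChannel(sc$images), ax0)
  expect_true(ax@refined)
  expect_equal(ax@angle, 20, tolerance = 0.5)

  # sheared plateau: cross-section centre drifts linearly; the refined
  # line must track the ridge rather than the pixel-set moment axis
  img <- matrix(0, 80, 80)
  for (c0 in 20:60) {
    ridge <- 40 + 0.3 * (c0 - 40)
    img[, c0] <- exp(-(seq_len(80) - ridge)^2 / (2 * 2.5^2))
  }
  pxg <- as.matrix(expand.grid(30:50, 20:60))
  reg <- new("FARegion", id = 1L, pixels = pxg,
             centroid = c(40, 40), area = nrow(pxg),
             bbox = c(30L, 50L, 20L, 60L))
  ax0 <- AxisLine(centre = c(40, 40), angle = 0, majorAxisPx = 40,
                  minorAxisPx = 12)
  axr <- refineAxisByRidge(reg, img, ax0)
  expect_true(axr@refined)
  expect_equal(axr@angle, atan2(0.3, 1) * 180 / pi, tolerance = 1)

  # hopeless data: every perpendicular fit rejected -> initial axis kept
  zero <- matrix(0, 80, 80)
  axf <- refineAxisByRidge(reg, zero, ax0)
  expect_false(axf@refined)
  expect_equal(axf@angle, ax0@angle)
  expect_equal(axf@centre, ax0@centre)
})

test_that("termination cuts the path where both channels fall below 30 percent", {
  # plateau of constant level on zero background, both channels identical
  img <- matrix(0, 60, 120)
  img[27:33, 31:90] <- 100 / 65535 * 655.35   # exact grid value
  pair <- ProjectedImagePair(img, img)
  reg <- rectRegion(27:33, 31:90)
  ax <- AxisLine(centre = c(30, 60.5), angle = 0, majorAxisPx = 60,
                 minorAxisPx = 7)
  path <- terminateAxis(ax, pair, reg)
  expect_false(is.null(path))
  co <- pathCoords(path)
  # direct profile computation of the 3x3 box means along row 30
  bm <- vapply(1:120, function(cc)
    mean(img[29:31, max(1, cc - 1):min(120, cc + 1)]), numeric(1))
  crossing <- range(which(bm >= 0.3 * max(bm)))
  expect_equal(min(co[, 2]), crossing[1], tolerance = 1)
  expect_equal(max(co[, 2]), crossing[2], tolerance = 1)
  expect_true(all(co[, 1] == 30))
  # never runs to the image border
  expect_gt(min(co[, 2]), 1)
  expect_lt(max(co[, 2]), 120)
})

test_that("termination requires BOTH channels below threshold", {
  red <- matrix(0, 60, 120); green <- matrix(0, 60, 120)
  red[27:33, 31:80] <- 0.5
  green[27:33, 31:85] <- 0.5     # green extends 5 px beyond red
  pair <- ProjectedImagePair(red, green)
  reg <- rectRegion(27:33, 31:80)
  ax <- AxisLine(centre = c(30, 55), angle = 0, majorAxisPx = 50,
                 minorAxisPx = 7)
  path <- terminateAxis(ax, pair, reg)
  co <- pathCoords(path)
  # the path must include the green-only pixels beyond the red end
  expect_gte(max(co[, 2]), 84)
})

test_that("head/tail orientation picks the end nearest the cell frame", {
  frame <- CellFrame(c(1, 200), c(1, 200))
  path <- AxisPath(cbind(100, 11:60), oriented = FALSE)
  oriented <- orientHeadTail(path, frame)
  expect_equal(pathCoords(oriented)[1, ], c(row = 100, col = 11))
  # flipped input gives the same orientation
  flipped <- AxisPath(cbind(100, 60:11), oriented = FALSE)
  expect_equal(pathCoords(orientHeadTail(flipped, frame)),
               pathCoords(oriented))
  # reflecting scene and frame together is covariant
  reflPath <- AxisPath(cbind(100, 201 - (11:60)), oriented = FALSE)
  reflOriented <- orientHeadTail(reflPath, frame)
  expect_equal(pathCoords(reflOriented)[1, ], c(row = 100, col = 190))
  # exact tie: deterministic tie-break toward smaller row/col end
  tiePath <- AxisPath(cbind(100, 81:120), oriented = FALSE)
  expect_equal(pathCoords(orientHeadTail(tiePath, frame))[1, ],
               c(row = 100, col = 81))
})

test_that("head assignment matches ground truth on clearly oriented synthetic scenes", {
  spec <- randomSceneSpec(nFAs = 15, imageShape = c(512L, 512L), seed = 21L)
  sc <- renderScene(spec)
  frame <- CellFrame(range(spec@cellPolygon[, 1]),
                     range(spec@cellPolygon[, 2]))
  meas <- measureScene(sc$images, segmentFAs(sc$images), frame)
  merged <- matchGroundTruth(meas[!meas$discarded, ], sc$truth)
  # ends differing by > 5 px in frame distance: orientation always right
  withHead <- merged[merged$trueHeadChannel != "none" &
                     merged$trueHeadPx >= 2, ]
  expect_gt(nrow(withHead), 0)
  expect_true(all(withHead$headChannel == withHead$trueHeadChannel))
})

test_that("noiseless path length matches the true axis length within 2 steps", {
  fas <- list(FASpec(centre = c(125, 80), angle = 0, coreLength = 30,
                     width = 8, headChannel = "red", headExtra = 4),
              FASpec(centre = c(170, 170), angle = 45, coreLength = 26,
                     width = 8, tailChannel = "green", tailExtra = 5))
  spec <- smallScene(fas)
  sc <- renderScene(spec)
  regs <- segmentFAs(sc$images)
  frame <- rectFrame()
  for (rg in regs) {
    ax <- refineAxisByRidge(rg, greenChannel(sc$images),
                            momentAxis(rg, greenChannel(sc$images)))
    path <- terminateAxis(ax, sc$images, rg)
    tr <- sc$truth[which.min((sc$truth$centreRow - rg@centroid[1])^2 +
                             (sc$truth$centreCol - rg@centroid[2])^2), ]
    trueLen <- stepLengthNm(
      AxisPath(rasterizeLine8(c(tr$headRow, tr$headCol),
                              c(tr$tailRow, tr$tailCol)))@diagonal)
    measLen <- max(path@cumNm)
    expect_lt(abs(measLen - trueLen), 2 * sqrt(3200) + 1e-9)
  }
})
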