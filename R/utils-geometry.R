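## Low-level geometry shared by the synthetic generator and the measurement.

#' Rasterize a straight line to an 8-connected pixel chain
#'
#' Bresenham walk between the rounded endpoints. Consecutive pixels differ
#' by at most 1 in each coordinate, so every step is either straight or
#' diagonal.
#'
#' @param p0,p1 numeric (row, col) endpoints; rounded to pixel centres.
#' @return n x 2 integer matrix of (row, col) pixels, ordered p0 -> p1.
#' @export
rasterizeLine8 <- function(p0, p1) {
  r0 <- round(p0[1]); c0 <- round(p0[2])
  r1 <- round(p1[1]); c1 <- round(p1[2])
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  n <- max(dr, dc)
  out <- matrix(0L, n + 1, 2)
  err <- dc - dr
  r <- r0; cl <- c0
  for (i in seq_len(n + 1)) {
    out[i, ] <- c(r, cl)
    e2 <- 2 * err
    if (e2 > -dr) { err <- err - dr; cl <- cl + sc }
    if (e2 < dc)  { err <- err + dc; r <- r + sr }
  }
  colnames(out) <- c("row", "col")
  out
}

#' Bilinear interpolation of image values at continuous positions
#'
#' Positions outside the image evaluate to 0.
#'
#' @param img numeric matrix.
#' @param r,c numeric vectors of row/col positions (1-based, continuous).
#' @return numeric vector of interpolated values.
#' @keywords internal
bilinearSample <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  val <- numeric(length(r))
  px <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- numeric(length(ri))
    v[ok] <- img[cbind(ri[ok], ci[ok])]
    v
  }
  val <- (1 - fr) * (1 - fc) * px(r0, c0) +
         (1 - fr) * fc       * px(r0, c0 + 1) +
         fr       * (1 - fc) * px(r0 + 1, c0) +
         fr       * fc       * px(r0 + 1, c0 + 1)
  val
}

#' Mean of the in-bounds 3x3 neighbourhood around a pixel
#' @keywords internal
boxMean3 <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  mean(img[max(1, r - 1):min(nr, r + 1), max(1, c - 1):min(nc, c + 1)])
}

#' Even-odd point-in-polygon test
#'
#' @param p numeric (row, col) point.
#' @param poly m x 2 (row, col) polygon vertices (implicitly closed).
#' @return logical.
#' @keywords internal
pointInPolygon <- function(p, poly) {
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  y <- poly[, 1]; x <- poly[, 2]
  yj <- y[j]; xj <- x[j]
  cross <- ((y > p[1]) != (yj > p[1])) &
    (p[2] < (xj - x) * (p[1] - y) / (yj - y) + x)
  sum(cross, na.rm = TRUE) %% 2 == 1
}

#' Scanline fill of a polygon into a binary mask
#'
#' Even-odd rule with half-open vertical intervals, so shared vertices are
#' counted once.
#'
#' @param poly m x 2 (row, col) vertices.
#' @param shape integer c(rows, cols).
#' @return integer matrix of 0/1.
#' @keywords internal
fillPolygon <- function(poly, shape) {
  mask <- matrix(0L, shape[1], shape[2])
  n <- nrow(poly)
  j <- c(2:n, 1)
  y1 <- poly[, 1]; x1 <- poly[, 2]
  y2 <- poly[j, 1]; x2 <- poly[j, 2]
  for (r in seq_len(shape[1])) {
    hit <- (y1 <= r) != (y2 <= r)
    if (!any(hit)) next
    xs <- x1[hit] + (r - y1[hit]) / (y2[hit] - y1[hit]) * (x2[hit] - x1[hit])
    xs <- sort(xs)
    for (k in seq(1, length(xs) - 1, by = 2)) {
      a <- ceiling(xs[k]); b <- floor(xs[k + 1])
      a <- max(1, a); b <- min(shape[2], b)
      if (a <= b) mask[r, a:b] <- 1L
    }
  }
  mask
}

## segment intersection helper (proper crossings only)
.segmentsCross <- function(a1, a2, b1, b2) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) -
    (q[2] - p[2]) * (r[1] - p[1])
  d1 <- d(b1, b2, a1); d2 <- d(b1, b2, a2)
  d3 <- d(a1, a2, b1); d4 <- d(a1, a2, b2)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

#' Does a closed polygon self-intersect?
#' @keywords internal
polygonSelfIntersects <- function(poly) {
  n <- nrow(poly)
  idx <- cbind(seq_len(n), c(2:n, 1))
  for (i in seq_len(n - 1)) {
    for (k in (i + 1):n) {
      # skip adjacent segments (share a vertex)
      if (abs(i - k) <= 1 || (i == 1 && k == n)) next
      if (.segmentsCross(poly[idx[i, 1], ], poly[idx[i, 2], ],
                         poly[idx[k, 1], ], poly[idx[k, 2], ]))
        return(TRUE)
    }
  }
  FALSE
}

#' Distance of an interior point to the perimeter of a rectangle
#' @keywords internal
distToFramePerimeter <- function(p, frame) {
  dr <- min(abs(p[1] - frame@rowRange[1]), abs(frame@rowRange[2] - p[1]))
  dc <- min(abs(p[2] - frame@colRange[1]), abs(frame@colRange[2] - p[2]))
  min(dr, dc)
}

#' Distance from a point to a line segment
#' @keywords internal
pointSegmentDistance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) 0 else max(0, min(1, sum((p - a) * ab) / len2))
  sqrt(sum((a + t * ab - p)^2))
}

#' Quantize intensities to a 16-bit grid in [0, 1]
#'
#' Synthetic images are digitized like camera data: values are clipped to
#' [0, 1] and rounded to multiples of 1/65535, which is also the exact
#' representation used by 16-bit TIFF storage.
#' @keywords internal
quantize16 <- function(x) {
  round(pmin(pmax(x, 0), 1) * 65535) / 65535
}
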