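# Independent oracles used to cross-check the package implementations.
# These deliberately use different algorithms from the package code.

# Winding-number point-in-polygon (signed angle summation). For simple
# polygons this agrees with the even-odd rule the package implements.
windingInside <- function(x, y, vx, vy) {
  n <- length(vx)
  ang <- 0
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    a1 <- atan2(vy[i] - y, vx[i] - x)
    a2 <- atan2(vy[j] - y, vx[j] - x)
    d <- a2 - a1
    if (d > pi) d <- d - 2 * pi
    if (d < -pi) d <- d + 2 * pi
    ang <- ang + d
  }
  abs(ang) > pi
}

# Brute-force rasterization: test every pixel center with the winding oracle.
bruteRaster <- function(vertices, shape) {
  grid <- matrix(FALSE, shape[1], shape[2])
  for (r in seq_len(shape[1])) {
    for (c in seq_len(shape[2])) {
      grid[r, c] <- windingInside(c - 0.5, r - 0.5, vertices[, 1], vertices[, 2])
    }
  }
  grid
}

# Random star-shaped polygon. Angles are jittered but evenly spaced, so
# every angular gap stays below pi and the polygon is guaranteed simple.
randomStarPolygon <- function(shape, rMin = 3, rMax = 10, nV = NULL) {
  if (is.null(nV)) nV <- sample(5:12, 1)
  cx <- runif(1, shape[2] * 0.25, shape[2] * 0.75)
  cy <- runif(1, shape[1] * 0.25, shape[1] * 0.75)
  th <- (seq_len(nV) - 1) * 2 * pi / nV +
    runif(nV, -0.4, 0.4) * 2 * pi / nV
  r <- runif(nV, rMin, rMax)
  PolygonROI(cbind(cx + r * cos(th), cy + r * sin(th)))
}

# Brute-force simulation of the expanding-box side rule, written directly
# from the printed procedure: start from a box 25% larger in area than the
# ROI, centered on the ROI centroid with the ROI bounding-box aspect ratio;
# each 1-px-wide side whose suprathreshold fraction is >= 10% moves outward
# one pixel (simultaneously for all four sides) until all sides fall below
# the rule or hit the border. Spillover counted by an explicit double loop.
bruteSpillover <- function(img, roiGrid, thr, initScale = 1.25,
                           sideFrac = 0.10) {
  nr <- nrow(img); nc <- ncol(img)
  idx <- which(roiGrid, arr.ind = TRUE)
  cy <- mean(idx[, 1] - 0.5); cx <- mean(idx[, 2] - 0.5)
  bbw <- max(idx[, 2]) - min(idx[, 2]) + 1
  bbh <- max(idx[, 1]) - min(idx[, 1]) + 1
  area <- initScale * nrow(idx)
  w <- sqrt(area * bbw / bbh)
  h <- area / w
  L <- max(0, floor(cx - w / 2)); R <- min(nc, ceiling(cx + w / 2))
  T <- max(0, floor(cy - h / 2)); B <- min(nr, ceiling(cy + h / 2))
  repeat {
    fl <- mean(img[(T + 1):B, L + 1] > thr)
    fr <- mean(img[(T + 1):B, R] > thr)
    ft <- mean(img[T + 1, (L + 1):R] > thr)
    fb <- mean(img[B, (L + 1):R] > thr)
    moved <- FALSE
    if (fl >= sideFrac && L > 0) { L <- L - 1; moved <- TRUE }
    if (fr >= sideFrac && R < nc) { R <- R + 1; moved <- TRUE }
    if (ft >= sideFrac && T > 0) { T <- T - 1; moved <- TRUE }
    if (fb >= sideFrac && B < nr) { B <- B + 1; moved <- TRUE }
    if (!moved) break
  }
  count <- 0L
  for (r in (T + 1):B) {
    for (c in (L + 1):R) {
      if (img[r, c] > thr && !roiGrid[r, c]) count <- count + 1L
    }
  }
  list(bounds = c(left = L, right = R, top = T, bottom = B),
       spillover = count)
}

# Random 64x64 test image: noisy background plus a few bright rectangles,
# some of which straddle the ROI boundary.
randomSpilloverImage <- function(nr = 64, nc = 64) {
  img <- matrix(pmax(0, pmin(255, round(rnorm(nr * nc, 30, 10)))), nr, nc)
  for (i in seq_len(sample(1:4, 1))) {
    r0 <- sample(1:(nr - 8), 1); c0 <- sample(1:(nc - 8), 1)
    img[r0:(r0 + sample(2:7, 1)), c0:(c0 + sample(2:7, 1))] <- 255
  }
  img
}

# Exact two-sided Mann-Whitney p-value for tiny untied samples, by full
# enumeration of rank assignments.
enumMannWhitneyP <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!any(duplicated(pooled)))
  n1 <- length(x)
  rk <- rank(pooled)
  obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2   # observed U for x
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(ix) sum(rank(pooled)[ix]) - n1 * (n1 + 1) / 2)
  pLow <- mean(us <= obs)
  pHigh <- mean(us >= obs)
  min(1, 2 * min(pLow, pHigh))
}

# Minimal SectionQuant for summary-level tests.
mkQuant <- function(idx, roiA, labeled, spill = 0L) {
  new("SectionQuant", sectionIndex = as.integer(idx),
      roiAreaPx = as.integer(roiA),
      thresholdSpec = thresholdFromPixels(c(10, 20)),
      labeledPxInRoi = as.integer(labeled), spilloverPx = as.integer(spill),
      finalBox = BoxROI(0, 1, 0, 1), backgroundBoxes = list(),
      boxAtBorder = c(left = FALSE, right = FALSE, top = FALSE,
                      bottom = FALSE))
}

# ImageJ .roi polygon record written from scratch (big-endian), so the
# package reader is checked against an independently constructed file.
writeImageJRoiBytes <- function(path, xs, ys) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("Iout", con, eos = NULL)
  writeBin(228L, con, size = 2, endian = "big")            # version
  writeBin(as.raw(c(0L, 0L)), con)                          # type = polygon, pad
  left <- min(xs); top <- min(ys)
  writeBin(as.integer(c(top, left, max(ys), max(xs), length(xs))),
           con, size = 2, endian = "big")
  writeBin(raw(64L - 18L), con)                             # header padding
  writeBin(as.integer(xs - left), con, size = 2, endian = "big")
  writeBin(as.integer(ys - top), con, size = 2, endian = "big")
}
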