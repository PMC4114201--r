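## Semi-automated injection-site quantification: background sampling,
## capped mean + 2*SD threshold, suprathreshold counting inside the nucleus
## ROI, expanding-box spillover estimation, per-brain volume summary.

#' Side length of a background sample box
#'
#' Each background box covers 1% of the image's pixels; boxes are squares
#' with side `round(sqrt(floor(0.01 * N)))`, so a 2048 x 2048 frame gives
#' 205 x 205 boxes and a 100 x 100 frame gives exact 10 x 10 boxes.
#'
#' @param nPixels total number of pixels in the image.
#' @return integer side length.
#' @export
backgroundBoxSide <- function(nPixels) {
  as.integer(round(sqrt(floor(0.01 * nPixels))))
}

#' Place the three background sample boxes
#'
#' Background is characterized from three regions, each about 1% of the
#' image area. When `positions` is omitted, boxes are placed
#' deterministically in image corners (top-left, top-right, bottom-left,
#' bottom-right order), skipping any corner whose box would intersect the
#' nucleus ROI -- mimicking an experimenter's choice of signal-free regions.
#' Supplied positions are honored even if they overlap the ROI (experimenter
#' override), with a warning.
#'
#' @param section an [ImageSection-class].
#' @param roiMask the nucleus [BinaryMask-class].
#' @param positions optional list of `c(left, top)` anchors (0-based) for
#'   the three boxes.
#' @return list of three [BoxROI-class] objects.
#' @export
placeBackgroundBoxes <- function(section, roiMask, positions = NULL) {
  d <- dim(section)
  rows <- d[1]; cols <- d[2]
  side <- backgroundBoxSide(rows * cols)
  if (side < 1L || 2L * side > min(rows, cols))
    stop("image too small for three 1%-area background boxes; use a smaller box fraction")
  grid <- maskGrid(roiMask)
  mkBox <- function(left, top)
    BoxROI(left, min(cols, left + side), top, min(rows, top + side))
  overlapsRoi <- function(b) {
    bb <- boxBounds(b)
    any(grid[(bb[["top"]] + 1L):bb[["bottom"]], (bb[["left"]] + 1L):bb[["right"]]])
  }
  if (!is.null(positions)) {
    if (length(positions) != 3L) stop("exactly three box positions are required")
    boxes <- lapply(positions, function(p) mkBox(p[1], p[2]))
    if (any(vapply(boxes, overlapsRoi, logical(1))))
      warning("a supplied background box overlaps the nucleus ROI (experimenter override)")
    return(boxes)
  }
  corners <- list(c(0L, 0L), c(cols - side, 0L), c(0L, rows - side),
                  c(cols - side, rows - side))
  boxes <- list()
  for (p in corners) {
    b <- mkBox(p[1], p[2])
    if (!overlapsRoi(b)) boxes[[length(boxes) + 1L]] <- b
    if (length(boxes) == 3L) break
  }
  if (length(boxes) < 3L)
    stop("could not place three ROI-disjoint background boxes in the image corners; supply positions or use a smaller box fraction")
  boxes
}

# Pixels of `channel` covered by a BoxROI (0-based half-open bounds).
.boxPixels <- function(channel, box) {
  bb <- boxBounds(box)
  channel[(bb[["top"]] + 1L):bb[["bottom"]], (bb[["left"]] + 1L):bb[["right"]]]
}

#' Compute the capped labeling threshold
#'
#' The threshold is the sample mean plus two sample standard deviations
#' (n - 1 denominator) of the pooled pixel set. If mean + 2*SD exceeds the
#' 8-bit maximum, the upper bound 255 - 2*SD is used instead and the result
#' is flagged as capped. A constant pixel set has SD 0 and threshold equal
#' to its mean. The pooled set is, by default, the nucleus-ROI pixels plus
#' the three background boxes in the tracer channel; `pool = "background"`
#' restricts pooling to the boxes only (a documented deviation for
#' sensitivity analysis).
#'
#' @param section an [ImageSection-class].
#' @param roiMask the nucleus [BinaryMask-class].
#' @param boxes list of three background [BoxROI-class] boxes.
#' @param channel tracer channel name (default `"tritc"`).
#' @param pool `"roi+background"` (default, the literal rule) or
#'   `"background"`.
#' @return a [ThresholdSpec-class].
#' @examples
#' \dontrun{computeThreshold(section, mask, boxes)}
#' @export
computeThreshold <- function(section, roiMask, boxes, channel = "tritc",
                             pool = c("roi+background", "background")) {
  pool <- match.arg(pool)
  ch <- getChannel(section, channel)
  px <- unlist(lapply(boxes, .boxPixels, channel = ch), use.names = FALSE)
  if (pool == "roi+background") px <- c(ch[maskGrid(roiMask)], px)
  thresholdFromPixels(px)
}

#' Threshold from a pooled pixel set
#'
#' The arithmetic core of [computeThreshold()], exposed so a pooled pixel
#' vector can be thresholded directly.
#'
#' @param pixels numeric vector of pooled intensities in \[0, 255\]
#'   (length >= 2, or >= 1 for a degenerate constant set).
#' @return a [ThresholdSpec-class].
#' @examples
#' thresholdValue(thresholdFromPixels(c(0, 0, 20, 20)))  # 33.094...
#' @export
thresholdFromPixels <- function(pixels) {
  if (length(pixels) < 1L) stop("at least one pixel is required")
  if (any(pixels < 0 | pixels > 255)) stop("intensities must lie in [0, 255]")
  m <- mean(pixels)
  s <- if (length(pixels) < 2L) 0 else stats::sd(pixels)
  thr <- m + 2 * s
  capped <- thr > 255
  if (capped) thr <- 255 - 2 * s
  thr <- min(255, max(0, thr))
  new("ThresholdSpec", mean = m, sd = s, threshold = thr, capped = capped)
}

#' Count labeled (suprathreshold) pixels inside a mask
#'
#' "Above the threshold" is strict: pixels exactly at the threshold are not
#' labeled.
#'
#' @param section an [ImageSection-class].
#' @param mask a [BinaryMask-class] congruent with the section.
#' @param threshold numeric threshold (or a [ThresholdSpec-class]).
#' @param channel channel name.
#' @return integer count.
#' @export
countLabeled <- function(section, mask, threshold, channel = "tritc") {
  ch <- getChannel(section, channel)
  if (!identical(dim(ch), dim(maskGrid(mask))))
    stop("mask dimensions do not match the section")
  if (is(threshold, "ThresholdSpec")) threshold <- thresholdValue(threshold)
  sum(ch[maskGrid(mask)] > threshold)
}

#' Mask of labeled pixels (for overlay export)
#'
#' @inheritParams countLabeled
#' @return a [BinaryMask-class] marking pixels strictly above threshold
#'   within `mask`.
#' @export
labeledMask <- function(section, mask, threshold, channel = "tritc") {
  ch <- getChannel(section, channel)
  if (is(threshold, "ThresholdSpec")) threshold <- thresholdValue(threshold)
  BinaryMask(maskGrid(mask) & ch > threshold)
}

# Initial spillover box: area = initAreaScale * ROI area, centered on the
# ROI centroid, aspect ratio taken from the ROI's bounding box, rounded
# outward to integers and clipped to the image (with a warning).
.initialSpilloverBox <- function(roiMask, shape, initAreaScale = 1.25) {
  grid <- maskGrid(roiMask)
  idx <- which(grid, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("ROI mask is empty")
  # 0-based pixel-center coordinates
  cy <- mean(idx[, 1] - 0.5)
  cx <- mean(idx[, 2] - 0.5)
  bbW <- diff(range(idx[, 2])) + 1L
  bbH <- diff(range(idx[, 1])) + 1L
  area <- initAreaScale * nrow(idx)
  w <- sqrt(area * bbW / bbH)
  h <- area / w
  left <- floor(cx - w / 2); right <- ceiling(cx + w / 2)
  top <- floor(cy - h / 2); bottom <- ceiling(cy + h / 2)
  clipped <- left < 0 || top < 0 || right > shape[2] || bottom > shape[1]
  if (clipped)
    warning("initial spillover box exceeds the image bounds; clipped")
  BoxROI(max(0, left), min(shape[2], right), max(0, top), min(shape[1], bottom))
}

#' Expanding-box estimation of tracer spillover
#'
#' Starting from a box 25% larger in area than the nucleus ROI and centered
#' on it, each of the four 1-pixel-wide sides is tested for the fraction of
#' its pixels exceeding the threshold; any side at or above the 10% rule is
#' moved outward by one pixel, independently of the others, until every
#' side's suprathreshold fraction falls below the rule or the side reaches
#' the image border (flagged). Corner pixels belong to both adjacent sides.
#' The spillover estimate is the count of suprathreshold pixels inside the
#' final box but outside the nucleus ROI.
#'
#' @param section an [ImageSection-class].
#' @param roiMask the nucleus [BinaryMask-class].
#' @param threshold numeric threshold or [ThresholdSpec-class].
#' @param channel tracer channel name.
#' @param initAreaScale initial box area as a multiple of the ROI area
#'   (default 1.25).
#' @param sideFraction expansion rule: a side expands while its
#'   suprathreshold fraction is `>= sideFraction` (default 0.10).
#' @return list with elements `box` (final [BoxROI-class]), `spilloverPx`
#'   (integer) and `atBorder` (named logical(4): side stopped at the image
#'   border while still above the rule).
#' @export
expandSpilloverBox <- function(section, roiMask, threshold, channel = "tritc",
                               initAreaScale = 1.25, sideFraction = 0.10) {
  ch <- getChannel(section, channel)
  if (is(threshold, "ThresholdSpec")) threshold <- thresholdValue(threshold)
  shape <- dim(ch)
  hot <- ch > threshold
  box <- .initialSpilloverBox(roiMask, shape, initAreaScale)
  b <- boxBounds(box)
  left <- b[["left"]]; right <- b[["right"]]
  top <- b[["top"]]; bottom <- b[["bottom"]]
  sideFrac <- function(which) {
    switch(which,
      left   = mean(hot[(top + 1L):bottom, left + 1L]),
      right  = mean(hot[(top + 1L):bottom, right]),
      top    = mean(hot[top + 1L, (left + 1L):right]),
      bottom = mean(hot[bottom, (left + 1L):right]))
  }
  atBorder <- c(left = FALSE, right = FALSE, top = FALSE, bottom = FALSE)
  repeat {
    expandable <- c(left = left > 0L, right = right < shape[2],
                    top = top > 0L, bottom = bottom < shape[1])
    frac <- vapply(c("left", "right", "top", "bottom"), sideFrac, numeric(1))
    over <- frac >= sideFraction
    atBorder <- over & !expandable
    grow <- over & expandable
    if (!any(grow)) break
    if (grow[["left"]]) left <- left - 1L
    if (grow[["right"]]) right <- right + 1L
    if (grow[["top"]]) top <- top - 1L
    if (grow[["bottom"]]) bottom <- bottom + 1L
  }
  if (any(atBorder))
    warning(sprintf("spillover box stopped at the image border on: %s",
                    paste(names(atBorder)[atBorder], collapse = ", ")))
  finalBox <- BoxROI(left, right, top, bottom)
  inBox <- matrix(FALSE, shape[1], shape[2])
  inBox[(top + 1L):bottom, (left + 1L):right] <- TRUE
  spill <- sum(hot & inBox & !maskGrid(roiMask))
  list(box = finalBox, spilloverPx = as.integer(spill), atBorder = atBorder)
}

#' Quantify one section end to end
#'
#' Composes background-box placement, threshold computation, suprathreshold
#' counting inside the nucleus ROI and expanding-box spillover estimation;
#' all intermediate values are retained in the returned object for audit.
#'
#' @param section an [ImageSection-class] containing the tracer channel.
#' @param roi the traced nucleus [PolygonROI-class] for this section.
#' @param tracerChannel tracer channel name (default `"tritc"`).
#' @param backgroundPositions optional list of three `c(left, top)` anchors
#'   for the background boxes.
#' @param pool pixel pooling rule for the threshold (see
#'   [computeThreshold()]).
#' @return a [SectionQuant-class].
#' @export
quantifySection <- function(section, roi, tracerChannel = "tritc",
                            backgroundPositions = NULL,
                            pool = c("roi+background", "background")) {
  pool <- match.arg(pool)
  mask <- rasterize(roi, dim(section))
  boxes <- placeBackgroundBoxes(section, mask, backgroundPositions)
  spec <- computeThreshold(section, mask, boxes, channel = tracerChannel,
                           pool = pool)
  labeled <- countLabeled(section, mask, spec, channel = tracerChannel)
  spill <- expandSpilloverBox(section, mask, spec, channel = tracerChannel)
  new("SectionQuant", sectionIndex = sectionIndex(section),
      roiAreaPx = as.integer(maskArea(mask)), thresholdSpec = spec,
      labeledPxInRoi = as.integer(labeled), spilloverPx = spill$spilloverPx,
      finalBox = spill$box, backgroundBoxes = boxes,
      boxAtBorder = spill$atBorder)
}

#' Summarize an injection across serial sections
#'
#' Per-section labeled and ROI areas (pixels x pixel size squared) are
#' converted to volumes by the section thickness and summed; the injection
#' accuracy is the volume percentage 100 * injected / ROI volume. The
#' epicenter is the section with the maximal labeled area fraction (robust
#' to ROI-area variation along the axis). Antero-posterior coverage is the
#' number of analyzed sections over the nucleus's total extent in sections;
#' at least 70% must be analyzed for the summary to be flagged acceptable.
#'
#' @param quants list of [SectionQuant-class] objects, one per analyzed
#'   section. Sections with zero ROI area are excluded with a warning.
#' @param thicknessUm section thickness in micrometers (default 80).
#' @param pixelSizeUm micrometers per pixel (default 0.742).
#' @param totalApExtentSections total antero-posterior extent of the
#'   nucleus, in sections; defaults to the number of analyzed sections.
#' @return an [InjectionSummary-class].
#' @export
summarizeInjection <- function(quants, thicknessUm = 80, pixelSizeUm = 0.742,
                               totalApExtentSections = length(quants)) {
  if (length(quants) == 0L) stop("at least one section is required")
  if (thicknessUm <= 0 || pixelSizeUm <= 0)
    stop("thickness and pixel size must be positive")
  zero <- vapply(quants, function(q) roiAreaPx(q) == 0L, logical(1))
  if (any(zero)) {
    warning(sprintf("%d section(s) with zero ROI area excluded", sum(zero)))
    quants <- quants[!zero]
    if (length(quants) == 0L) stop("no section with a non-empty ROI")
  }
  pxArea <- pixelSizeUm^2
  df <- data.frame(
    section_index = vapply(quants, sectionIndex, integer(1)),
    roi_area_px = vapply(quants, roiAreaPx, integer(1)),
    labeled_px = vapply(quants, labeledPx, integer(1)),
    spillover_px = vapply(quants, spilloverPx, integer(1))
  )
  df$labeled_fraction <- df$labeled_px / df$roi_area_px
  df$labeled_volume_um3 <- df$labeled_px * pxArea * thicknessUm
  df$roi_volume_um3 <- df$roi_area_px * pxArea * thicknessUm
  volPct <- 100 * sum(df$labeled_volume_um3) / sum(df$roi_volume_um3)
  epi <- which.max(df$labeled_fraction)
  new("InjectionSummary",
      volumeFractionPct = volPct,
      epicenterSectionIndex = df$section_index[epi],
      epicenterAreaPct = 100 * df$labeled_fraction[epi],
      apCoverageFraction = length(quants) / totalApExtentSections,
      coverageOk = length(quants) / totalApExtentSections >= 0.70,
      totalSpilloverVolumeUm3 = sum(df$spillover_px) * pxArea * thicknessUm,
      perSection = {
        ps <- df[order(df$section_index), , drop = FALSE]
        rownames(ps) <- NULL
        ps
      })
}
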