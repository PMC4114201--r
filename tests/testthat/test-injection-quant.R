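test_that("threshold follows the capped mean + 2*SD rule", {
  t1 <- thresholdFromPixels(rep(10, 5))
  expect_equal(thresholdValue(t1), 10)           # constant set: sd = 0
  expect_false(isCapped(t1))

  t2 <- thresholdFromPixels(c(0, 0, 20, 20))     # sample SD, n - 1
  expect_equal(t2@mean, 10)
  expect_equal(t2@sd, sqrt(400 / 3))
  expect_equal(thresholdValue(t2), 10 + 2 * sqrt(400 / 3), tolerance = 1e-12)
  expect_false(isCapped(t2))

  t3 <- thresholdFromPixels(c(160, 200, 240))    # mean 200, sd 40 exactly
  expect_equal(t3@mean, 200)
  expect_equal(t3@sd, 40)
  expect_equal(thresholdValue(t3), 175)          # 255 - 2 * 40
  expect_true(isCapped(t3))

  expect_error(thresholdFromPixels(numeric()), "at least one")
  expect_error(thresholdFromPixels(c(10, 300)), "\\[0, 255\\]")
})

test_that("threshold is equivariant under constant intensity shifts (below the cap)", {
  set.seed(5)
  for (i in 1:20) {
    px <- sample(0:80, 50, replace = TRUE)
    c0 <- sample(1:100, 1)
    t0 <- thresholdFromPixels(px)
    t1 <- thresholdFromPixels(px + c0)
    if (!isCapped(t0) && !isCapped(t1))
      expect_equal(thresholdValue(t1), thresholdValue(t0) + c0,
                   tolerance = 1e-9)
  }
})

test_that("threshold pooling switch changes the pooled set as documented", {
  img <- matrix(20, 100, 100)
  roi <- PolygonROI(cbind(c(40, 60, 60, 40), c(40, 40, 60, 60)))
  mask <- rasterize(roi, c(100, 100))
  img[maskGrid(mask)] <- 200   # bright ROI
  sec <- ImageSection(list(tritc = img))
  boxes <- placeBackgroundBoxes(sec, mask)
  tLit <- computeThreshold(sec, mask, boxes)
  tBg <- computeThreshold(sec, mask, boxes, pool = "background")
  expect_equal(thresholdValue(tBg), 20)          # constant background
  expect_gt(thresholdValue(tLit), thresholdValue(tBg))
})

test_that("background boxes cover 1% of pixels each and avoid the ROI", {
  expect_equal(backgroundBoxSide(2048^2), 205L)
  expect_equal(backgroundBoxSide(100^2), 10L)

  img <- matrix(0, 100, 100)
  roi <- PolygonROI(cbind(c(2, 20, 20, 2), c(2, 2, 20, 20)))  # corner ROI
  sec <- ImageSection(list(tritc = img))
  mask <- rasterize(roi, c(100, 100))
  boxes <- placeBackgroundBoxes(sec, mask)
  expect_length(boxes, 3)
  expect_true(all(vapply(boxes, boxArea, integer(1)) == 100L))
  # pairwise disjoint and ROI-disjoint
  occ <- matrix(0L, 100, 100)
  for (b in boxes) {
    bb <- boxBounds(b)
    occ[(bb[["top"]] + 1):bb[["bottom"]], (bb[["left"]] + 1):bb[["right"]]] <-
      occ[(bb[["top"]] + 1):bb[["bottom"]], (bb[["left"]] + 1):bb[["right"]]] + 1L
  }
  expect_true(all(occ <= 1L))
  expect_equal(sum(occ[maskGrid(mask)]), 0L)

  # experimenter override: accepted with a warning
  expect_warning(placeBackgroundBoxes(sec, mask,
                                      positions = list(c(0, 0), c(50, 50),
                                                       c(80, 80))),
                 "override")
})

test_that("labeled-pixel counting is strict and matches an exhaustive loop", {
  img <- matrix(100, 10, 10)
  sec <- ImageSection(list(tritc = img))
  mask <- BinaryMask(matrix(TRUE, 10, 10))
  expect_equal(countLabeled(sec, mask, 100), 0)   # at threshold: not labeled

  img2 <- matrix(0, 10, 10)
  img2[1:7] <- 255
  grid <- matrix(FALSE, 10, 10); grid[1:50] <- TRUE
  expect_equal(countLabeled(ImageSection(list(tritc = img2)),
                            BinaryMask(grid), 100), 7)

  set.seed(7)
  img3 <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  grid3 <- matrix(runif(64 * 64) < 0.4, 64, 64)
  want <- 0L
  for (r in 1:64) for (c in 1:64)
    if (grid3[r, c] && img3[r, c] > 127.5) want <- want + 1L
  expect_equal(countLabeled(ImageSection(list(tritc = img3)),
                            BinaryMask(grid3), 127.5), want)

  expect_error(countLabeled(ImageSection(list(tritc = img3)),
                            BinaryMask(matrix(TRUE, 5, 5)), 10),
               "dimensions")
})

test_that("spillover box stays at its initial bounds when nothing exceeds threshold", {
  img <- matrix(10, 64, 64)
  sec <- ImageSection(list(tritc = img))
  roi <- randomStarPolygon(c(64, 64), rMin = 8, rMax = 14)
  mask <- rasterize(roi, c(64, 64))
  res <- expandSpilloverBox(sec, mask, 50)
  want <- bruteSpillover(img, maskGrid(mask), 50)
  expect_equal(boxBounds(res$box), want$bounds)
  expect_equal(res$spilloverPx, 0L)
  expect_false(any(res$atBorder))
})

test_that("a bright bar on one side expands only that side past the bar", {
  img <- matrix(0, 64, 64)
  roi <- PolygonROI(cbind(c(24, 40, 40, 24), c(24, 24, 40, 40)))
  mask <- rasterize(roi, c(64, 64))
  # vertical bright bar (1-based cols 41:45) crossing the initial right
  # side of the box, fully outside the ROI (ROI occupies cols 25:40); the
  # bar rows avoid the top/bottom strips, which share corner pixels with
  # the vertical sides
  img[26:39, 41:45] <- 255
  sec <- ImageSection(list(tritc = img))
  res <- expandSpilloverBox(sec, mask, 100)
  init <- tracequant:::.initialSpilloverBox(mask, c(64, 64))
  bi <- boxBounds(init); bf <- boxBounds(res$box)
  expect_equal(bf[["left"]], bi[["left"]])      # only the right side moves
  expect_equal(bf[["top"]], bi[["top"]])
  expect_equal(bf[["bottom"]], bi[["bottom"]])
  expect_gt(bf[["right"]], 45L)                 # expanded past the bar
  # spillover = bar pixels inside the final box (all outside the ROI)
  expect_equal(res$spilloverPx,
               sum(img[(bf[["top"]] + 1):bf[["bottom"]],
                       (bf[["left"]] + 1):bf[["right"]]] > 100))
  # cross-check against the brute-force side-rule simulation
  want <- bruteSpillover(img, maskGrid(mask), 100)
  expect_equal(boxBounds(res$box), want$bounds)
  expect_equal(res$spilloverPx, want$spillover)
})

test_that("a side blocked by the image border stops there and is flagged", {
  img <- matrix(0, 64, 64)
  roi <- PolygonROI(cbind(c(24, 40, 40, 24), c(24, 24, 40, 40)))
  mask <- rasterize(roi, c(64, 64))
  img[, 41:64] <- 255                           # bright through to the right border
  sec <- ImageSection(list(tritc = img))
  expect_warning(res <- expandSpilloverBox(sec, mask, 100), "border")
  expect_equal(boxBounds(res$box)[["right"]], 64L)
  expect_true(res$atBorder[["right"]])
  want <- suppressWarnings(bruteSpillover(img, maskGrid(mask), 100))
  expect_equal(boxBounds(res$box), want$bounds)
  expect_equal(res$spilloverPx, want$spillover)
})

test_that("section quantification closes the loop on constructed images", {
  # blank section: the 2-SD rule labels only the Gaussian upper tail
  g <- generateInjectionSeries(nSections = 1, fractionProfile = 0,
                               backgroundSd = 5, seed = 31)
  q <- quantifySection(g$sections[[1]], g$rois[[1]])
  expect_lt(labeledPx(q) / roiAreaPx(q), 0.05)

  # saturated ROI: cap rule fires and nearly the whole ROI is labeled
  img <- matrix(20, 128, 128)
  roi <- PolygonROI(cbind(c(40, 90, 90, 40), c(40, 40, 90, 90)))
  mask <- rasterize(roi, c(128, 128))
  img[maskGrid(mask)] <- 255
  sec <- ImageSection(list(tritc = img))
  q2 <- quantifySection(sec, roi)
  expect_true(isCapped(thresholdSpec(q2)))
  expect_gt(labeledPx(q2) / roiAreaPx(q2), 0.99)
})

test_that("injection summary arithmetic, epicenter and the 70% coverage rule", {
  s <- summarizeInjection(list(mkQuant(1, 1000, 100)),
                          totalApExtentSections = 1)
  expect_equal(volumeFractionPct(s), 10)
  expect_equal(epicenterAreaPct(s), 10)
  expect_equal(epicenterSectionIndex(s), 1L)

  s2 <- summarizeInjection(list(mkQuant(1, 1000, 200), mkQuant(2, 1000, 0)),
                           totalApExtentSections = 2)
  expect_equal(volumeFractionPct(s2), 10)       # (200 + 0) / 2000
  expect_equal(epicenterSectionIndex(s2), 1L)
  expect_equal(epicenterAreaPct(s2), 20)

  s3 <- summarizeInjection(lapply(1:7, function(i) mkQuant(i, 500, 10)),
                           totalApExtentSections = 10)
  expect_equal(unname(apCoverage(s3)["fraction"]), 0.7)
  expect_true(unname(apCoverage(s3)["ok"]) == 1)  # "at least 70%" boundary
  s4 <- summarizeInjection(lapply(1:6, function(i) mkQuant(i, 500, 10)),
                           totalApExtentSections = 10)
  expect_false(unname(apCoverage(s4)["ok"]) == 1)

  # spillover volume bookkeeping: px * pixel area * thickness
  s5 <- summarizeInjection(list(mkQuant(1, 100, 10, spill = 5)),
                           thicknessUm = 80, pixelSizeUm = 0.742)
  expect_equal(spilloverVolumeUm3(s5), 5 * 0.742^2 * 80)
})

test_that("injection summary is permutation-invariant in section order", {
  qs <- list(mkQuant(1, 900, 80), mkQuant(2, 1100, 300), mkQuant(3, 1000, 50))
  a <- summarizeInjection(qs, totalApExtentSections = 4)
  b <- summarizeInjection(qs[c(3, 1, 2)], totalApExtentSections = 4)
  expect_equal(volumeFractionPct(a), volumeFractionPct(b))
  expect_equal(epicenterSectionIndex(a), epicenterSectionIndex(b))
  expect_equal(perSection(a), perSection(b))

  expect_warning(
    s <- summarizeInjection(list(mkQuant(1, 1000, 100), mkQuant(2, 0, 0)),
                            totalApExtentSections = 2),
    "zero ROI area")
  expect_equal(volumeFractionPct(s), 10)
})
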