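test_that("generators are pure functions of parameters plus seed", {
  a <- generateInjectionSeries(nSections = 2, seed = 9)
  b <- generateInjectionSeries(nSections = 2, seed = 9)
  expect_identical(lapply(a$sections, getChannel, name = "tritc"),
                   lapply(b$sections, getChannel, name = "tritc"))
  expect_identical(a$truth, b$truth)
  c <- generateInjectionSeries(nSections = 2, seed = 10)
  expect_false(identical(getChannel(a$sections[[1]], "tritc"),
                         getChannel(c$sections[[1]], "tritc")))

  ca <- generateColocCells(5, rho = 0.3, seed = 21)
  cb <- generateColocCells(5, rho = 0.3, seed = 21)
  expect_identical(channelNames(ca$stack), c("gfp", "red"))
  expect_identical(getChannel(ca$stack, "gfp"), getChannel(cb$stack, "gfp"))

  ea <- generateIpscExperiment(seed = 33)
  eb <- generateIpscExperiment(seed = 33)
  expect_identical(ea$records, eb$records)

  # the generators must not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generateInjectionSeries(nSections = 1, seed = 2))
  expect_identical(runif(1), before)
})

test_that("noiseless injection generation closes the loop exactly", {
  g <- generateInjectionSeries(nSections = 1, fractionProfile = 0.10,
                               backgroundSd = 0, seed = 4)
  q <- quantifySection(g$sections[[1]], g$rois[[1]])
  expect_equal(labeledPx(q) / roiAreaPx(q),
               g$truth$per_section$fraction[1])
  expect_equal(g$truth$per_section$labeled_px[1],
               round(0.10 * g$truth$per_section$roi_area_px[1]))
})

test_that("injection truth volume fraction is the area-weighted mean of section fractions", {
  profile <- seq(0.08, 0.30, length.out = 6)
  g <- generateInjectionSeries(nSections = 6, fractionProfile = profile,
                               seed = 12)
  ps <- g$truth$per_section
  # oracle: direct weighted mean of realized per-section fractions
  expect_equal(g$truth$volume_fraction,
               sum(ps$fraction * ps$roi_area_px) / sum(ps$roi_area_px))
  expect_true(all(abs(ps$fraction - profile) < 0.001))
})

test_that("injection generator rejects unattainable parameters", {
  expect_error(generateInjectionSeries(nSections = 2,
                                       fractionProfile = c(0.5, 1.2),
                                       seed = 1),
               "\\[0, 1\\]")
  expect_error(generateInjectionSeries(nSections = 5, volumeFraction = 0.9,
                                       seed = 1),
               "unattainable")
  expect_error(generateInjectionSeries(coreIntensity = 30, backgroundMean = 20,
                                       backgroundSd = 5, seed = 1),
               "separability")
})

test_that("coloc generator hits the requested pixel correlation and packs safely", {
  # one large cell (~10^4 px) converges to the generating rho
  for (rho in c(-0.6, 0, 0.7)) {
    g <- generateColocCells(1, rho = rho, cellRadiusPx = 57,
                            fieldShape = c(140, 140), seed = 8)
    px <- extractCellPixels(g$stack, g$cells[[1]])
    expect_gt(length(px$A), 1e4)
    expect_lt(abs(cor(px$A, px$B) - rho), 0.05)
  }

  expect_error(generateColocCells(500, rho = 0, cellRadiusPx = 10,
                                  fieldShape = c(100, 100), seed = 1),
               "at most \\d+ fit")

  # cell masks are pairwise disjoint in the field
  g <- generateColocCells(12, rho = 0.5, seed = 19)
  occ <- matrix(0L, dim(g$stack)[1], dim(g$stack)[2])
  for (cell in g$cells) {
    b <- cellBounds(cell)
    sub <- occ[(b[["ymin"]] + 1):b[["ymax"]], (b[["xmin"]] + 1):b[["xmax"]]]
    occ[(b[["ymin"]] + 1):b[["ymax"]], (b[["xmin"]] + 1):b[["xmax"]]] <-
      sub + cell@mask[, , 1]
  }
  expect_true(all(occ <= 1L))
})

test_that("IPSC generator arithmetic is exact in the noiseless limit", {
  g <- generateIpscExperiment(nCellsPerGroup = c(young = 2, adult = 2),
                              groupFractions = c(young = 0.24, adult = 0.06),
                              totalAmpMeanPA = 100, noiseCv = 0, seed = 2)
  young <- g$records[g$records$group == "young", ]
  expect_equal(young$amp_total_pA, c(100, 100))
  expect_equal(young$amp_after_strychnine_pA, c(24, 24))
  expect_equal(young$amp_after_both_pA, c(0, 0))

  # f = 0: residual after strychnine equals the leak
  g0 <- generateIpscExperiment(nCellsPerGroup = c(a = 2, b = 2),
                               groupFractions = c(a = 0, b = 0.5),
                               totalAmpMeanPA = 200, noiseCv = 0,
                               leakPA = 10, seed = 2)
  a <- g0$records[g0$records$group == "a", ]
  expect_equal(a$amp_after_strychnine_pA, c(10, 10))

  expect_error(generateIpscExperiment(groupFractions = c(p14 = 1.2, "p55+" = 0),
                                      seed = 1),
               "\\[0, 1\\]")
})
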