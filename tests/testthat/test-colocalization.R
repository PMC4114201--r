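test_that("cell pixel extraction respects crop bounds, masks and ordering", {
  A <- array(seq_len(4 * 4 * 2) %% 256, c(4, 4, 2))
  B <- (A + 10) %% 256
  stack <- ImageStack(list(gfp = A, red = B))

  roi <- CellROI(0, 2, 0, 2, 0, 1)
  px <- extractCellPixels(stack, roi)
  expect_length(px$A, 4)                      # 2 x 2 x 1 crop
  expect_length(px$B, 4)
  # pixel order is consistent between channels
  expect_equal((px$A + 10) %% 256, px$B)

  m <- array(FALSE, c(2, 2, 1)); m[c(1, 2, 4)] <- TRUE
  roiM <- CellROI(0, 2, 0, 2, 0, 1, mask = m)
  expect_length(extractCellPixels(stack, roiM)$A, 3)

  expect_error(extractCellPixels(stack, CellROI(2, 6, 0, 2, 0, 1)),
               "outside the stack")
  # congruence of channels is enforced at stack construction
  expect_error(ImageStack(list(gfp = A, red = array(0, c(3, 4, 2)))),
               "identical dimensions")
})

test_that("PDM matches hand arithmetic", {
  expect_equal(computePdm(c(0, 2), c(0, 2)), c(1, 1))     # means = 1
  expect_equal(computePdm(c(0, 2), c(2, 0)), c(-1, -1))
  expect_equal(computePdm(rep(5, 4), c(1, 2, 3, 4)), rep(0, 4))
  expect_error(computePdm(1:3, 1:4), "equal length")
})

test_that("ICQ attains its analytic extremes and a near-zero null", {
  A <- c(0, 10, 50, 200, 255, 3, 77)
  r <- computeIcq(A, A)
  expect_equal(icqValue(r), 0.5)
  expect_equal(icqValue(computeIcq(A, 255 - A)), -0.5)

  set.seed(123)
  u <- sample(0:255, 1e6, replace = TRUE)
  v <- sample(0:255, 1e6, replace = TRUE)
  expect_lt(abs(icqValue(computeIcq(u, v))), 0.005)

  expect_error(computeIcq(rep(7, 5), c(1, 2, 3, 4, 5)), "constant channel A")
  expect_error(computeIcq(c(1, 2), c(3)), "equal length")
  expect_error(computeIcq(c(1), c(3)), "at least 2")
})

test_that("ICQ is symmetric and invariant under positive affine rescaling", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(20:200, 1)
    A <- sample(0:255, n, replace = TRUE)
    B <- sample(0:255, n, replace = TRUE)
    r <- computeIcq(A, B)
    expect_equal(icqValue(computeIcq(B, A)), icqValue(r))   # symmetry
    a1 <- runif(1, 0.1, 5); b1 <- runif(1, -20, 20)
    a2 <- runif(1, 0.1, 5); b2 <- runif(1, -20, 20)
    expect_equal(icqValue(computeIcq(a1 * A + b1, a2 * B + b2)), icqValue(r))
    expect_lte(abs(icqValue(r)), 0.5)
  }
})

test_that("ICQ zero-PDM bookkeeping matches its reported counts", {
  # constructed so some pixels sit exactly at a channel mean
  A <- c(0, 2, 1, 1, 4, 0)   # mean 4/3: no exact hits
  B <- c(1, 3, 2, 2, 3, 1)   # mean 2: two exact hits -> PDM 0
  r <- computeIcq(A, B)
  expect_equal(r@nPdmZero, 2L)
  expect_equal(icqValue(r), r@nPdmPositive / (r@nPixels - r@nPdmZero) - 0.5)
})

test_that("mean ICQ increases with the generating correlation", {
  means <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(rho) {
    g <- generateColocCells(30, rho = rho, seed = 101)
    mean(icqTable(g$stack, g$cells)$icq)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  # bivariate-normal prediction: ICQ ~ asin(rho) / pi before discretization
  expect_lt(abs(means[3] - asin(0.5) / pi), 0.04)
})

test_that("the colocalization color map is the normalized PDM", {
  set.seed(9)
  A <- matrix(sample(0:255, 256, TRUE), 16, 16)
  B <- matrix(sample(0:255, 256, TRUE), 16, 16)
  res <- nmdpMap(A, B)
  # brute-force per-pixel formula
  want <- matrix(0, 16, 16)
  for (r in 1:16) for (c in 1:16) {
    want[r, c] <- (A[r, c] - mean(A)) * (B[r, c] - mean(B)) /
      ((max(A) - mean(A)) * (max(B) - mean(B)))
  }
  want[want > 1] <- 1
  want[want < -1] <- -1
  expect_equal(res$map, want)
  expect_identical(res$hotspots, res$map > 0)
  # sign pattern equals the PDM sign pattern pixel-for-pixel
  pdm <- matrix(computePdm(as.vector(A), as.vector(B)), 16, 16)
  expect_identical(sign(res$map), sign(pdm))

  # anchors: joint maximum -> 1; a pixel at both channel means -> 0
  A2 <- matrix(c(0, 10, 20, 10), 2, 2)   # mean 10 attained
  B2 <- matrix(c(0, 30, 60, 30), 2, 2)
  res2 <- nmdpMap(A2, B2)
  expect_equal(res2$map[1, 2], 1)        # (A_max, B_max) pixel
  expect_equal(res2$map[2, 1], 0)        # pixel at the channel means
  expect_error(nmdpMap(matrix(5, 2, 2), B2), "constant")
  expect_error(nmdpMap(A2, matrix(0, 3, 3)), "congruent")
})

test_that("group comparison uses the exact rank-sum distribution when it should", {
  g <- compareIcqGroups(c(1, 2, 3), c(10, 11, 12))
  expect_equal(pValue(g), 0.1)                       # 2 * 1/20, exact
  expect_equal(pValue(g), enumMannWhitneyP(c(1, 2, 3), c(10, 11, 12)))
  expect_match(g@method, "exact")

  set.seed(15)
  x <- runif(8); y <- runif(9) + 0.2
  expect_equal(pValue(compareIcqGroups(x, y)), enumMannWhitneyP(x, y))

  # identical (tied) groups: approximation path, p = 1
  gid <- compareIcqGroups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(pValue(gid), 1)
  expect_match(gid@method, "approximation")

  # exchanging labels leaves the p-value unchanged
  expect_equal(pValue(compareIcqGroups(y, x)), pValue(compareIcqGroups(x, y)))

  # large samples switch to the normal approximation
  big <- compareIcqGroups(runif(30), runif(25))
  expect_match(big@method, "approximation")

  expect_error(compareIcqGroups(1, c(1, 2)), "at least 2")
})

test_that("Li's per-cell sign test flags dependent staining", {
  set.seed(4)
  A <- sample(0:255, 500, replace = TRUE)
  noisyB <- pmin(255, pmax(0, A + sample(-20:20, 500, TRUE)))
  expect_lt(icqSignTest(A, noisyB)$p.value, 1e-6)
  u <- sample(0:255, 500, replace = TRUE)
  expect_gt(icqSignTest(A, u)$p.value, 1e-4)
})
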