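## Seedable synthetic-data generators with ground-truth manifests. Each is a
## pure function of its parameter set plus seed; every downstream analysis
## stage can be validated closed-loop against the manifest.

# Nucleus-shaped polygon: a laterally elongated ellipse with smooth
# low-order radial wobble (always a simple star-shaped polygon).
.nucleusPolygon <- function(center, areaPx, elongation = 1.6, nVertices = 40,
                            wobble = 0.12, label = "nucleus") {
  theta <- seq(0, 2 * pi, length.out = nVertices + 1)[-(nVertices + 1)]
  b <- sqrt(areaPx / (pi * elongation))
  a <- b * elongation
  r0 <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  k <- 2:4
  amp <- stats::runif(3, 0, wobble)
  ph <- stats::runif(3, 0, 2 * pi)
  w <- 1 + amp[1] * cos(k[1] * theta + ph[1]) +
    amp[2] * cos(k[2] * theta + ph[2]) + amp[3] * cos(k[3] * theta + ph[3])
  PolygonROI(cbind(center[1] + r0 * w * cos(theta),
                   center[2] + r0 * w * sin(theta)), label = label)
}

# Smooth scalar field over the grid: negative squared distance to a focus
# point plus low-frequency cosine perturbation. Thresholding its top-k
# pixels inside a mask yields an irregular but contiguous blob with exact
# area control.
.blobField <- function(rows, cols, focus, scalePx) {
  X <- matrix(rep(seq_len(cols) - 0.5, each = rows), rows, cols)
  Y <- matrix(rep(seq_len(rows) - 0.5, times = cols), rows, cols)
  f <- -((X - focus[1])^2 + (Y - focus[2])^2)
  for (i in 1:3) {
    fx <- stats::runif(1, 0.5, 1.5) / scalePx
    fy <- stats::runif(1, 0.5, 1.5) / scalePx
    ph <- stats::runif(1, 0, 2 * pi)
    f <- f + 0.3 * scalePx^2 * cos(2 * pi * (fx * X + fy * Y) + ph)
  }
  f
}

#' Generate a synthetic serial-section injection series
#'
#' Emulates epifluorescent serial sections through a tracer-injected
#' nucleus: each section carries a nucleus-shaped polygon ROI, a contiguous
#' injected blob at `coreIntensity` occupying a stated fraction of the ROI,
#' optional spillover lobes placed just outside a randomly chosen arc of
#' the ROI boundary, and additive Gaussian background noise, discretized
#' (round half up) and clipped to \[0, 255\]. A Nissl-like delineation
#' channel marks the nucleus. The per-section injected fraction follows
#' `fractionProfile` if given; otherwise a bell-shaped antero-posterior
#' profile is scaled so the ground-truth volume fraction equals
#' `volumeFraction`. Identical seeds give bit-identical output.
#'
#' @param nSections number of serial sections (default 10).
#' @param fieldShape image (rows, cols); default `c(256, 256)`, a
#'   downscaled survey frame that keeps simulation tractable.
#' @param roiAreaFraction nucleus ROI area as a fraction of the frame
#'   (default 0.04).
#' @param volumeFraction target ground-truth injected volume fraction of
#'   the nucleus (default 0.14). Ignored when `fractionProfile` is given.
#' @param fractionProfile optional numeric vector (length `nSections`) of
#'   per-section injected area fractions in \[0, 1\].
#' @param coreIntensity intensity of injected pixels before noise
#'   (default 200). Must exceed
#'   `backgroundMean + separabilityFactor * backgroundSd`.
#' @param backgroundMean,backgroundSd background level and additive
#'   Gaussian noise SD (defaults 20 and 5).
#' @param spilloverFraction spillover lobe area per section as a fraction
#'   of the ROI area (default 0: no spillover).
#' @param separabilityFactor guard requiring
#'   `coreIntensity > backgroundMean + separabilityFactor * backgroundSd`
#'   (default 4).
#' @param pixelSizeUm,thicknessUm section geometry metadata.
#' @param seed integer RNG seed.
#' @return list with `sections` (list of [ImageSection-class] with channels
#'   `tritc`, `nissl`), `rois` (list of [PolygonROI-class]) and `truth`
#'   (ground-truth manifest: per-section realized fractions and spillover
#'   counts, the global volume fraction, and the generator parameters).
#' @export
generateInjectionSeries <- function(nSections = 10, fieldShape = c(256, 256),
                                    roiAreaFraction = 0.04,
                                    volumeFraction = 0.14,
                                    fractionProfile = NULL,
                                    coreIntensity = 200, backgroundMean = 20,
                                    backgroundSd = 5, spilloverFraction = 0,
                                    separabilityFactor = 4,
                                    pixelSizeUm = 0.742, thicknessUm = 80,
                                    seed = 1L) {
  rows <- fieldShape[1]; cols <- fieldShape[2]
  if (coreIntensity <= backgroundMean + separabilityFactor * backgroundSd)
    stop("core intensity must exceed backgroundMean + separabilityFactor * backgroundSd")
  if (!is.null(fractionProfile)) {
    if (length(fractionProfile) != nSections)
      stop("fractionProfile must have one entry per section")
    if (any(fractionProfile < 0 | fractionProfile > 1))
      stop("section fractions must lie in [0, 1]")
  }
  withSeed(seed, {
    targetArea <- roiAreaFraction * rows * cols
    rois <- vector("list", nSections)
    masks <- vector("list", nSections)
    areas <- integer(nSections)
    for (s in seq_len(nSections)) {
      ctr <- c(cols / 2 + stats::runif(1, -5, 5),
               rows / 2 + stats::runif(1, -5, 5))
      rois[[s]] <- .nucleusPolygon(ctr, targetArea, label = "MNTB")
      masks[[s]] <- rasterize(rois[[s]], c(rows, cols))
      areas[s] <- maskArea(masks[[s]])
    }
    if (is.null(fractionProfile)) {
      s <- seq_len(nSections)
      bell <- exp(-((s - (nSections + 1) / 2) / (0.3 * nSections))^2)
      fractions <- volumeFraction * sum(areas) * bell / sum(bell * areas)
      if (any(fractions > 1))
        stop(sprintf(
          "volumeFraction %.3g unattainable with this profile; maximum attainable is %.3g",
          volumeFraction, volumeFraction / max(fractions)))
    } else {
      fractions <- fractionProfile
    }
    sections <- vector("list", nSections)
    perSection <- data.frame(section_index = seq_len(nSections),
                             roi_area_px = areas,
                             labeled_px = NA_integer_,
                             fraction = NA_real_,
                             spillover_px = NA_integer_)
    for (s in seq_len(nSections)) {
      grid <- maskGrid(masks[[s]])
      A <- areas[s]
      k <- as.integer(round(fractions[s] * A))
      if (k > A)
        stop(sprintf("section %d: fraction %.3g unattainable (max 1)", s,
                     fractions[s]))
      tritc <- matrix(backgroundMean, rows, cols)
      if (k > 0L) {
        inRoi <- which(grid)
        focusIdx <- inRoi[sample.int(length(inRoi), 1L)]
        focus <- c((focusIdx - 1L) %/% rows + 0.5, (focusIdx - 1L) %% rows + 0.5)
        f <- .blobField(rows, cols, focus, sqrt(A / pi))
        blob <- inRoi[order(f[inRoi], decreasing = TRUE)[seq_len(k)]]
        tritc[blob] <- coreIntensity
      }
      kSp <- as.integer(round(spilloverFraction * A))
      if (kSp > 0L) {
        outRoi <- which(!grid)
        # seed the lobe just outside a random boundary arc: walk outward
        # from the centroid at a random angle until leaving the ROI
        idx <- which(grid, arr.ind = TRUE)
        cy <- mean(idx[, 1] - 0.5); cx <- mean(idx[, 2] - 0.5)
        ang <- stats::runif(1, 0, 2 * pi)
        step <- 0
        repeat {
          step <- step + 1
          px <- floor(cx + step * cos(ang)) + 1L
          py <- floor(cy + step * sin(ang)) + 1L
          if (px < 1L || px > cols || py < 1L || py > rows) break
          if (!grid[py, px]) break
        }
        px <- min(max(px, 1L), cols); py <- min(max(py, 1L), rows)
        ox <- (outRoi - 1L) %/% rows + 1L
        oy <- (outRoi - 1L) %% rows + 1L
        d2 <- (ox - px)^2 + (oy - py)^2
        lobe <- outRoi[order(d2)[seq_len(min(kSp, length(outRoi)))]]
        tritc[lobe] <- coreIntensity
      }
      nissl <- matrix(backgroundMean, rows, cols)
      nissl[grid] <- 90  # Nissl-like delineation of the nucleus
      n <- rows * cols
      tritc <- clip255(roundHalfUp(tritc + stats::rnorm(n, 0, backgroundSd)))
      nissl <- clip255(roundHalfUp(nissl + stats::rnorm(n, 0, backgroundSd)))
      sections[[s]] <- ImageSection(list(tritc = tritc, nissl = nissl),
                                    pixelSizeUm = pixelSizeUm,
                                    thicknessUm = thicknessUm,
                                    sectionIndex = s)
      perSection$labeled_px[s] <- k
      perSection$fraction[s] <- k / A
      perSection$spillover_px[s] <- kSp
    }
    truth <- list(
      per_section = perSection,
      # thickness is uniform here, so this is the thickness-weighted mean of
      # section fractions weighted additionally by ROI area -- exactly the
      # quantity the volume-percentage estimator measures
      volume_fraction = sum(perSection$labeled_px) / sum(perSection$roi_area_px),
      params = list(nSections = nSections, fieldShape = fieldShape,
                    roiAreaFraction = roiAreaFraction,
                    coreIntensity = coreIntensity,
                    backgroundMean = backgroundMean,
                    backgroundSd = backgroundSd,
                    spilloverFraction = spilloverFraction,
                    pixelSizeUm = pixelSizeUm, thicknessUm = thicknessUm,
                    seed = seed)
    )
    list(sections = sections, rois = rois, truth = truth)
  })
}

#' Generate a synthetic two-channel field of cells with known correlation
#'
#' Emulates two-channel (e.g. GFP / immunolabel) images of labeled somata:
#' non-overlapping disk-shaped cells on a noisy background. Within each
#' cell, the two channels are drawn from a bivariate Gaussian with Pearson
#' correlation `rho` (a Gaussian copula over Gaussian marginals with mean
#' `cellMean` and SD `cellSd`), then discretized round-half-up and clipped
#' to \[0, 255\]; outside cells the channels are independent background
#' noise. Cells are placed on a jittered grid so disks never overlap.
#'
#' @param nCells number of cells (>= 1).
#' @param rho generating channel correlation in \[-1, 1\].
#' @param cellRadiusPx disk radius in pixels (default 6).
#' @param fieldShape image (rows, cols); default `c(256, 256)`.
#' @param nPlanes number of z planes (cells span all planes; default 1).
#' @param backgroundMean,backgroundSd background noise parameters
#'   (defaults 30 and 8).
#' @param cellMean,cellSd marginal intensity distribution inside cells
#'   (defaults 120 and 30).
#' @param group group label stamped on every cell (e.g. `"p14"`).
#' @param seed integer RNG seed.
#' @return list with `stack` (two-channel [ImageStack-class], channels
#'   `gfp`, `red`), `cells` (list of [CellROI-class] with disk masks) and
#'   `truth` (per-cell generating rho, bounds, group, parameters).
#' @export
generateColocCells <- function(nCells, rho, cellRadiusPx = 6,
                               fieldShape = c(256, 256), nPlanes = 1,
                               backgroundMean = 30, backgroundSd = 8,
                               cellMean = 120, cellSd = 30, group = "",
                               seed = 1L) {
  if (nCells < 1L) stop("nCells must be at least 1")
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]")
  rows <- fieldShape[1]; cols <- fieldShape[2]
  r <- cellRadiusPx
  spacing <- 2L * r + 5L
  nx <- (cols - 2L) %/% spacing
  ny <- (rows - 2L) %/% spacing
  if (nCells > nx * ny)
    stop(sprintf("cannot pack %d cells of radius %d into a %d x %d field; at most %d fit",
                 nCells, r, rows, cols, nx * ny))
  withSeed(seed, {
    slots <- sample.int(nx * ny, nCells)
    A <- array(0, c(rows, cols, nPlanes))
    B <- array(0, c(rows, cols, nPlanes))
    nvox <- rows * cols * nPlanes
    A[] <- stats::rnorm(nvox, backgroundMean, backgroundSd)
    B[] <- stats::rnorm(nvox, backgroundMean, backgroundSd)
    cells <- vector("list", nCells)
    truthCells <- vector("list", nCells)
    for (i in seq_len(nCells)) {
      gx <- (slots[i] - 1L) %% nx
      gy <- (slots[i] - 1L) %/% nx
      # jitter within the slot, keeping at least 1 px between disks
      cx <- 1L + gx * spacing + r + 1L + stats::runif(1, -1, 1)
      cy <- 1L + gy * spacing + r + 1L + stats::runif(1, -1, 1)
      xmin <- floor(cx - r); xmax <- ceiling(cx + r)
      ymin <- floor(cy - r); ymax <- ceiling(cy + r)
      w <- xmax - xmin; h <- ymax - ymin
      px <- rep(xmin + seq_len(w) - 0.5, each = h)
      py <- rep(ymin + seq_len(h) - 0.5, times = w)
      disk <- (px - cx)^2 + (py - cy)^2 <= r^2
      diskM <- matrix(disk, h, w)
      mask <- array(diskM, c(h, w, nPlanes))
      nin <- sum(mask)
      z1 <- stats::rnorm(nin)
      z2 <- stats::rnorm(nin)
      aVal <- cellMean + cellSd * z1
      bVal <- cellMean + cellSd * (rho * z1 + sqrt(1 - rho^2) * z2)
      subA <- A[(ymin + 1):ymax, (xmin + 1):xmax, , drop = FALSE]
      subB <- B[(ymin + 1):ymax, (xmin + 1):xmax, , drop = FALSE]
      subA[mask] <- aVal
      subB[mask] <- bVal
      A[(ymin + 1):ymax, (xmin + 1):xmax, ] <- subA
      B[(ymin + 1):ymax, (xmin + 1):xmax, ] <- subB
      cells[[i]] <- CellROI(xmin, xmax, ymin, ymax, 0L, nPlanes, mask = mask,
                            cellId = sprintf("cell_%03d", i), group = group)
      truthCells[[i]] <- list(cell_id = sprintf("cell_%03d", i), rho = rho,
                              bounds = c(xmin, xmax, ymin, ymax),
                              group = group)
    }
    A <- clip255(roundHalfUp(A))
    B <- clip255(roundHalfUp(B))
    stack <- ImageStack(list(gfp = A, red = B), zStepUm = 1)
    truth <- list(cells = truthCells,
                  params = list(nCells = nCells, rho = rho,
                                cellRadiusPx = cellRadiusPx,
                                fieldShape = fieldShape, nPlanes = nPlanes,
                                backgroundMean = backgroundMean,
                                backgroundSd = backgroundSd,
                                cellMean = cellMean, cellSd = cellSd,
                                group = group, seed = seed))
    list(stack = stack, cells = cells, truth = truth)
  })
}

#' Generate a synthetic pharmacological IPSC experiment
#'
#' Per cell, the total evoked inhibitory amplitude is drawn around
#' `totalAmpMeanPA` with coefficient of variation `noiseCv`; the residual
#' after strychnine is the cell's GABA fraction of the total with
#' multiplicative noise of the same CV; the residual after both blockers
#' is a configurable leak (default 0). Draws violating the amplitude
#' ordering are resampled a bounded number of times, then an error is
#' raised.
#'
#' @param nCellsPerGroup named integer vector of group sizes; the default
#'   `c(p14 = 5, "p55+" = 4)` mirrors a young/adult comparison.
#' @param groupFractions named numeric vector of true GABA fractions per
#'   group, in \[0, 1\]; default `c(p14 = 0.24, "p55+" = 0.06)`.
#' @param totalAmpMeanPA mean total amplitude magnitude in pA
#'   (default 3000, a typical evoked inhibitory peak at these synapses).
#' @param noiseCv coefficient of variation of both the total and the
#'   residual (default 0.05).
#' @param leakPA residual magnitude after both blockers (default 0).
#' @param seed integer RNG seed.
#' @return list with `records` (data.frame: `cell_id`, `group`,
#'   `amp_total_pA`, `amp_after_strychnine_pA`, `amp_after_both_pA`) and
#'   `truth` (per-group true fractions and parameters).
#' @export
generateIpscExperiment <- function(nCellsPerGroup = c(p14 = 5, "p55+" = 4),
                                   groupFractions = c(p14 = 0.24, "p55+" = 0.06),
                                   totalAmpMeanPA = 3000, noiseCv = 0.05,
                                   leakPA = 0, seed = 1L) {
  if (is.null(names(nCellsPerGroup)) || is.null(names(groupFractions)))
    stop("nCellsPerGroup and groupFractions must be named by group")
  if (!setequal(names(nCellsPerGroup), names(groupFractions)))
    stop("group names must match between sizes and fractions")
  if (any(groupFractions < 0 | groupFractions > 1))
    stop("GABA fractions must lie in [0, 1]")
  if (noiseCv < 0) stop("noiseCv must be non-negative")
  withSeed(seed, {
    rows <- list()
    cellN <- 0L
    for (g in names(nCellsPerGroup)) {
      f <- groupFractions[[g]]
      for (i in seq_len(nCellsPerGroup[[g]])) {
        cellN <- cellN + 1L
        total <- NA_real_
        for (try in 1:100) {
          cand <- totalAmpMeanPA * (1 + stats::rnorm(1, 0, noiseCv))
          if (cand > leakPA) { total <- cand; break }
        }
        if (is.na(total)) stop("could not sample a positive total amplitude (noiseCv too large?)")
        resid <- NA_real_
        for (try in 1:100) {
          cand <- leakPA + f * (total - leakPA) * (1 + stats::rnorm(1, 0, noiseCv))
          if (cand >= leakPA && cand <= total) { resid <- cand; break }
        }
        if (is.na(resid)) stop("could not sample an ordered residual amplitude (noiseCv too large?)")
        rows[[cellN]] <- data.frame(cell_id = sprintf("cell_%03d", cellN),
                                    group = g, amp_total_pA = total,
                                    amp_after_strychnine_pA = resid,
                                    amp_after_both_pA = leakPA)
      }
    }
    records <- do.call(rbind, rows)
    truth <- list(group_fractions = as.list(groupFractions),
                  params = list(nCellsPerGroup = as.list(nCellsPerGroup),
                                totalAmpMeanPA = totalAmpMeanPA,
                                noiseCv = noiseCv, leakPA = leakPA,
                                seed = seed))
    list(records = records, truth = truth)
  })
}
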