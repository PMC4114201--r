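## Li intensity-correlation analysis: per-cell PDM and ICQ, the normalized
## colocalization color map, Li's sign test, and nonparametric group
## comparison.

#' Extract paired channel intensities for one cell
#'
#' Crops both channels of a two-channel stack to the cell's bounds and
#' returns paired intensity vectors in a consistent voxel order. When the
#' cell carries a voxel mask, only masked-in voxels are returned.
#'
#' @param stack an [ImageStack-class] with at least two channels.
#' @param roi a [CellROI-class].
#' @param channels length-2 character vector naming channels A and B;
#'   defaults to the stack's first two channels.
#' @return list with numeric vectors `A` and `B` of equal length.
#' @export
extractCellPixels <- function(stack, roi, channels = NULL) {
  if (is.null(channels)) channels <- channelNames(stack)[1:2]
  if (length(channels) != 2L) stop("exactly two channels are required")
  d <- dim(stack)
  b <- cellBounds(roi)
  if (b[["xmin"]] < 0L || b[["ymin"]] < 0L || b[["zmin"]] < 0L ||
      b[["xmax"]] > d[2] || b[["ymax"]] > d[1] || b[["zmax"]] > d[3])
    stop("cell crop extends outside the stack")
  crop <- function(ch) {
    a <- getChannel(stack, ch)[(b[["ymin"]] + 1L):b[["ymax"]],
                               (b[["xmin"]] + 1L):b[["xmax"]],
                               (b[["zmin"]] + 1L):b[["zmax"]], drop = FALSE]
    if (!is.null(roi@mask)) a[roi@mask] else as.vector(a)
  }
  list(A = crop(channels[1]), B = crop(channels[2]))
}

#' Product of the differences from the mean (PDM)
#'
#' For paired intensity vectors A and B, the per-pixel PDM is
#' `(A_i - mean(A)) * (B_i - mean(B))`. Positive values mark pixels where
#' the two channels deviate from their means in the same direction.
#'
#' @param A,B equal-length numeric vectors.
#' @return numeric vector of per-pixel products.
#' @examples
#' computePdm(c(0, 2), c(0, 2))  # 1 1
#' @export
computePdm <- function(A, B) {
  if (length(A) != length(B)) stop("A and B must have equal length")
  if (length(A) == 0L) stop("empty intensity vectors")
  (A - mean(A)) * (B - mean(B))
}

#' Intensity correlation quotient (ICQ)
#'
#' The ICQ is the fraction of pixels with positive PDM, among pixels with
#' nonzero PDM, minus 0.5. It lies in \[-0.5, +0.5\]: random staining gives
#' values near 0, dependent staining positive values, segregated staining
#' negative values. Pixels with PDM exactly 0 are excluded from the ratio
#' (their count is reported so the alternative convention can be
#' recomputed).
#'
#' @param A,B equal-length numeric vectors, length >= 2.
#' @return an [ICQResult-class].
#' @examples
#' icqValue(computeIcq(c(0, 1, 2, 5), c(0, 1, 2, 5)))  # +0.5
#' @export
computeIcq <- function(A, B) {
  if (length(A) != length(B)) stop("A and B must have equal length")
  if (length(A) < 2L) stop("at least 2 pixels are required")
  pdm <- computePdm(A, B)
  nZero <- sum(pdm == 0)
  nPos <- sum(pdm > 0)
  denom <- length(pdm) - nZero
  if (denom == 0L) {
    const <- c("A", "B")[c(stats::sd(A) == 0, stats::sd(B) == 0)]
    stop(sprintf("ICQ undefined: all PDM values are zero (constant channel %s)",
                 if (length(const) > 0) paste(const, collapse = " and ")
                 else "pattern"))
  }
  new("ICQResult", icq = nPos / denom - 0.5, nPixels = length(pdm),
      nPdmPositive = as.integer(nPos), nPdmZero = as.integer(nZero),
      meanA = mean(A), meanB = mean(B))
}

#' Li's per-cell sign test on the PDM
#'
#' A two-sided exact binomial test of whether the number of positive-PDM
#' pixels among nonzero-PDM pixels departs from the 50% expected under
#' independent staining. Provided for completeness of the intensity
#' correlation analysis; the group-level comparison
#' ([compareIcqGroups()]) is the headline statistic.
#'
#' @param A,B equal-length numeric vectors.
#' @return `htest` object from [stats::binom.test()].
#' @export
icqSignTest <- function(A, B) {
  r <- computeIcq(A, B)
  stats::binom.test(r@nPdmPositive, r@nPixels - r@nPdmZero, p = 0.5)
}

#' Normalized colocalization color map (nMDP)
#'
#' Per pixel, the PDM normalized by the product of the maximal channel
#' deviations, `(A_max - mean(A)) * (B_max - mean(B))`, clipped to
#' \[-1, 1\]. Values near +1 mark colocalization hot spots; the returned
#' `hotspots` layer marks pixels with positive values.
#'
#' @param sectionA,sectionB congruent intensity matrices (neither constant).
#' @return list with `map` (numeric matrix in \[-1, 1\]) and `hotspots`
#'   (logical matrix, `map > 0`).
#' @export
nmdpMap <- function(sectionA, sectionB) {
  if (!identical(dim(sectionA), dim(sectionB)))
    stop("channels must be congruent")
  mA <- mean(sectionA); mB <- mean(sectionB)
  dA <- max(sectionA) - mA; dB <- max(sectionB) - mB
  if (dA == 0 || dB == 0)
    stop("constant channel: color map normalization is undefined")
  map <- (sectionA - mA) * (sectionB - mB) / (dA * dB)
  map[map > 1] <- 1
  map[map < -1] <- -1
  list(map = map, hotspots = map > 0)
}

#' Compute per-cell ICQ values over a stack
#'
#' @param stack an [ImageStack-class] with two channels.
#' @param cells list of [CellROI-class] objects.
#' @param channels length-2 channel names (default: first two).
#' @return data.frame with columns `cell_id`, `group`, `n_pixels`, `icq`.
#' @export
icqTable <- function(stack, cells, channels = NULL) {
  rows <- lapply(cells, function(cell) {
    px <- extractCellPixels(stack, cell, channels)
    r <- computeIcq(px$A, px$B)
    data.frame(cell_id = cellId(cell), group = cellGroup(cell),
               n_pixels = nPixels(r), icq = icqValue(r))
  })
  do.call(rbind, rows)
}

#' Compare ICQ distributions between two groups
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test. The exact distribution is
#' used when both groups have at most 20 values and there are no ties;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param icqGroup1,icqGroup2 numeric vectors of per-cell ICQ values
#'   (each length >= 2).
#' @return a [GroupComparison-class].
#' @examples
#' pValue(compareIcqGroups(c(1, 2, 3), c(10, 11, 12)))  # 0.1 (exact)
#' @export
compareIcqGroups <- function(icqGroup1, icqGroup2) {
  if (length(icqGroup1) < 2L || length(icqGroup2) < 2L)
    stop("each group requires at least 2 values")
  ties <- anyDuplicated(c(icqGroup1, icqGroup2)) > 0L
  exact <- length(icqGroup1) <= 20L && length(icqGroup2) <= 20L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(icqGroup1, icqGroup2, exact = exact, correct = TRUE)
  )
  new("GroupComparison", statistic = unname(wt$statistic),
      pValue = max(wt$p.value, .Machine$double.xmin),
      n1 = length(icqGroup1), n2 = length(icqGroup2),
      median1 = stats::median(icqGroup1), median2 = stats::median(icqGroup2),
      method = if (exact) "Mann-Whitney rank-sum, exact"
               else "Mann-Whitney rank-sum, normal approximation with continuity correction")
}
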