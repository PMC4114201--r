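#' @import methods
NULL

## ---------------------------------------------------------------------------
## Image containers
## ---------------------------------------------------------------------------

#' ImageSection: one multi-channel 2D section
#'
#' A single physical section imaged in one or more fluorescence channels.
#' Channels are stored as numeric matrices (rows = y, columns = x) holding
#' integer intensities on the 8-bit working scale 0--255 (use
#' [convertTo8bit()] for 12/16-bit sources). Pixel size is isotropic in x/y.
#'
#' @slot channels named list of intensity matrices, one per channel; all
#'   matrices share identical dimensions and hold integers in \[0, 255\].
#' @slot pixelSizeUm micrometers per pixel (> 0).
#' @slot thicknessUm physical section thickness in micrometers (> 0).
#' @slot sectionIndex integer position along the antero-posterior axis.
#' @export
setClass("ImageSection",
  slots = c(
    channels     = "list",
    pixelSizeUm  = "numeric",
    thicknessUm  = "numeric",
    sectionIndex = "integer"
  )
)

setValidity("ImageSection", function(object) {
  ch <- object@channels
  if (length(ch) == 0L) return("at least one channel is required")
  if (is.null(names(ch)) || any(!nzchar(names(ch))) || anyDuplicated(names(ch)))
    return("channels must be a uniquely named list")
  if (!all(vapply(ch, is.matrix, logical(1))))
    return("every channel must be a matrix")
  dims <- vapply(ch, dim, integer(2))
  if (length(ch) > 1L && any(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1]))
    return("all channels must share identical dimensions")
  for (nm in names(ch)) {
    v <- ch[[nm]]
    if (anyNA(v)) return(sprintf("channel '%s' contains NA", nm))
    if (any(v < 0 | v > 255)) return(sprintf("channel '%s' has intensities outside [0, 255]", nm))
    if (any(v != floor(v))) return(sprintf("channel '%s' has non-integer intensities", nm))
  }
  if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
    return("pixelSizeUm must be a single positive number")
  if (length(object@thicknessUm) != 1L || object@thicknessUm <= 0)
    return("thicknessUm must be a single positive number")
  if (length(object@sectionIndex) != 1L) return("sectionIndex must be a single integer")
  TRUE
})

#' Construct an ImageSection
#'
#' @param channels named list of intensity matrices (integers in 0--255).
#' @param pixelSizeUm micrometers per pixel; default 0.742 (10x epifluorescence
#'   acquisition typical for brainstem section surveys).
#' @param thicknessUm section thickness in micrometers; default 80.
#' @param sectionIndex integer position along the antero-posterior axis.
#' @return an [ImageSection-class] object.
#' @examples
#' img <- matrix(0L, 16, 16)
#' sec <- ImageSection(list(tritc = img, nissl = img), sectionIndex = 1)
#' @export
ImageSection <- function(channels, pixelSizeUm = 0.742, thicknessUm = 80,
                         sectionIndex = 1L) {
  channels <- lapply(channels, function(m) {
    storage.mode(m) <- "double"
    m
  })
  new("ImageSection", channels = channels, pixelSizeUm = pixelSizeUm,
      thicknessUm = thicknessUm, sectionIndex = as.integer(sectionIndex))
}

#' ImageStack: one multi-channel 3D stack
#'
#' Channels are 3D arrays indexed \[y, x, z\]; intensities are integers on the
#' 0--255 scale. Used by the colocalization workflow, where per-cell crops
#' span x, y and z.
#'
#' @slot channels named list of 3D arrays of identical dimensions.
#' @slot pixelSizeUm micrometers per pixel in x/y.
#' @slot zStepUm micrometers between consecutive planes.
#' @export
setClass("ImageStack",
  slots = c(channels = "list", pixelSizeUm = "numeric", zStepUm = "numeric")
)

setValidity("ImageStack", function(object) {
  ch <- object@channels
  if (length(ch) == 0L) return("at least one channel is required")
  if (is.null(names(ch)) || any(!nzchar(names(ch))) || anyDuplicated(names(ch)))
    return("channels must be a uniquely named list")
  if (!all(vapply(ch, function(a) is.array(a) && length(dim(a)) == 3L, logical(1))))
    return("every channel must be a 3D array [y, x, z]")
  dims <- vapply(ch, dim, integer(3))
  if (length(ch) > 1L && any(dims != dims[, 1]))
    return("all channels must share identical dimensions")
  for (nm in names(ch)) {
    v <- ch[[nm]]
    if (anyNA(v) || any(v < 0 | v > 255) || any(v != floor(v)))
      return(sprintf("channel '%s' must hold integers in [0, 255]", nm))
  }
  if (object@pixelSizeUm <= 0 || object@zStepUm <= 0)
    return("pixelSizeUm and zStepUm must be positive")
  TRUE
})

#' Construct an ImageStack
#'
#' @param channels named list of 3D arrays \[y, x, z\], integers in 0--255.
#' @param pixelSizeUm micrometers per pixel in x/y.
#' @param zStepUm micrometers between planes.
#' @return an [ImageStack-class] object.
#' @export
ImageStack <- function(channels, pixelSizeUm = 0.742, zStepUm = 1) {
  channels <- lapply(channels, function(a) {
    storage.mode(a) <- "double"
    a
  })
  new("ImageStack", channels = channels, pixelSizeUm = pixelSizeUm,
      zStepUm = zStepUm)
}

## ---------------------------------------------------------------------------
## Regions of interest
## ---------------------------------------------------------------------------

#' PolygonROI: an experimenter-traced outline
#'
#' Vertices are (x, y) pixel coordinates in the package-wide convention:
#' 0-based, x rightward, y downward, pixel centers at half-integers. The
#' polygon must be simple (non-self-intersecting); this is validated on
#' construction and on load.
#'
#' @slot vertices numeric matrix with columns x, y; at least 3 rows.
#' @slot label free-text label (e.g. the nucleus name).
#' @export
setClass("PolygonROI", slots = c(vertices = "matrix", label = "character"))

setValidity("PolygonROI", function(object) {
  v <- object@vertices
  if (!is.numeric(v) || ncol(v) != 2L) return("vertices must be a numeric n x 2 matrix")
  if (nrow(v) < 3L) return("a polygon requires at least 3 vertices")
  if (anyNA(v)) return("vertices contain NA")
  if (any(v[-nrow(v), 1] == v[-1, 1] & v[-nrow(v), 2] == v[-1, 2]))
    return("consecutive duplicate vertices (zero-length edge)")
  if (!.isSimplePolygon(v)) return("polygon is self-intersecting; only simple polygons are supported")
  TRUE
})

#' Construct a PolygonROI
#'
#' @param vertices n x 2 numeric matrix (or 2-column object coercible to one)
#'   of (x, y) vertex coordinates, 0-based with pixel centers at
#'   half-integers.
#' @param label free-text label.
#' @return a [PolygonROI-class] object.
#' @examples
#' roi <- PolygonROI(cbind(c(0, 10, 10, 0), c(0, 0, 5, 5)), label = "MNTB")
#' @export
PolygonROI <- function(vertices, label = "") {
  vertices <- as.matrix(vertices)
  colnames(vertices) <- c("x", "y")
  new("PolygonROI", vertices = vertices, label = label)
}

#' BoxROI: an axis-aligned rectangle with independently movable sides
#'
#' Bounds are integer pixel coordinates, half-open in each axis:
#' `left <= x < right`, `top <= y < bottom` (0-based). Used for background
#' sample boxes and the expanding spillover box.
#'
#' @slot left,right,top,bottom integer bounds; `right > left`,
#'   `bottom > top`.
#' @export
setClass("BoxROI",
  slots = c(left = "integer", right = "integer", top = "integer", bottom = "integer")
)

setValidity("BoxROI", function(object) {
  if (object@right <= object@left) return("right must exceed left")
  if (object@bottom <= object@top) return("bottom must exceed top")
  if (object@left < 0L || object@top < 0L) return("bounds must be non-negative")
  TRUE
})

#' Construct a BoxROI
#'
#' @param left,right,top,bottom integer pixel bounds, half-open
#'   (`left <= x < right`, `top <= y < bottom`), 0-based.
#' @return a [BoxROI-class] object.
#' @export
BoxROI <- function(left, right, top, bottom) {
  new("BoxROI", left = as.integer(left), right = as.integer(right),
      top = as.integer(top), bottom = as.integer(bottom))
}

#' BinaryMask: a boolean pixel mask congruent with a section
#'
#' @slot grid logical matrix (rows = y, columns = x).
#' @export
setClass("BinaryMask", slots = c(grid = "matrix"))

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@grid)) return("grid must be a logical matrix")
  if (anyNA(object@grid)) return("grid contains NA")
  TRUE
})

#' Construct a BinaryMask
#'
#' @param grid logical matrix.
#' @return a [BinaryMask-class] object.
#' @export
BinaryMask <- function(grid) new("BinaryMask", grid = grid)

#' CellROI: a 3D crop holding one cell
#'
#' Bounds are half-open, 0-based ranges in x, y and z. An optional logical
#' mask (dimensions \[y, x, z\] congruent with the crop) restricts analysis
#' to the cell proper within the rectangular crop.
#'
#' @slot xmin,xmax,ymin,ymax,zmin,zmax integer crop bounds, half-open.
#' @slot mask logical array congruent with the crop, or NULL.
#' @slot cellId character identifier.
#' @slot group group label (e.g. "p14", "p55+").
#' @export
setClass("CellROI",
  slots = c(xmin = "integer", xmax = "integer", ymin = "integer",
            ymax = "integer", zmin = "integer", zmax = "integer",
            mask = "ANY", cellId = "character", group = "character")
)

setValidity("CellROI", function(object) {
  if (object@xmax <= object@xmin || object@ymax <= object@ymin ||
      object@zmax <= object@zmin)
    return("crop must be non-empty in every axis")
  if (!is.null(object@mask)) {
    d <- c(object@ymax - object@ymin, object@xmax - object@xmin,
           object@zmax - object@zmin)
    if (!is.logical(object@mask) || !identical(dim(object@mask), as.integer(d)))
      return("mask must be a logical array congruent with the crop [y, x, z]")
  }
  TRUE
})

#' Construct a CellROI
#'
#' @param xmin,xmax,ymin,ymax,zmin,zmax half-open 0-based crop bounds.
#' @param mask optional logical array \[y, x, z\] congruent with the crop.
#' @param cellId character identifier.
#' @param group group label.
#' @return a [CellROI-class] object.
#' @export
CellROI <- function(xmin, xmax, ymin, ymax, zmin = 0L, zmax = 1L,
                    mask = NULL, cellId = "", group = "") {
  new("CellROI", xmin = as.integer(xmin), xmax = as.integer(xmax),
      ymin = as.integer(ymin), ymax = as.integer(ymax),
      zmin = as.integer(zmin), zmax = as.integer(zmax),
      mask = mask, cellId = cellId, group = group)
}

## ---------------------------------------------------------------------------
## Quantification results
## ---------------------------------------------------------------------------

#' ThresholdSpec: the capped mean + 2*SD labeling threshold
#'
#' The labeling threshold is the sample mean of the pooled pixel set plus two
#' sample standard deviations. If that exceeds the 8-bit maximum, the upper
#' bound 255 - 2*SD is used instead and `capped` is set.
#'
#' @slot mean pooled sample mean.
#' @slot sd pooled sample standard deviation (n - 1 denominator).
#' @slot threshold final threshold (real-valued; pixels are labeled by a
#'   strict ">" comparison).
#' @slot capped TRUE iff mean + 2*sd > 255 so the upper-bound rule fired.
#' @export
setClass("ThresholdSpec",
  slots = c(mean = "numeric", sd = "numeric", threshold = "numeric",
            capped = "logical")
)

setValidity("ThresholdSpec", function(object) {
  if (object@threshold < 0 || object@threshold > 255)
    return("threshold must lie in [0, 255]")
  if (object@sd < 0) return("sd must be non-negative")
  TRUE
})

#' SectionQuant: per-section injection quantification
#'
#' @slot sectionIndex integer antero-posterior index.
#' @slot roiAreaPx pixels inside the rasterized nucleus ROI.
#' @slot thresholdSpec the [ThresholdSpec-class] used.
#' @slot labeledPxInRoi suprathreshold pixels inside the ROI.
#' @slot spilloverPx suprathreshold pixels outside the ROI, inside the final
#'   spillover box.
#' @slot finalBox the converged spillover [BoxROI-class].
#' @slot backgroundBoxes list of the three background sample boxes.
#' @slot boxAtBorder logical(4), named left/right/top/bottom: side stopped at
#'   the image border before its suprathreshold fraction fell below the rule.
#' @export
setClass("SectionQuant",
  slots = c(sectionIndex = "integer", roiAreaPx = "integer",
            thresholdSpec = "ThresholdSpec", labeledPxInRoi = "integer",
            spilloverPx = "integer", finalBox = "BoxROI",
            backgroundBoxes = "list", boxAtBorder = "logical")
)

setValidity("SectionQuant", function(object) {
  if (object@labeledPxInRoi > object@roiAreaPx)
    return("labeled pixels cannot exceed the ROI area")
  if (object@spilloverPx < 0L) return("spillover count must be non-negative")
  TRUE
})

#' InjectionSummary: whole-nucleus injection accuracy
#'
#' @slot volumeFractionPct 100 * injected volume / ROI volume over the
#'   analyzed sections.
#' @slot epicenterSectionIndex section with the maximal labeled area
#'   fraction.
#' @slot epicenterAreaPct 100 * labeled / ROI area at the epicenter section.
#' @slot apCoverageFraction analyzed sections / total antero-posterior
#'   extent of the nucleus in sections.
#' @slot coverageOk TRUE iff at least 70% of the antero-posterior extent was
#'   analyzed.
#' @slot totalSpilloverVolumeUm3 spillover pixels x pixel area x thickness,
#'   cubic micrometers.
#' @slot perSection data.frame of per-section audit values.
#' @export
setClass("InjectionSummary",
  slots = c(volumeFractionPct = "numeric", epicenterSectionIndex = "integer",
            epicenterAreaPct = "numeric", apCoverageFraction = "numeric",
            coverageOk = "logical", totalSpilloverVolumeUm3 = "numeric",
            perSection = "data.frame")
)

setValidity("InjectionSummary", function(object) {
  if (object@volumeFractionPct < 0 || object@volumeFractionPct > 100)
    return("volumeFractionPct must lie in [0, 100]")
  if (!identical(object@coverageOk, object@apCoverageFraction >= 0.70))
    return("coverageOk must equal apCoverageFraction >= 0.70")
  TRUE
})

## ---------------------------------------------------------------------------
## Colocalization results
## ---------------------------------------------------------------------------

#' ICQResult: Li intensity-correlation summary for one cell
#'
#' The intensity correlation quotient is the fraction of pixels whose
#' product of the differences from the mean (PDM) is positive, among pixels
#' with nonzero PDM, minus 0.5; it is bounded in \[-0.5, +0.5\].
#'
#' @slot icq the quotient.
#' @slot nPixels pixels analyzed.
#' @slot nPdmPositive pixels with PDM > 0.
#' @slot nPdmZero pixels with PDM exactly 0 (excluded from the ratio).
#' @slot meanA,meanB channel sample means.
#' @export
setClass("ICQResult",
  slots = c(icq = "numeric", nPixels = "integer", nPdmPositive = "integer",
            nPdmZero = "integer", meanA = "numeric", meanB = "numeric")
)

setValidity("ICQResult", function(object) {
  if (abs(object@icq) > 0.5 + 1e-12) return("|icq| cannot exceed 0.5")
  denom <- object@nPixels - object@nPdmZero
  if (denom > 0L &&
      abs(object@icq - (object@nPdmPositive / denom - 0.5)) > 1e-12)
    return("icq must equal nPdmPositive / (nPixels - nPdmZero) - 0.5")
  TRUE
})

#' GroupComparison: nonparametric two-group comparison
#'
#' @slot statistic rank-sum statistic (Wilcoxon W for the first group).
#' @slot pValue two-sided p-value.
#' @slot n1,n2 group sizes.
#' @slot median1,median2 group medians.
#' @slot method description of the test variant used.
#' @export
setClass("GroupComparison",
  slots = c(statistic = "numeric", pValue = "numeric", n1 = "integer",
            n2 = "integer", median1 = "numeric", median2 = "numeric",
            method = "character")
)

setValidity("GroupComparison", function(object) {
  if (object@pValue <= 0 || object@pValue > 1)
    return("pValue must lie in (0, 1]")
  TRUE
})

## ---------------------------------------------------------------------------
## IPSC decomposition results
## ---------------------------------------------------------------------------

#' FractionSummary: glycine/GABA decomposition across groups
#'
#' @slot perCell data.frame with one row per valid record: cell_id, group,
#'   gaba_fraction, glycine_fraction.
#' @slot groupStats data.frame with one row per group: n, mean and SD of
#'   the GABA fraction.
#' @slot statistic t statistic of the between-group test on gaba_fraction.
#' @slot pValue two-sided p-value (bounded below by the smallest positive
#'   double when both groups are degenerate with different means).
#' @slot method test variant ("Welch" or "Student").
#' @slot flagged data.frame of records excluded for invariant violations.
#' @export
setClass("FractionSummary",
  slots = c(perCell = "data.frame", groupStats = "data.frame",
            statistic = "numeric", pValue = "numeric", method = "character",
            flagged = "data.frame")
)
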