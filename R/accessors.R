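## Accessors and show() methods. Slots are never accessed with @ by user code.

#' @rdname ImageSection-class
#' @param object,x an object.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname ImageSection-class
#' @export
setMethod("channelNames", "ImageSection", function(x) names(x@channels))

#' @rdname ImageStack-class
#' @export
setMethod("channelNames", "ImageStack", function(x) names(x@channels))

#' Extract one channel's intensity grid
#'
#' @param x an [ImageSection-class] or [ImageStack-class].
#' @param name channel name.
#' @return a matrix (section) or 3D array (stack).
#' @export
setGeneric("getChannel", function(x, name) standardGeneric("getChannel"))

#' @rdname getChannel
#' @export
setMethod("getChannel", "ImageSection", function(x, name) {
  if (!name %in% names(x@channels))
    stop(sprintf("no channel '%s'; available: %s", name,
                 paste(names(x@channels), collapse = ", ")))
  x@channels[[name]]
})

#' @rdname getChannel
#' @export
setMethod("getChannel", "ImageStack", function(x, name) {
  if (!name %in% names(x@channels))
    stop(sprintf("no channel '%s'; available: %s", name,
                 paste(names(x@channels), collapse = ", ")))
  x@channels[[name]]
})

#' @describeIn ImageSection-class image dimensions (rows, cols).
#' @export
setMethod("dim", "ImageSection", function(x) dim(x@channels[[1]]))

#' @describeIn ImageStack-class stack dimensions (rows, cols, planes).
#' @export
setMethod("dim", "ImageStack", function(x) dim(x@channels[[1]]))

#' @rdname ImageSection-class
#' @export
setGeneric("pixelSizeUm", function(x) standardGeneric("pixelSizeUm"))

#' @rdname ImageSection-class
#' @export
setMethod("pixelSizeUm", "ImageSection", function(x) x@pixelSizeUm)

#' @rdname ImageStack-class
#' @export
setMethod("pixelSizeUm", "ImageStack", function(x) x@pixelSizeUm)

#' @rdname ImageSection-class
#' @export
setGeneric("thicknessUm", function(x) standardGeneric("thicknessUm"))

#' @rdname ImageSection-class
#' @export
setMethod("thicknessUm", "ImageSection", function(x) x@thicknessUm)

#' @rdname ImageSection-class
#' @export
setGeneric("sectionIndex", function(x) standardGeneric("sectionIndex"))

#' @rdname ImageSection-class
#' @export
setMethod("sectionIndex", "ImageSection", function(x) x@sectionIndex)

#' @rdname SectionQuant-class
#' @export
setMethod("sectionIndex", "SectionQuant", function(x) x@sectionIndex)

#' @rdname PolygonROI-class
#' @export
setGeneric("roiVertices", function(x) standardGeneric("roiVertices"))

#' @rdname PolygonROI-class
#' @export
setMethod("roiVertices", "PolygonROI", function(x) x@vertices)

#' @rdname PolygonROI-class
#' @export
setGeneric("roiLabel", function(x) standardGeneric("roiLabel"))

#' @rdname PolygonROI-class
#' @export
setMethod("roiLabel", "PolygonROI", function(x) x@label)

#' @rdname BoxROI-class
#' @export
setGeneric("boxBounds", function(x) standardGeneric("boxBounds"))

#' @rdname BoxROI-class
#' @export
setMethod("boxBounds", "BoxROI", function(x)
  c(left = x@left, right = x@right, top = x@top, bottom = x@bottom))

#' @describeIn BoxROI-class box area in pixels.
#' @export
setGeneric("boxArea", function(x) standardGeneric("boxArea"))

#' @rdname BoxROI-class
#' @export
setMethod("boxArea", "BoxROI", function(x)
  as.integer((x@right - x@left) * (x@bottom - x@top)))

#' @rdname BinaryMask-class
#' @export
setGeneric("maskGrid", function(x) standardGeneric("maskGrid"))

#' @rdname BinaryMask-class
#' @export
setMethod("maskGrid", "BinaryMask", function(x) x@grid)

#' @describeIn BinaryMask-class number of TRUE pixels.
#' @export
setGeneric("maskArea", function(x) standardGeneric("maskArea"))

#' @rdname BinaryMask-class
#' @export
setMethod("maskArea", "BinaryMask", function(x) sum(x@grid))

#' @rdname ThresholdSpec-class
#' @export
setGeneric("thresholdValue", function(x) standardGeneric("thresholdValue"))

#' @rdname ThresholdSpec-class
#' @export
setMethod("thresholdValue", "ThresholdSpec", function(x) x@threshold)

#' @rdname ThresholdSpec-class
#' @export
setGeneric("isCapped", function(x) standardGeneric("isCapped"))

#' @rdname ThresholdSpec-class
#' @export
setMethod("isCapped", "ThresholdSpec", function(x) x@capped)

#' @rdname SectionQuant-class
#' @export
setGeneric("labeledPx", function(x) standardGeneric("labeledPx"))

#' @rdname SectionQuant-class
#' @export
setMethod("labeledPx", "SectionQuant", function(x) x@labeledPxInRoi)

#' @rdname SectionQuant-class
#' @export
setGeneric("roiAreaPx", function(x) standardGeneric("roiAreaPx"))

#' @rdname SectionQuant-class
#' @export
setMethod("roiAreaPx", "SectionQuant", function(x) x@roiAreaPx)

#' @rdname SectionQuant-class
#' @export
setGeneric("spilloverPx", function(x) standardGeneric("spilloverPx"))

#' @rdname SectionQuant-class
#' @export
setMethod("spilloverPx", "SectionQuant", function(x) x@spilloverPx)

#' @rdname SectionQuant-class
#' @export
setGeneric("thresholdSpec", function(x) standardGeneric("thresholdSpec"))

#' @rdname SectionQuant-class
#' @export
setMethod("thresholdSpec", "SectionQuant", function(x) x@thresholdSpec)

#' @rdname SectionQuant-class
#' @export
setGeneric("finalBox", function(x) standardGeneric("finalBox"))

#' @rdname SectionQuant-class
#' @export
setMethod("finalBox", "SectionQuant", function(x) x@finalBox)

#' @rdname SectionQuant-class
#' @export
setGeneric("backgroundBoxes", function(x) standardGeneric("backgroundBoxes"))

#' @rdname SectionQuant-class
#' @export
setMethod("backgroundBoxes", "SectionQuant", function(x) x@backgroundBoxes)

#' @rdname InjectionSummary-class
#' @export
setGeneric("volumeFractionPct", function(x) standardGeneric("volumeFractionPct"))

#' @rdname InjectionSummary-class
#' @export
setMethod("volumeFractionPct", "InjectionSummary", function(x) x@volumeFractionPct)

#' @rdname InjectionSummary-class
#' @export
setGeneric("epicenterAreaPct", function(x) standardGeneric("epicenterAreaPct"))

#' @rdname InjectionSummary-class
#' @export
setMethod("epicenterAreaPct", "InjectionSummary", function(x) x@epicenterAreaPct)

#' @rdname InjectionSummary-class
#' @export
setGeneric("epicenterSectionIndex", function(x) standardGeneric("epicenterSectionIndex"))

#' @rdname InjectionSummary-class
#' @export
setMethod("epicenterSectionIndex", "InjectionSummary", function(x) x@epicenterSectionIndex)

#' @rdname InjectionSummary-class
#' @export
setGeneric("apCoverage", function(x) standardGeneric("apCoverage"))

#' @rdname InjectionSummary-class
#' @export
setMethod("apCoverage", "InjectionSummary", function(x)
  c(fraction = x@apCoverageFraction, ok = x@coverageOk))

#' @rdname InjectionSummary-class
#' @export
setGeneric("perSection", function(x) standardGeneric("perSection"))

#' @rdname InjectionSummary-class
#' @export
setMethod("perSection", "InjectionSummary", function(x) x@perSection)

#' @rdname InjectionSummary-class
#' @export
setGeneric("spilloverVolumeUm3", function(x) standardGeneric("spilloverVolumeUm3"))

#' @rdname InjectionSummary-class
#' @export
setMethod("spilloverVolumeUm3", "InjectionSummary", function(x) x@totalSpilloverVolumeUm3)

#' @rdname ICQResult-class
#' @export
setGeneric("icqValue", function(x) standardGeneric("icqValue"))

#' @rdname ICQResult-class
#' @export
setMethod("icqValue", "ICQResult", function(x) x@icq)

#' @rdname ICQResult-class
#' @export
setGeneric("nPixels", function(x) standardGeneric("nPixels"))

#' @rdname ICQResult-class
#' @export
setMethod("nPixels", "ICQResult", function(x) x@nPixels)

#' @rdname GroupComparison-class
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname GroupComparison-class
#' @export
setMethod("pValue", "GroupComparison", function(x) x@pValue)

#' @rdname FractionSummary-class
#' @export
setMethod("pValue", "FractionSummary", function(x) x@pValue)

#' @rdname GroupComparison-class
#' @export
setGeneric("testStatistic", function(x) standardGeneric("testStatistic"))

#' @rdname GroupComparison-class
#' @export
setMethod("testStatistic", "GroupComparison", function(x) x@statistic)

#' @rdname FractionSummary-class
#' @export
setMethod("testStatistic", "FractionSummary", function(x) x@statistic)

#' @rdname FractionSummary-class
#' @export
setGeneric("groupStats", function(x) standardGeneric("groupStats"))

#' @rdname FractionSummary-class
#' @export
setMethod("groupStats", "FractionSummary", function(x) x@groupStats)

#' @rdname FractionSummary-class
#' @export
setGeneric("perCell", function(x) standardGeneric("perCell"))

#' @rdname FractionSummary-class
#' @export
setMethod("perCell", "FractionSummary", function(x) x@perCell)

#' @rdname CellROI-class
#' @export
setGeneric("cellId", function(x) standardGeneric("cellId"))

#' @rdname CellROI-class
#' @export
setMethod("cellId", "CellROI", function(x) x@cellId)

#' @rdname CellROI-class
#' @export
setGeneric("cellGroup", function(x) standardGeneric("cellGroup"))

#' @rdname CellROI-class
#' @export
setMethod("cellGroup", "CellROI", function(x) x@group)

#' @rdname CellROI-class
#' @export
setGeneric("cellBounds", function(x) standardGeneric("cellBounds"))

#' @rdname CellROI-class
#' @export
setMethod("cellBounds", "CellROI", function(x)
  c(xmin = x@xmin, xmax = x@xmax, ymin = x@ymin, ymax = x@ymax,
    zmin = x@zmin, zmax = x@zmax))

## show() -------------------------------------------------------------------

setMethod("show", "ImageSection", function(object) {
  d <- dim(object)
  cat(sprintf("ImageSection #%d: %d x %d px, %s channel(s) [%s]\n",
              object@sectionIndex, d[1], d[2], length(object@channels),
              paste(names(object@channels), collapse = ", ")))
  cat(sprintf("  pixel %.3g um, thickness %.3g um\n",
              object@pixelSizeUm, object@thicknessUm))
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object)
  cat(sprintf("ImageStack: %d x %d x %d, channels [%s]\n", d[1], d[2], d[3],
              paste(names(object@channels), collapse = ", ")))
})

setMethod("show", "PolygonROI", function(object) {
  cat(sprintf("PolygonROI '%s': %d vertices\n", object@label,
              nrow(object@vertices)))
})

setMethod("show", "BoxROI", function(object) {
  cat(sprintf("BoxROI [%d, %d) x [%d, %d), area %d px\n", object@left,
              object@right, object@top, object@bottom, boxArea(object)))
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask %d x %d, %d px set\n", nrow(object@grid),
              ncol(object@grid), maskArea(object)))
})

setMethod("show", "ThresholdSpec", function(object) {
  cat(sprintf("ThresholdSpec: mean %.3f, sd %.3f -> threshold %.3f%s\n",
              object@mean, object@sd, object@threshold,
              if (object@capped) " (capped at 255 - 2*SD)" else ""))
})

setMethod("show", "SectionQuant", function(object) {
  cat(sprintf("SectionQuant #%d: ROI %d px, labeled %d (%.1f%%), spillover %d px\n",
              object@sectionIndex, object@roiAreaPx, object@labeledPxInRoi,
              100 * object@labeledPxInRoi / max(1L, object@roiAreaPx),
              object@spilloverPx))
  show(object@thresholdSpec)
})

setMethod("show", "InjectionSummary", function(object) {
  cat(sprintf("InjectionSummary: %.2f%% of nucleus volume injected\n",
              object@volumeFractionPct))
  cat(sprintf("  epicenter section %d (%.1f%% of section area)\n",
              object@epicenterSectionIndex, object@epicenterAreaPct))
  cat(sprintf("  antero-posterior coverage %.0f%% (%s)\n",
              100 * object@apCoverageFraction,
              if (object@coverageOk) "meets the 70% rule" else "below the 70% rule"))
  cat(sprintf("  spillover volume %.3g um^3\n", object@totalSpilloverVolumeUm3))
})

setMethod("show", "ICQResult", function(object) {
  cat(sprintf("ICQResult: icq %+.4f over %d px (%d PDM>0, %d PDM=0)\n",
              object@icq, object@nPixels, object@nPdmPositive,
              object@nPdmZero))
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison (%s): W = %g, p = %.4g; n = %d vs %d; medians %.4g vs %.4g\n",
              object@method, object@statistic, object@pValue, object@n1,
              object@n2, object@median1, object@median2))
})

setMethod("show", "FractionSummary", function(object) {
  cat(sprintf("FractionSummary (%s t-test): t = %.3f, p = %.4g\n",
              object@method, object@statistic, object@pValue))
  print(object@groupStats, row.names = FALSE)
  if (nrow(object@flagged) > 0L)
    cat(sprintf("  %d record(s) flagged and excluded\n", nrow(object@flagged)))
})

setMethod("show", "CellROI", function(object) {
  cat(sprintf("CellROI '%s' (%s): x [%d,%d) y [%d,%d) z [%d,%d)%s\n",
              object@cellId, object@group, object@xmin, object@xmax,
              object@ymin, object@ymax, object@zmin, object@zmax,
              if (is.null(object@mask)) "" else sprintf(", %d voxels masked in",
                                                        sum(object@mask))))
})
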