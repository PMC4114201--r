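## File I/O: multi-page TIFF sections, polygon ROI files (JSON dialect plus
## the ImageJ .roi binary record), and tabular outputs.

#' Write an ImageSection to a multi-page TIFF
#'
#' One 8-bit grayscale page per channel, in the section's channel order.
#' Channel names are not stored in the file; supply them again on read
#' (the usual arrangement when acquisition software names filter cubes in a
#' separate config).
#'
#' @param section an [ImageSection-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSectionTiff <- function(section, path) {
  stopifnot(is(section, "ImageSection"))
  pages <- lapply(section@channels, function(m) m / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read an ImageSection from a multi-page TIFF
#'
#' @param path TIFF file with one 8-bit page per channel.
#' @param channels character vector naming the channels, in page order.
#' @param pixelSizeUm,thicknessUm,sectionIndex section metadata (not stored
#'   in the TIFF).
#' @return an [ImageSection-class].
#' @export
readSectionTiff <- function(path, channels, pixelSizeUm = 0.742,
                            thicknessUm = 80, sectionIndex = 1L) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(channels))
    stop(sprintf("TIFF has %d page(s) but %d channel name(s) were supplied",
                 length(pages), length(channels)))
  names(pages) <- channels
  ImageSection(pages, pixelSizeUm = pixelSizeUm, thicknessUm = thicknessUm,
               sectionIndex = sectionIndex)
}

#' Write a polygon ROI to the package JSON dialect
#'
#' The file records the coordinate convention explicitly:
#' `"0-based,center"` means 0-based pixel coordinates with pixel centers at
#' half-integers, x rightward, y downward.
#'
#' @param roi a [PolygonROI-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRoiJson <- function(roi, path) {
  stopifnot(is(roi, "PolygonROI"))
  obj <- list(label = roiLabel(roi),
              vertices = unname(roiVertices(roi)),
              convention = "0-based,center")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a polygon ROI from the package JSON dialect
#'
#' @param path JSON file written by [writeRoiJson()] (fields `label`,
#'   `vertices`, `convention`).
#' @return a [PolygonROI-class]; the polygon is validated (simplicity,
#'   vertex count) on load.
#' @export
readRoiJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$vertices)) stop("ROI JSON lacks a 'vertices' field")
  if (!identical(obj$convention, "0-based,center"))
    stop(sprintf("unsupported ROI coordinate convention '%s'",
                 as.character(obj$convention)))
  PolygonROI(matrix(as.numeric(obj$vertices), ncol = 2),
             label = if (is.null(obj$label)) "" else obj$label)
}

#' Import a polygon from an ImageJ .roi file
#'
#' Parses the polygon-family record types of the ImageJ ROI binary format
#' (polygon, freehand, traced). Coordinates are the stored integer vertex
#' positions, interpreted in the package's 0-based convention.
#'
#' @param path an ImageJ `.roi` file.
#' @return a [PolygonROI-class].
#' @export
readImageJRoi <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 64L || rawToChar(raw[1:4]) != "Iout")
    stop("not an ImageJ .roi file (missing 'Iout' magic)")
  int16 <- function(off) {  # big-endian signed short at 0-based offset
    readBin(raw[(off + 1):(off + 2)], "integer", size = 2, endian = "big")
  }
  type <- as.integer(raw[7])  # byte at 0-based offset 6
  # 0 = polygon, 7 = freehand, 8 = traced
  if (!type %in% c(0L, 7L, 8L))
    stop(sprintf("ImageJ ROI type %d is not a polygon record", type))
  top <- int16(8); left <- int16(10)
  n <- int16(16)
  if (n < 3L) stop("ImageJ ROI has fewer than 3 vertices")
  coordOff <- 64L
  xs <- vapply(seq_len(n) - 1L, function(i) int16(coordOff + 2L * i), integer(1))
  ys <- vapply(seq_len(n) - 1L, function(i) int16(coordOff + 2L * (n + i)), integer(1))
  PolygonROI(cbind(left + xs, top + ys),
             label = sub("\\.roi$", "", basename(path)))
}

#' Write per-section quantification results to CSV
#'
#' One row per section with the documented stable columns: `section_index`,
#' `roi_area_px`, `threshold`, `labeled_px_in_roi`, `spillover_px`,
#' `box_left`, `box_right`, `box_top`, `box_bottom`. An empty input yields
#' a header-only file.
#'
#' @param quants list of [SectionQuant-class] objects (possibly empty).
#' @param path output CSV path.
#' @return the data.frame written, invisibly.
#' @export
writeQuantCsv <- function(quants, path) {
  df <- quantTable(quants)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Tabulate per-section quantification results
#'
#' @param quants list of [SectionQuant-class] objects.
#' @return a data.frame with one row per section (zero rows if empty).
#' @export
quantTable <- function(quants) {
  if (length(quants) == 0L) {
    return(data.frame(section_index = integer(), roi_area_px = integer(),
                      threshold = numeric(), labeled_px_in_roi = integer(),
                      spillover_px = integer(), box_left = integer(),
                      box_right = integer(), box_top = integer(),
                      box_bottom = integer()))
  }
  do.call(rbind, lapply(quants, function(q) {
    b <- boxBounds(finalBox(q))
    data.frame(section_index = sectionIndex(q), roi_area_px = roiAreaPx(q),
               threshold = thresholdValue(thresholdSpec(q)),
               labeled_px_in_roi = labeledPx(q), spillover_px = spilloverPx(q),
               box_left = b[["left"]], box_right = b[["right"]],
               box_top = b[["top"]], box_bottom = b[["bottom"]])
  }))
}

#' Write an injection summary to JSON
#'
#' @param summary an [InjectionSummary-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeInjectionSummaryJson <- function(summary, path) {
  stopifnot(is(summary, "InjectionSummary"))
  obj <- list(volume_fraction_pct = volumeFractionPct(summary),
              epicenter_section_index = epicenterSectionIndex(summary),
              epicenter_area_pct = epicenterAreaPct(summary),
              ap_coverage_fraction = unname(apCoverage(summary)["fraction"]),
              coverage_ok = unname(apCoverage(summary)["ok"]) == 1,
              total_spillover_volume_um3 = spilloverVolumeUm3(summary))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a labeled-pixel mask as an 8-bit TIFF
#'
#' Marks suprathreshold pixels (the overlay the original workflow rendered
#' as pink dots) as 255 on a 0 background.
#'
#' @param mask a [BinaryMask-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeLabeledMaskTiff <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask"))
  tiff::writeTIFF(maskGrid(mask) * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read per-cell IPSC amplitude records from CSV
#'
#' Required columns: `cell_id`, `group`, `amp_total_pA`,
#' `amp_after_strychnine_pA`, `amp_after_both_pA`; `amp_washout_pA` is
#' optional. Amplitudes are peak magnitudes in picoamperes.
#'
#' @param path CSV file.
#' @return a data.frame of records.
#' @export
readIpscCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "group", "amp_total_pA", "amp_after_strychnine_pA",
            "amp_after_both_pA")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop(sprintf("IPSC CSV lacks required column(s): %s",
                 paste(miss, collapse = ", ")))
  df
}
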