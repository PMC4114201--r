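## Depth conversion and polygon rasterization: the pixel-level primitives
## every downstream quantification relies on.

#' Convert a raw intensity grid to the 8-bit working depth
#'
#' Higher bit depths are mapped by integer division by `2^(depth - 8)`
#' (a pure bit shift). This is a linear depth conversion, not a min-max
#' contrast stretch: relative intensities are preserved and no image
#' statistics enter the mapping.
#'
#' @param raw integer matrix (or vector) of raw intensities.
#' @param bitDepth declared source depth: 8, 12 or 16.
#' @return the input mapped to integers in \[0, 255\]; 8-bit input is
#'   returned unchanged.
#' @examples
#' convertTo8bit(matrix(c(0, 1000, 4095), 1), bitDepth = 12)  # 0 62 255
#' @export
convertTo8bit <- function(raw, bitDepth = 12) {
  if (!bitDepth %in% c(8, 12, 16))
    stop("bitDepth must be one of 8, 12, 16")
  if (anyNA(raw)) stop("raw intensities contain NA")
  if (any(raw != floor(raw))) stop("raw intensities must be integers")
  lim <- 2^bitDepth - 1
  bad <- which(raw < 0 | raw > lim)
  if (length(bad) > 0L) {
    i <- bad[1]
    loc <- if (is.matrix(raw)) {
      sprintf("pixel (row %d, col %d)", (i - 1L) %% nrow(raw) + 1L,
              (i - 1L) %/% nrow(raw) + 1L)
    } else sprintf("element %d", i)
    stop(sprintf("value %g at %s outside the declared %d-bit range [0, %d]",
                 raw[i], loc, bitDepth, lim))
  }
  if (bitDepth == 8) return(raw)
  raw %/% 2^(bitDepth - 8)
}

#' Rasterize a polygon ROI onto a pixel grid
#'
#' A pixel belongs to the mask iff its center lies inside the polygon under
#' the even-odd rule. In the package convention coordinates are 0-based with
#' x rightward and y downward, so the center of the pixel at (column c,
#' row r) is (c + 0.5, r + 0.5) for 0-based c, r.
#'
#' @param roi a [PolygonROI-class].
#' @param shape integer (rows, cols) of the target grid.
#' @return a [BinaryMask-class] of the given shape. A polygon lying entirely
#'   outside the grid yields an empty mask with a warning.
#' @examples
#' m <- rasterize(PolygonROI(cbind(c(0, 10, 10, 0), c(0, 0, 5, 5))), c(20, 20))
#' maskArea(m)  # 50
#' @export
rasterize <- function(roi, shape) {
  stopifnot(is(roi, "PolygonROI"))
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape <= 0L))
    stop("shape must be two positive integers (rows, cols)")
  validObject(roi)
  v <- roiVertices(roi)
  rows <- shape[1]; cols <- shape[2]
  # restrict the test to the polygon's bounding box for speed
  cMin <- max(1L, floor(min(v[, 1]) + 0.5) + 1L)
  cMax <- min(cols, ceiling(max(v[, 1]) - 0.5) + 1L)
  rMin <- max(1L, floor(min(v[, 2]) + 0.5) + 1L)
  rMax <- min(rows, ceiling(max(v[, 2]) - 0.5) + 1L)
  grid <- matrix(FALSE, rows, cols)
  if (cMin <= cMax && rMin <= rMax) {
    cs <- cMin:cMax
    rs <- rMin:rMax
    px <- rep(cs - 0.5, each = length(rs))   # center x, 0-based
    py <- rep(rs - 0.5, times = length(cs))  # center y, 0-based
    inside <- .pointInPolygon(px, py, v[, 1], v[, 2])
    grid[rs, cs] <- inside
  }
  if (!any(grid))
    warning("polygon produced an empty mask (entirely outside the image?)")
  BinaryMask(grid)
}
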