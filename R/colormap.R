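#' Render a reflectivity color map
#'
#' Maps each voxel's percent reflectivity through a fixed symmetric
#' diverging scale (blue = negative, white = zero, red = positive) with 256
#' quantization levels. Values outside \code{[lo, hi]} are clipped to the
#' endpoint colors; flagged (NA) voxels render transparent. The legend
#' records the scale so colors can be inverted back to values within one
#' quantization step.
#'
#' @param result a \code{\linkS4class{ReflectivityResult}} (or a numeric
#'   array of percent values).
#' @param rangePercent length-2 display range \code{c(lo, hi)}, lo < hi.
#' @param levels number of quantization levels.
#' @return A list of class \code{"voxreflColorMap"}: \code{colors}
#'   (character array of #RRGGBBAA hex colors, transparent where flagged),
#'   \code{legend} (breaks, bin-center values, colors, range).
#' @export
renderColorMap <- function(result, rangePercent = c(-100, 100),
                           levels = 256L) {
  lo <- rangePercent[1]; hi <- rangePercent[2]
  if (!(lo < hi)) stop("rangePercent must satisfy lo < hi")
  vox <- if (is(result, "ReflectivityResult")) result@voxelMap else result
  pal <- colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(levels)
  pal <- paste0(pal, "FF")
  u <- (pmin(pmax(vox, lo), hi) - lo) / (hi - lo)
  idx <- pmin(floor(u * levels) + 1L, levels)
  cols <- array("#00000000", dim(vox))
  okv <- !is.na(vox)
  cols[okv] <- pal[idx[okv]]
  centers <- lo + (seq_len(levels) - 0.5) / levels * (hi - lo)
  structure(list(colors = cols,
                 legend = list(range = c(lo, hi), levels = levels,
                               centers = centers, colors = pal)),
            class = "voxreflColorMap")
}

#' Invert rendered colors back to percent values via the legend
#'
#' @param cmap a \code{"voxreflColorMap"} from \code{\link{renderColorMap}}.
#' @return Numeric array of bin-center percent values (NA where
#'   transparent). Accurate to one quantization step for in-range values.
#' @export
colorMapValues <- function(cmap) {
  idx <- match(cmap$colors, cmap$legend$colors)
  out <- array(cmap$legend$centers[idx], dim(cmap$colors))
  out
}

#' Write one axial slice of a color map as PNG
#'
#' @param cmap a \code{"voxreflColorMap"}.
#' @param path output PNG path.
#' @param slice axial (third-axis) slice index; defaults to the middle.
#' @return \code{path}, invisibly (requires the png package).
#' @export
writeColorMapPNG <- function(cmap, path, slice = NULL) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the png package is required to write PNG output")
  d <- dim(cmap$colors)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  hex <- cmap$colors[, , slice]
  rgba <- array(0, c(d[2], d[1], 4))
  ch <- function(h, a, b) strtoi(substr(h, a, b), 16L) / 255
  rgba[, , 1] <- t(matrix(ch(hex, 2, 3), d[1], d[2]))
  rgba[, , 2] <- t(matrix(ch(hex, 4, 5), d[1], d[2]))
  rgba[, , 3] <- t(matrix(ch(hex, 6, 7), d[1], d[2]))
  rgba[, , 4] <- t(matrix(ch(hex, 8, 9), d[1], d[2]))
  png::writePNG(rgba, path)
  invisible(path)
}
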