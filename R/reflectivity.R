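#' ROI-mean reflectivity
#'
#' The traditional region-of-interest formulation: percent signal
#' difference of the two ROI means,
#' \code{(testMean - controlMean) / controlMean * 100}.
#'
#' @param testMean,controlMean mean signals of the test and control ROIs
#'   (controlMean must be positive).
#' @return Reflectivity in percent.
#' @export
reflectivityROI <- function(testMean, controlMean) {
  if (!is.finite(controlMean) || controlMean <= 0)
    stop(sprintf("control mean must be positive, got %g", controlMean))
  (testMean - controlMean) / controlMean * 100
}

#' Voxel-wise reflectivity between registered volumes
#'
#' With a voxel-on-voxel match between the test image I and control image
#' g, the global reflectivity is the ratio of sums
#' \code{R = sum(I_i - g_i) / sum(g_i) * 100} over the N analysis voxels,
#' and each voxel gets its own percent value
#' \code{(I_i - g_i) / g_i * 100} (flagged \code{NA} where \code{g_i <= 0}).
#' On a fixed common mask the global value is algebraically identical to
#' \code{\link{reflectivityROI}} applied to the two mask means.
#'
#' @param test,control \code{\linkS4class{Volume3D}} objects on the same
#'   grid (the test volume typically resampled by
#'   \code{\link{resampleVolume}}).
#' @param mask optional logical array; always intersected with the voxels
#'   valid in both volumes.
#' @param provenance optional named list stored in the result.
#' @return A \code{\linkS4class{ReflectivityResult}}.
#' @export
reflectivityVoxelwise <- function(test, control, mask = NULL,
                                  provenance = list()) {
  if (!identical(dim(test@values), dim(control@values)))
    stop("test and control volumes are on different grids")
  if (max(abs(test@spacing - control@spacing)) > 1e-9 ||
      max(abs(test@origin - control@origin)) > 1e-6)
    stop("test and control volumes are on different grids (geometry)")
  ok <- validMask(test) & validMask(control)
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(ok))) stop("mask grid mismatch")
    ok <- ok & mask
  }
  n <- sum(ok)
  if (n < 1L) stop("no valid voxels in the analysis mask")
  I <- test@values[ok]
  g <- control@values[ok]
  sg <- sum(g)
  if (sg <= 0) stop(sprintf("sum of control signal must be positive, got %g", sg))
  globalR <- sum(I - g) / sg * 100
  vox <- array(NA_real_, dim(test@values))
  pos <- ok & !is.na(control@values) & control@values > 0 &
    !is.na(test@values)
  vox[pos] <- (test@values[pos] - control@values[pos]) /
    control@values[pos] * 100
  new("ReflectivityResult", globalPercent = globalR, voxelMap = vox,
      nVoxels = as.integer(n),
      provenance = c(provenance, list(sumTest = sum(I), sumControl = sg)))
}

#' @describeIn ReflectivityResult-class global percent reflectivity.
#' @param x a \code{ReflectivityResult}.
#' @export
globalReflectivity <- function(x) x@globalPercent

#' @describeIn ReflectivityResult-class per-voxel percent map.
#' @export
reflectivityMap <- function(x) x@voxelMap

setMethod("show", "ReflectivityResult", function(object) {
  cat(sprintf("ReflectivityResult: global R = %.2f%% over %d voxels\n",
              object@globalPercent, object@nVoxels))
  v <- object@voxelMap[!is.na(object@voxelMap)]
  if (length(v))
    cat(sprintf("  voxel map: median %.2f%%, IQR [%.2f, %.2f]%%\n",
                median(v), quantile(v, 0.25), quantile(v, 0.75)))
})

#' Paired two-tailed t-test
#'
#' Exact Student-t paired test on the differences d = x - y:
#' \code{t = mean(d) / (sd(d) / sqrt(n))}, df = n - 1, two-tailed p.
#' Degenerate cases follow a documented convention: all-zero differences
#' give t = 0, p = 1; zero-variance nonzero differences give t = +/-Inf,
#' p = 0 (the limit).
#'
#' @param x,y paired measurements of equal length n >= 2.
#' @return A \code{\linkS4class{TTestResult}}.
#' @export
pairedTTest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs")
  d <- x - y
  if (sd(d) == 0) {
    if (all(d == 0))
      return(new("TTestResult", statistic = 0, df = n - 1, pValue = 1))
    return(new("TTestResult", statistic = sign(mean(d)) * Inf, df = n - 1,
               pValue = 0))
  }
  ht <- stats::t.test(x, y, paired = TRUE, alternative = "two.sided")
  new("TTestResult", statistic = unname(ht$statistic),
      df = unname(ht$parameter), pValue = ht$p.value)
}

setMethod("show", "TTestResult", function(object) {
  cat(sprintf("Paired t-test: t = %.4f, df = %d, two-tailed p = %.4g\n",
              object@statistic, object@df, object@pValue))
})
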