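#' Voxel-wise T1 fitting from an arrayed-TR spin-echo series
#'
#' Fits the saturation-recovery model
#' \code{S(TR) = s0 (1 - exp(-TR / T1))} per voxel by Levenberg-Marquardt
#' nonlinear least squares (the constant TE-decay factor is absorbed into
#' s0). Initialization comes from a log-linearized estimate; T1 is bounded
#' to a physical range. Voxels with no usable TR dependence (constant or
#' non-increasing signal) are excluded from the fit mask with a reason
#' code.
#'
#' @param series list of co-registered \code{\linkS4class{Volume3D}}
#'   volumes, one per TR.
#' @param trMs repetition times in ms, matching \code{series} (at least 3
#'   distinct values).
#' @param mask optional logical array restricting the fit.
#' @param t1Bounds lower/upper T1 bounds, ms.
#' @return A \code{\linkS4class{T1Map}}. Reason codes: 0 fitted, 1 outside
#'   the requested mask, 2 degenerate signal, 3 solver failure.
#' @export
fitT1Map <- function(series, trMs, mask = NULL,
                     t1Bounds = c(50, 10000)) {
  if (length(series) != length(trMs))
    stop("series and trMs lengths differ")
  if (length(unique(trMs)) < 3L) stop("need at least 3 distinct TRs")
  d <- dim(series[[1]]@values)
  for (v in series)
    if (!identical(dim(v@values), d))
      stop("series volumes are not on a common grid")
  trMs <- as.numeric(trMs)
  S <- vapply(series, function(v) as.numeric(v@values), numeric(prod(d)))
  if (is.null(mask)) mask <- array(TRUE, d)
  t1 <- s0 <- rmse <- array(NA_real_, d)
  reason <- array(1L, d)
  idx <- which(mask)
  ord <- order(trMs)
  trs <- trMs[ord]
  model <- function(par, tr) par[2] * (1 - exp(-tr / par[1]))
  resid <- function(par, tr, y) y - model(par, tr)
  # residual r = y - s0 (1 - e^(-tr/t1)):
  # dr/dt1 = +s0 e tr / t1^2, dr/ds0 = -(1 - e)
  jac <- function(par, tr, y) {
    e <- exp(-tr / par[1])
    cbind(par[2] * e * tr / par[1]^2, -(1 - e))
  }
  for (v in idx) {
    y <- S[v, ord]
    if (anyNA(y) || diff(range(y)) <= 1e-9 * max(abs(y), 1)) {
      reason[v] <- 2L
      next
    }
    if (suppressWarnings(cor(y, trs)) <= 0) {
      reason[v] <- 2L
      next
    }
    s0g <- max(y) * 1.02
    w <- y < s0g & y > 0
    t1g <- if (sum(w) >= 2) {
      sl <- coef(lm(log(1 - y[w] / s0g) ~ trs[w]))[2]
      if (is.finite(sl) && sl < 0) -1 / sl else 1000
    } else 1000
    t1g <- min(max(t1g, t1Bounds[1]), t1Bounds[2])
    fit <- try(minpack.lm::nls.lm(
      par = c(t1g, s0g), fn = resid, jac = jac, tr = trs, y = y,
      lower = c(t1Bounds[1], 1e-12), upper = c(t1Bounds[2], Inf),
      control = minpack.lm::nls.lm.control(maxiter = 100)), silent = TRUE)
    if (inherits(fit, "try-error") || any(!is.finite(coef(fit)))) {
      reason[v] <- 3L
      next
    }
    p <- coef(fit)
    t1[v] <- p[1]
    s0[v] <- p[2]
    rmse[v] <- sqrt(mean(resid(p, trs, y)^2))
    reason[v] <- 0L
  }
  new("T1Map", t1 = t1, s0 = s0, rmse = rmse, fitMask = reason == 0L,
      reason = reason)
}

setMethod("show", "T1Map", function(object) {
  v <- object@t1[object@fitMask]
  cat(sprintf("T1Map: %d voxels fitted", length(v)))
  if (length(v))
    cat(sprintf(", median T1 = %.0f ms [%.0f, %.0f]",
                median(v), quantile(v, 0.25), quantile(v, 0.75)))
  cat("\n")
})

#' Relaxivity regression of 1/T1 against concentration
#'
#' Ordinary least squares of the relaxation rate R1 = 1000 / T1(ms)
#' (s^-1) on contrast-agent concentration (mM). The slope is the
#' relaxivity r1 (mM^-1 s^-1); the intercept is the diamagnetic rate of
#' the matrix.
#'
#' @param concMM concentrations, mM (at least two distinct values; at
#'   least three points recommended).
#' @param t1Ms T1 values, ms (> 0), same length.
#' @return A \code{\linkS4class{RelaxivityFit}}.
#' @export
fitRelaxivity <- function(concMM, t1Ms) {
  if (length(concMM) != length(t1Ms)) stop("lengths differ")
  if (length(unique(concMM)) < 2L)
    stop("need at least two distinct concentrations")
  if (any(t1Ms <= 0)) stop("t1Ms must be positive")
  r1 <- 1000 / t1Ms
  fit <- lm(r1 ~ concMM)
  tss <- sum((r1 - mean(r1))^2)
  rss <- sum(fit$residuals^2)
  rsq <- if (tss > 0) 1 - rss / tss else 1
  new("RelaxivityFit", r1 = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]), rSquared = rsq,
      n = length(concMM))
}

setMethod("show", "RelaxivityFit", function(object) {
  cat(sprintf("RelaxivityFit: r1 = %.4g mM^-1 s^-1, intercept %.4g s^-1, r^2 = %.4f (n = %d)\n",
              object@r1, object@intercept, object@rSquared, object@n))
})

#' T1-based contrast enhancement between two samples
#'
#' Default (\code{mode = "rate"}): percent change of mask-mean relaxation
#' rates, \code{(R1_test - R1_control) / R1_control * 100}, using
#' R1 = 1000/T1(ms); contrast agents shorten T1, raising R1, so positive
#' enhancement means more agent in the test sample.
#' \code{mode = "signal"} instead applies the ROI-mean reflectivity formula
#' to supplied T1-weighted signal means.
#'
#' @param t1Test,t1Control \code{\linkS4class{T1Map}} objects on a common
#'   grid.
#' @param mask optional logical array; intersected with both fit masks.
#' @param mode \code{"rate"} or \code{"signal"}.
#' @param testSignalMean,controlSignalMean T1-weighted ROI means (signal
#'   mode only).
#' @return Enhancement in percent, with attribute \code{"mode"} recording
#'   which definition was used.
#' @export
t1Enhancement <- function(t1Test, t1Control, mask = NULL,
                          mode = c("rate", "signal"),
                          testSignalMean = NULL, controlSignalMean = NULL) {
  mode <- match.arg(mode)
  if (mode == "signal") {
    if (is.null(testSignalMean) || is.null(controlSignalMean))
      stop("signal mode needs testSignalMean and controlSignalMean")
    return(structure(reflectivityROI(testSignalMean, controlSignalMean),
                     mode = "signal"))
  }
  okT <- t1Test@fitMask
  okC <- t1Control@fitMask
  if (!is.null(mask)) { okT <- okT & mask; okC <- okC & mask }
  if (!any(okT) || !any(okC)) stop("empty fit-mask overlap")
  r1t <- mean(1000 / t1Test@t1[okT])
  r1c <- mean(1000 / t1Control@t1[okC])
  structure((r1t - r1c) / r1c * 100, mode = "rate")
}
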