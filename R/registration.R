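#' Mutual information of two images
#'
#' MI in nats over a \code{bins x bins} joint histogram of the two value
#' sets inside the sample mask: \code{sum p(a,b) log[p(a,b)/(p(a) p(b))]}
#' with \code{0 log 0 = 0}. \code{binning = "hard"} (the definition used by
#' the tests and oracles) assigns each sample to one bin;
#' \code{binning = "soft"} splits each sample linearly between the two
#' adjacent bins, which makes the metric continuous in the image values and
#' is what the affine optimizer uses internally.
#'
#' @param a,b \code{\linkS4class{Volume3D}} objects or numeric arrays on a
#'   common grid.
#' @param bins number of histogram bins per image.
#' @param sampleMask optional logical array; defaults to voxels valid in
#'   both images.
#' @param binning \code{"hard"} or \code{"soft"}.
#' @param rangeA,rangeB binning ranges; default the observed range of the
#'   masked values.
#' @return MI in nats.
#' @export
mutualInformation <- function(a, b, bins = 32L, sampleMask = NULL,
                              binning = c("hard", "soft"), rangeA = NULL,
                              rangeB = NULL) {
  binning <- match.arg(binning)
  va <- if (is(a, "Volume3D")) a@values else a
  vb <- if (is(b, "Volume3D")) b@values else b
  ok <- is.finite(va) & is.finite(vb)
  if (!is.null(sampleMask)) ok <- ok & sampleMask
  x <- as.numeric(va[ok]); y <- as.numeric(vb[ok])
  if (length(x) < bins)
    stop(sprintf("only %d defined voxels for %d bins", length(x), bins))
  h <- .jointHistogram(x, y, bins, binning, rangeA, rangeB)
  .miFromJoint(h)
}

.jointHistogram <- function(x, y, bins, binning = "hard", rangeA = NULL,
                            rangeB = NULL) {
  bins <- as.integer(bins)
  ra <- rangeA %||% range(x)
  rb <- rangeB %||% range(y)
  if (binning == "hard") {
    ia <- .hardBin(x, ra, bins)
    ib <- .hardBin(y, rb, bins)
    h <- matrix(tabulate(ia + bins * (ib - 1L), bins * bins), bins, bins)
  } else {
    if (rb[2] <= rb[1]) rb <- c(rb[1], rb[1] + 1)
    if (ra[2] <= ra[1]) ra <- c(ra[1], ra[1] + 1)
    h <- .soft_hist_cpp(x, y, bins, ra[1], ra[2], rb[1], rb[2])
  }
  h
}

.hardBin <- function(x, r, bins) {
  if (r[2] <= r[1]) return(rep(1L, length(x)))
  i <- floor((x - r[1]) / (r[2] - r[1]) * bins) + 1L
  pmin(pmax(i, 1L), bins)
}

.miFromJoint <- function(h) {
  p <- h / sum(h)
  pa <- rowSums(p)
  pb <- colSums(p)
  pp <- outer(pa, pb)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / pp[nz]))
}

#' Histogram entropy of one image
#'
#' Shannon entropy (nats) of the hard-binned histogram, with the same
#' binning convention as \code{\link{mutualInformation}}; MI(X, X) equals
#' this entropy.
#'
#' @inheritParams mutualInformation
#' @param x image or numeric values.
#' @param rangeX binning range.
#' @return Entropy in nats.
#' @export
histogramEntropy <- function(x, bins = 32L, sampleMask = NULL,
                             rangeX = NULL) {
  vx <- if (is(x, "Volume3D")) x@values else x
  ok <- is.finite(vx)
  if (!is.null(sampleMask)) ok <- ok & sampleMask
  v <- as.numeric(vx[ok])
  i <- .hardBin(v, rangeX %||% range(v), as.integer(bins))
  p <- tabulate(i, bins) / length(i)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Resample a volume through a transform
#'
#' Produces a volume on the reference grid; each output voxel takes the
#' interpolated input value at its mapped physical location
#' \code{T(x) = affine(x + warp(x))}. Voxels mapping outside the input
#' domain (or onto invalid input voxels) are flagged invalid, never
#' zero-filled.
#'
#' @param volume the moving \code{\linkS4class{Volume3D}}.
#' @param reference a \code{\linkS4class{Volume3D}} (or
#'   \code{\linkS4class{TubeVOI}}) defining the output grid.
#' @param affine optional \code{\linkS4class{AffineTransform12}} (or a
#'   \code{\linkS4class{RegistrationResult}}, in which case its warp is
#'   used too).
#' @param warp optional \code{\linkS4class{BSplineField}}.
#' @param interpolation \code{"linear"} or \code{"nearest"}.
#' @return A \code{\linkS4class{Volume3D}} on the reference grid.
#' @export
resampleVolume <- function(volume, reference, affine = NULL, warp = NULL,
                           interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (is(affine, "RegistrationResult")) {
    if (is.null(warp)) warp <- affine@warp
    affine <- affine@affine
  }
  outDims <- if (is(reference, "Volume3D")) dim(reference@values)
             else dim(reference@mask)
  refGeom <- reference
  A34 <- if (is.null(affine)) .identity34() else .affine34(affine)
  if (is.null(warp)) {
    coef <- numeric(); cd <- c(0L, 0L, 0L); bo <- c(0, 0, 0); bs <- c(1, 1, 1)
  } else {
    coef <- as.numeric(warp@coefficients)
    cd <- as.integer(dim(warp@coefficients)[1:3])
    bo <- warp@origin; bs <- warp@spacing
  }
  res <- .resample_cpp(
    as.numeric(volume@values),
    if (is.null(volume@valid)) NULL else as.logical(volume@valid),
    as.integer(dim(volume@values)), as.integer(outDims),
    .idx2phys(refGeom), .phys2idx(volume), A34, coef, cd, bo, bs,
    if (interpolation == "nearest") 0L else 1L)
  vals <- array(res$values, outDims)
  valid <- array(res$valid, outDims)
  vals[!valid] <- NA_real_
  Volume3D(vals, refGeom@spacing, refGeom@origin, refGeom@direction,
           meta = c(volume@meta, list(resampled = TRUE)), valid = valid)
}

#' Apply a registration's composite transform to physical points
#'
#' @param reg a \code{\linkS4class{RegistrationResult}}.
#' @param points n x 3 matrix of physical coordinates, mm.
#' @return n x 3 matrix of mapped coordinates
#'   \code{affine(x + warp(x))}.
#' @export
transformPoints <- function(reg, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (!is.null(reg@warp))
    points <- points + bsplineDisplacement(reg@warp, points)
  applyAffine(reg@affine, points)
}

#' Residual displacement against a known ground-truth deformation
#'
#' When a target was generated from a reference scene through a known
#' transform \code{T_true} (the simulator's applied affine/warp), a perfect
#' registration satisfies \code{T_true(T_reg(x)) = x}. This returns the
#' per-point composition displacement magnitudes, the registration
#' counterpart of a target-registration error.
#'
#' @param reg a \code{\linkS4class{RegistrationResult}}.
#' @param truthAffine,truthWarp the applied ground-truth transforms (either
#'   may be NULL).
#' @param points n x 3 matrix of physical test points (e.g. tube-mask
#'   voxel centers).
#' @return Numeric vector of displacement magnitudes, mm.
#' @export
registrationError <- function(reg, truthAffine = NULL, truthWarp = NULL,
                              points) {
  points <- matrix(as.numeric(points), ncol = 3)
  mapped <- transformPoints(reg, points)
  if (!is.null(truthWarp))
    mapped <- mapped + bsplineDisplacement(truthWarp, mapped)
  if (!is.null(truthAffine))
    mapped <- applyAffine(truthAffine, mapped)
  sqrt(rowSums((mapped - points)^2))
}

# dense feature image; DistanceMaps are cropped to the mask bounding box
# (plus a margin) so registration cost scales with the tube, not the scan
.asDense <- function(x, margin = 4L) {
  if (!is(x, "DistanceMap")) return(x)
  vol <- distanceMapVolume(x)
  d <- dim(vol@values)
  lo <- pmax(x@mask@bbox[1, ] - margin, 1L)
  hi <- pmin(x@mask@bbox[2, ] + margin, d)
  if (all(lo == 1L) && all(hi == d)) return(vol)
  vals <- vol@values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  Volume3D(vals, vol@spacing, as.numeric(voxelToPhysical(vol, lo)),
           vol@direction)
}

.maskCentroidOf <- function(x) {
  if (is(x, "DistanceMap")) return(x@mask@centroid)
  v <- x@values
  m <- is.finite(v) & v > 0
  if (!any(m)) m <- is.finite(v)
  colMeans(.maskPhysical(m, x))
}

#' Affine registration of distance maps by mutual information
#'
#' Finds the 12-parameter affine transform (3x3 matrix + translation about
#' the reference-tube centroid) maximizing the mutual information between
#' the reference distance map and the target distance map resampled through
#' the transform. Optimization is dense (every voxel sampled),
#' single-start, initialized at centroid alignment, and driven by L-BFGS-B
#' with finite-difference gradients on a soft-binned (continuous) MI.
#'
#' @param reference,target \code{\linkS4class{DistanceMap}} objects (or
#'   dense \code{\linkS4class{Volume3D}} feature images).
#' @param bins histogram bins for the MI metric.
#' @param maxit maximum L-BFGS-B iterations.
#' @param matrixBound,translationBoundMm box constraints on the matrix
#'   offsets from identity and on the translation.
#' @param factr L-BFGS-B convergence factor.
#' @return A \code{\linkS4class{RegistrationResult}} whose
#'   \code{metricTrace} records the improving MI values; if the optimizer
#'   fails to improve on the centroid initialization, that initialization
#'   is returned with \code{improved = FALSE} and a warning.
#' @export
registerAffine <- function(reference, target, bins = 32L, maxit = 100L,
                           matrixBound = 0.35, translationBoundMm = 20,
                           factr = 1e7) {
  fixedVol <- .asDense(reference)
  movingVol <- .asDense(target)
  ctr <- .maskCentroidOf(reference)
  t0 <- .maskCentroidOf(target) - ctr
  fvals <- as.numeric(fixedVol@values)
  ra <- .binRange(fvals)
  rb <- .binRange(as.numeric(movingVol@values))
  outDims <- as.integer(dim(fixedVol@values))
  i2p <- .idx2phys(fixedVol)
  p2i <- .phys2idx(movingVol)
  mvals <- as.numeric(movingVol@values)
  mdims <- as.integer(dim(movingVol@values))
  trScale <- 10
  nothing <- c(0L, 0L, 0L)
  minVox <- max(bins * bins, 200L)
  env <- new.env()
  env$best <- -Inf
  env$trace <- numeric()
  fn <- function(p) {
    M <- diag(3) + matrix(p[1:9], 3, 3)
    tr <- t0 + p[10:12] * trScale
    A34 <- .affine34(affineTransform(M, tr, ctr))
    res <- .resample_cpp(mvals, NULL, mdims, outDims, i2p, p2i, A34,
                         numeric(), nothing, c(0, 0, 0), c(1, 1, 1), 1L)
    ok <- res$valid
    nOk <- sum(ok)
    if (nOk < minVox) return(1e6)
    h <- .jointHistogram(fvals[ok], res$values[ok], bins, "soft", ra, rb)
    # weight by the overlap fraction: bare MI rewards shrinking the overlap
    # (dropping background voxels sharpens the histogram), which on a tube
    # lets the optimizer slide along the axis; the weight removes that
    # incentive while leaving the aligned optimum untouched
    mi <- .miFromJoint(h) * nOk / length(ok)
    if (mi > env$best) {
      env$best <- mi
      env$trace <- c(env$trace, mi)
    }
    -mi
  }
  p0 <- rep(0, 12)
  init <- fn(p0)
  lower <- c(rep(-matrixBound, 9), rep(-translationBoundMm / trScale, 3))
  upper <- -lower
  # finite-difference steps sized to the soft-MI surface: smaller steps
  # read mostly interpolation noise and stall the line search
  opt <- optim(p0, fn, method = "L-BFGS-B", lower = lower, upper = upper,
               control = list(maxit = maxit, factr = factr,
                              ndeps = rep(5e-3, 12)))
  improved <- opt$value < init
  p <- if (improved) opt$par else p0
  if (!improved)
    warning("affine optimizer failed to improve on centroid initialization")
  tf <- affineTransform(diag(3) + matrix(p[1:9], 3, 3),
                        t0 + p[10:12] * trScale, ctr)
  new("RegistrationResult", affine = tf, warp = NULL,
      metricTrace = env$trace, finalMetric = -min(opt$value, init),
      improved = improved)
}

.binRange <- function(v, probs = c(0.01, 0.99)) {
  v <- v[is.finite(v)]
  r <- as.numeric(quantile(v, probs, names = FALSE))
  if (r[2] <= r[1]) r <- range(v)
  if (r[2] <= r[1]) r <- c(r[1], r[1] + 1)
  r
}

# smooth (sigma in voxels) and subsample a dense volume by an integer factor
.shrinkVolume <- function(vol, factor, sigmaVox = 0) {
  vals <- vol@values
  vals[is.na(vals)] <- 0
  d <- dim(vals)
  if (sigmaVox > 0)
    vals <- array(.gaussian_smooth_cpp(as.numeric(vals), as.integer(d),
                                       rep(sigmaVox, 3)), d)
  if (factor > 1L) {
    ix <- seq(1, d[1], by = factor)
    iy <- seq(1, d[2], by = factor)
    iz <- seq(1, d[3], by = factor)
    vals <- vals[ix, iy, iz, drop = FALSE]
    Volume3D(vals, vol@spacing * factor, vol@origin, vol@direction)
  } else {
    Volume3D(vals, vol@spacing, vol@origin, vol@direction)
  }
}

#' Multiresolution cubic B-spline elastic registration
#'
#' Refines an initial affine alignment with a free-form deformation:
#' four resolution stages (image shrink factors 8, 4, 2, 1 with matched
#' Gaussian smoothing), control-point spacing starting at a quarter of the
#' volume extent and halving per stage (floored at twice the voxel
#' spacing), and L-BFGS-B over the control-point displacements with box
#' constraints on displacement magnitude. The default metric is
#' mean-squares on the supplied feature images (use the interior distance
#' maps for intensity-invariant shape alignment) with an exact analytic
#' gradient; \code{metric = "mi"} optimizes soft-binned mutual information
#' with finite-difference gradients instead. Coefficients are carried
#' between stages by evaluating the coarse field at the finer control
#' points. The composite transform is \code{affine(x + warp(x))}.
#'
#' @param reference,target dense \code{\linkS4class{Volume3D}} feature
#'   images (or \code{\linkS4class{DistanceMap}}s) on their native grids.
#' @param initial the affine initialization (e.g. from
#'   \code{\link{registerAffine}}).
#' @param shrink,smoothSigma per-stage shrink factors and Gaussian sigmas
#'   (voxels).
#' @param metric \code{"meansq"} or \code{"mi"}.
#' @param displacementBoundMm box constraint on control displacements.
#' @param maxit L-BFGS-B iteration cap per stage.
#' @param bins histogram bins (MI metric only).
#' @param lambda ridge penalty on the control-point displacements
#'   (\code{lambda * mean(coef^2)} added to the metric). The tube's
#'   rotational symmetry leaves tangential displacement components
#'   undetermined by any shape- or homogeneous-intensity metric; the
#'   penalty anchors those components at the minimal-deformation solution
#'   instead of letting them drift.
#' @param minControlSpacingMm floor on control spacing; defaults to four
#'   times the largest voxel spacing. Finer control grids start fitting
#'   sub-voxel boundary voxelization jitter in the feature images.
#' @return A \code{\linkS4class{RegistrationResult}} carrying the initial
#'   affine and the finest-stage \code{\linkS4class{BSplineField}};
#'   \code{metricTrace} holds the per-stage start/end metric values.
#' @export
registerBSpline <- function(reference, target, initial = affineTransform(),
                            shrink = c(8L, 4L, 2L, 1L),
                            smoothSigma = c(4, 2, 1, 0),
                            metric = c("meansq", "mi"),
                            displacementBoundMm = 10, maxit = 50L,
                            bins = 32L, lambda = 0.05,
                            minControlSpacingMm = NULL) {
  metric <- match.arg(metric)
  if (is(initial, "RegistrationResult")) initial <- initial@affine
  fixedFull <- .asDense(reference)
  movingFull <- .asDense(target)
  d <- dim(fixedFull@values)
  extent <- d * fixedFull@spacing
  minSp <- minControlSpacingMm %||% (4 * max(fixedFull@spacing))
  A34 <- .affine34(initial)
  field <- NULL
  trace <- numeric()
  rb <- .binRange(as.numeric(movingFull@values))
  ra <- .binRange(as.numeric(fixedFull@values))
  # keep at least ~8 voxels per axis at every stage so coarse levels stay
  # better-determined than the control grid
  maxShrink <- max(1L, floor(min(d) / 8))
  for (s in seq_along(shrink)) {
    f <- min(shrink[s], maxShrink)
    fixed <- .shrinkVolume(fixedFull, f, smoothSigma[s])
    moving <- .shrinkVolume(movingFull, f, smoothSigma[s])
    delta <- pmax(extent / 4 / 2^(s - 1), minSp)
    bso <- fixedFull@origin - delta
    ng <- as.integer(ceiling(extent / delta) + 4)
    coef <- array(0, c(ng, 3))
    if (!is.null(field)) {
      cp <- .gridPhys(bso, delta, ng)
      u <- bsplineDisplacement(field, cp)
      coef <- array(u, c(ng, 3))
    }
    outDims <- as.integer(dim(fixed@values))
    i2p <- .idx2phys(fixed)
    p2i <- .phys2idx(moving)
    fvals <- as.numeric(fixed@values)
    mvals <- as.numeric(moving@values)
    mdims <- as.integer(dim(moving@values))
    if (metric == "meansq") {
      cache <- new.env()
      evalAt <- function(p) {
        if (!identical(cache$p, p)) {
          cache$res <- .ssd_ffd_cpp(fvals, NULL, mvals, NULL, mdims,
                                    outDims, i2p, p2i, A34, p, ng, bso,
                                    delta)
          cache$p <- p
        }
        cache$res
      }
      fn <- function(p) evalAt(p)$value + lambda * mean(p^2)
      gr <- function(p) evalAt(p)$gradient + 2 * lambda * p / length(p)
    } else {
      fn <- function(p) {
        res <- .resample_cpp(mvals, NULL, mdims, outDims, i2p, p2i, A34,
                             p, ng, bso, delta, 1L)
        ok <- res$valid
        if (sum(ok) < bins * bins) return(1e6)
        -.miFromJoint(.jointHistogram(fvals[ok], res$values[ok], bins,
                                      "soft", ra, rb)) + lambda * mean(p^2)
      }
      gr <- NULL
    }
    p0 <- as.numeric(coef)
    v0 <- fn(p0)
    opt <- optim(p0, fn, gr, method = "L-BFGS-B",
                 lower = -displacementBoundMm, upper = displacementBoundMm,
                 control = list(maxit = maxit))
    pBest <- if (opt$value <= v0) opt$par else p0
    trace <- c(trace, v0, min(opt$value, v0))
    field <- bsplineField(array(pBest, c(ng, 3)), bso, delta)
  }
  new("RegistrationResult", affine = initial, warp = field,
      metricTrace = trace, finalMetric = trace[length(trace)],
      improved = TRUE)
}

.gridPhys <- function(origin, spacing, n) {
  i <- (seq_len(n[1]) - 1) * spacing[1] + origin[1]
  j <- (seq_len(n[2]) - 1) * spacing[2] + origin[2]
  k <- (seq_len(n[3]) - 1) * spacing[3] + origin[3]
  cbind(rep(i, times = n[2] * n[3]),
        rep(rep(j, each = n[1]), times = n[3]),
        rep(k, each = n[1] * n[2]))
}
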