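#' Specify a synthetic tube
#'
#' @param center cylinder center, mm.
#' @param radius cylinder radius, mm.
#' @param length cylinder length, mm.
#' @param axis cylinder axis (normalized internally).
#' @param signal mean T1-weighted intensity, a.u.
#' @param t1Ms,s0 relaxation time (ms) and equilibrium signal for TR-series
#'   generation; may be omitted for plain T1-weighted phantoms.
#' @param role tube role: \code{"test"}, \code{"control"} or \code{"water"}.
#' @return A \code{\linkS4class{TubeSpec}}.
#' @export
tubeSpec <- function(center, radius, length, axis = c(0, 0, 1),
                     signal = NA_real_, t1Ms = NA_real_, s0 = NA_real_,
                     role = "test") {
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("axis must be nonzero")
  new("TubeSpec", center = as.numeric(center), radius = radius,
      length = length, axis = axis / nrm, signal = signal, t1Ms = t1Ms,
      s0 = s0, role = role)
}

#' Specify a synthetic tube phantom
#'
#' @param tubes list of \code{\link{tubeSpec}} objects.
#' @param gridShape voxels per axis (default 64 x 64 x 64).
#' @param spacing mm per voxel.
#' @param backgroundLevel background signal, a.u.
#' @param noiseSigma Rician noise scale (per Gaussian component), a.u.
#' @param appliedAffine,appliedWarp optional known misalignment; the scene
#'   is sampled at \code{affine(x + warp(x))} so the stored transforms are
#'   the ground truth a registration should invert.
#' @param seed integer seed; identical specs (including seed) produce
#'   bit-identical phantoms.
#' @return A \code{\linkS4class{PhantomSpec}}. The grid is centered on the
#'   physical origin.
#' @export
phantomSpec <- function(tubes, gridShape = c(64L, 64L, 64L),
                        spacing = c(1, 1, 1), backgroundLevel = 0,
                        noiseSigma = 0, appliedAffine = NULL,
                        appliedWarp = NULL, seed = 1L) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      spacing = as.numeric(spacing), tubes = tubes,
      backgroundLevel = backgroundLevel, noiseSigma = noiseSigma,
      appliedAffine = appliedAffine, appliedWarp = appliedWarp,
      seed = as.integer(seed))
}

#' Default three-tube phantom layout
#'
#' One test tube, one control tube and one water tube side by side on a
#' common axial grid, mirroring a tube rack in a volume coil: 64 mm^3 field
#' of view at 1 mm isotropic spacing, tubes of 6 mm radius and 40 mm length
#' along z at x = -20, 0, +20 mm. Default signals put the test tube at 1.2x
#' the control (120 vs 100 a.u.) with water at 60 a.u. (water is dark on
#' T1-weighted images); default T1s are 800 / 1600 / 3000 ms with s0 1000.
#'
#' @param testSignal,controlSignal,waterSignal tube means, a.u.
#' @param noiseSigma Rician noise scale, a.u.
#' @param seed integer seed.
#' @param ... passed on to \code{\link{phantomSpec}} (e.g.
#'   \code{appliedAffine}, \code{appliedWarp}).
#' @return A \code{\linkS4class{PhantomSpec}}.
#' @export
defaultPhantomSpec <- function(testSignal = 120, controlSignal = 100,
                               waterSignal = 60, noiseSigma = 2, seed = 1L,
                               ...) {
  tubes <- list(
    tubeSpec(c(-20, 0, 0), radius = 6, length = 40, signal = testSignal,
             t1Ms = 800, s0 = 1000, role = "test"),
    tubeSpec(c(0, 0, 0), radius = 6, length = 40, signal = controlSignal,
             t1Ms = 1600, s0 = 1000, role = "control"),
    tubeSpec(c(20, 0, 0), radius = 6, length = 40, signal = waterSignal,
             t1Ms = 3000, s0 = 1000, role = "water"))
  phantomSpec(tubes, gridShape = c(64L, 64L, 64L), spacing = c(1, 1, 1),
              backgroundLevel = 0, noiseSigma = noiseSigma, seed = seed, ...)
}

# physical voxel-center coordinates of a centered grid, as an n x 3 matrix
.gridPoints <- function(gridShape, spacing) {
  org <- -(gridShape - 1) / 2 * spacing
  i <- (seq_len(gridShape[1]) - 1) * spacing[1] + org[1]
  j <- (seq_len(gridShape[2]) - 1) * spacing[2] + org[2]
  k <- (seq_len(gridShape[3]) - 1) * spacing[3] + org[3]
  list(origin = org,
       pts = cbind(rep(i, times = gridShape[2] * gridShape[3]),
                   rep(rep(j, each = gridShape[1]), times = gridShape[3]),
                   rep(k, each = gridShape[1] * gridShape[2])))
}

# TRUE for points inside the (continuous) cylinder
.inCylinder <- function(pts, tube) {
  rel <- sweep(pts, 2, tube@center)
  along <- rel %*% tube@axis
  rad2 <- rowSums(rel^2) - along^2
  (abs(along) <= tube@length / 2) & (rad2 <= tube@radius^2)
}

# bounding box (mm) of a cylinder
.cylinderBounds <- function(tube) {
  a <- tube@axis
  half <- abs(a) * tube@length / 2 + sqrt(pmax(0, 1 - a^2)) * tube@radius
  rbind(tube@center - half, tube@center + half)
}

#' Generate a synthetic tube phantom
#'
#' Voxels whose centers fall inside a tube cylinder take that tube's signal,
#' all others the background level; Rician noise (magnitude of the signal
#' plus two independent Gaussian components of scale \code{noiseSigma}) is
#' then applied. When the spec carries an applied affine/warp, the
#' continuous scene is evaluated at the deformed location
#' \code{affine(x + warp(x))} — exact resampling of the ideal scene — and
#' the true transforms are returned alongside.
#'
#' @param spec a \code{\linkS4class{PhantomSpec}}.
#' @return A \code{\linkS4class{TubePhantom}} with the noisy volume, the
#'   ground-truth label array and the applied transforms.
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  for (t in spec@tubes) validObject(t)
  gp <- .gridPoints(spec@gridShape, spec@spacing)
  ext <- rbind(gp$origin - spec@spacing / 2,
               gp$origin + (spec@gridShape - 0.5) * spec@spacing)
  for (ti in seq_along(spec@tubes)) {
    b <- .cylinderBounds(spec@tubes[[ti]])
    if (any(b[1, ] < ext[1, ]) || any(b[2, ] > ext[2, ]))
      stop(sprintf("tube %d (%s) extends outside the grid", ti,
                   spec@tubes[[ti]]@role))
  }
  pts <- gp$pts
  if (!is.null(spec@appliedWarp))
    pts <- pts + bsplineDisplacement(spec@appliedWarp, pts)
  if (!is.null(spec@appliedAffine))
    pts <- applyAffine(spec@appliedAffine, pts)
  labels <- integer(nrow(pts))
  for (ti in seq_along(spec@tubes)) {
    inside <- .inCylinder(pts, spec@tubes[[ti]])
    if (any(labels[inside] != 0L))
      stop(sprintf("tube %d (%s) overlaps tube %d", ti,
                   spec@tubes[[ti]]@role, max(labels[inside])))
    labels[inside] <- ti
  }
  values <- rep(spec@backgroundLevel, nrow(pts))
  for (ti in seq_along(spec@tubes)) {
    s <- spec@tubes[[ti]]@signal
    if (!is.na(s)) values[labels == ti] <- s
  }
  values <- .addRician(values, spec@noiseSigma, spec@seed)
  dim(values) <- spec@gridShape
  labels <- array(labels, spec@gridShape)
  vol <- Volume3D(values, spec@spacing, gp$origin,
                  meta = list(description = "synthetic tube phantom",
                              seed = spec@seed))
  new("TubePhantom", volume = vol, labels = labels, spec = spec,
      appliedAffine = spec@appliedAffine, appliedWarp = spec@appliedWarp)
}

# Rician noise: magnitude of (S + N(0,s), N(0,s)); restores the caller's
# RNG state so generation is reproducible and side-effect free
.addRician <- function(values, sigma, seed) {
  if (sigma <= 0) return(values)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  n <- length(values)
  sqrt((values + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
}

#' Generate an arrayed-TR saturation-recovery series
#'
#' One volume per repetition time, co-registered by construction, with
#' noiseless voxel signal \code{S(TR) = s0 (1 - exp(-TR / t1Ms))} inside
#' each tube before Rician noise. Every tube must carry \code{t1Ms} and
#' \code{s0}.
#'
#' @param spec a \code{\linkS4class{PhantomSpec}}.
#' @param trListMs repetition times in ms (positive).
#' @return List with \code{series} (list of \code{\linkS4class{Volume3D}},
#'   one per TR, each tagged with \code{TR_ms} metadata), \code{labels}
#'   and \code{trMs}.
#' @export
generateTRSeries <- function(spec, trListMs) {
  stopifnot(length(trListMs) >= 1, all(trListMs > 0))
  for (ti in seq_along(spec@tubes)) {
    tb <- spec@tubes[[ti]]
    if (is.na(tb@t1Ms) || is.na(tb@s0))
      stop(sprintf("tube %d (%s) is missing t1Ms/s0", ti, tb@role))
  }
  base <- generatePhantom(.noiseless(spec))
  labels <- base@labels
  series <- vector("list", length(trListMs))
  for (q in seq_along(trListMs)) {
    tr <- trListMs[q]
    values <- array(spec@backgroundLevel, spec@gridShape)
    for (ti in seq_along(spec@tubes)) {
      tb <- spec@tubes[[ti]]
      values[labels == ti] <- tb@s0 * (1 - exp(-tr / tb@t1Ms))
    }
    values <- .addRician(as.numeric(values), spec@noiseSigma,
                         spec@seed + q)
    dim(values) <- spec@gridShape
    series[[q]] <- Volume3D(values, spec@spacing, base@volume@origin,
                            meta = list(TR_ms = tr))
  }
  list(series = series, labels = labels, trMs = trListMs)
}

.noiseless <- function(spec) {
  s <- spec
  s@noiseSigma <- 0
  s
}

setMethod("show", "TubePhantom", function(object) {
  cat(sprintf("TubePhantom: %d tubes on a %s grid%s\n",
              length(object@spec@tubes),
              paste(dim(object@labels), collapse = " x "),
              if (is.null(object@appliedAffine) &&
                  is.null(object@appliedWarp)) ""
              else " (with applied misalignment)"))
  show(object@volume)
})
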