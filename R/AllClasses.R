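#' 3D scalar MRI volume with physical geometry
#'
#' A scalar signal field on a regular 3D grid together with the mapping from
#' 0-based voxel indices to physical (mm) coordinates:
#' \code{phys = origin + direction \%*\% (spacing * index)}. Voxels can be
#' flagged invalid (e.g. outside a resampling domain); invalid voxels carry
#' \code{NA} in \code{values} and \code{FALSE} in \code{valid}, and are
#' excluded from all downstream sums.
#'
#' @slot values 3D numeric array of signal values (arbitrary units).
#' @slot spacing numeric(3), voxel spacing in mm (strictly positive).
#' @slot origin numeric(3), physical coordinate of voxel (0,0,0), mm.
#' @slot direction 3x3 orthonormal direction-cosine matrix.
#' @slot valid logical array matching \code{values}, or \code{NULL} meaning
#'   all voxels valid.
#' @slot meta named list of acquisition metadata (e.g. \code{TR_ms},
#'   \code{TE_ms}, \code{description}, provenance entries).
#' @export
setClass("Volume3D",
  representation(values = "array", spacing = "numeric", origin = "numeric",
                 direction = "matrix", valid = "ANY", meta = "list"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0),
            direction = diag(3), valid = NULL, meta = list()))

setValidity("Volume3D", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite numbers")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite numbers")
  if (!all(dim(object@direction) == c(3L, 3L)) ||
      max(abs(crossprod(object@direction) - diag(3))) > 1e-6)
    msg <- c(msg, "direction must be a 3x3 orthonormal matrix")
  if (!is.null(object@valid)) {
    if (!is.logical(object@valid) ||
        !identical(dim(object@valid), dim(object@values)))
      msg <- c(msg, "valid must be NULL or a logical array matching values")
    else if (any(!is.finite(object@values[object@valid])))
      msg <- c(msg, "values flagged valid must be finite")
  } else if (any(!is.finite(object@values))) {
    msg <- c(msg, "values must be finite when no valid mask is supplied")
  }
  if (length(msg)) msg else TRUE
})

#' Labeled tube volume of interest
#'
#' A boolean voxel mask for one Eppendorf tube, aligned to its parent
#' volume's grid and carrying the same physical geometry so it remains
#' self-contained after cropping.
#'
#' @slot mask logical 3D array.
#' @slot role one of \code{"test"}, \code{"control"}, \code{"water"},
#'   \code{"unknown"}.
#' @slot bbox 2x3 integer matrix of inclusive 1-based index ranges
#'   (row 1 = lower, row 2 = upper) tightly bounding the mask.
#' @slot centroid numeric(3), physical centroid of the mask voxels, mm.
#' @slot voxelCount number of \code{TRUE} voxels.
#' @slot spacing,origin,direction grid geometry, as in
#'   \code{\linkS4class{Volume3D}}.
#' @export
setClass("TubeVOI",
  representation(mask = "array", role = "character", bbox = "matrix",
                 centroid = "numeric", voxelCount = "integer",
                 spacing = "numeric", origin = "numeric",
                 direction = "matrix"))

setValidity("TubeVOI", function(object) {
  msg <- character()
  if (!is.logical(object@mask) || length(dim(object@mask)) != 3L)
    msg <- c(msg, "mask must be a logical 3D array")
  n <- sum(object@mask)
  if (n < 1L) msg <- c(msg, "mask must contain at least one voxel")
  if (object@voxelCount != n)
    msg <- c(msg, "voxelCount must equal the number of TRUE mask voxels")
  if (!object@role %in% c("test", "control", "water", "unknown"))
    msg <- c(msg, "role must be test, control, water or unknown")
  if (n >= 1L) {
    idx <- which(object@mask, arr.ind = TRUE)
    bb <- rbind(apply(idx, 2, min), apply(idx, 2, max))
    if (!all(object@bbox == bb)) msg <- c(msg, "bbox must tightly bound the mask")
  }
  if (length(msg)) msg else TRUE
})

#' Interior Euclidean distance map of a tube mask
#'
#' Distances (mm) from every mask voxel to the object boundary, solved by
#' first-order fast marching. Boundary voxels (mask voxels with at least one
#' face-connected non-mask neighbour, the grid border counting as outside)
#' carry exactly 0; voxels outside the mask are invalid (\code{NA}).
#'
#' @slot values numeric 3D array, \code{NA} outside the mask.
#' @slot mask the defining \code{\linkS4class{TubeVOI}}.
#' @export
setClass("DistanceMap",
  representation(values = "array", mask = "TubeVOI"))

setValidity("DistanceMap", function(object) {
  msg <- character()
  if (!identical(dim(object@values), dim(object@mask@mask)))
    msg <- c(msg, "values grid must match the mask grid")
  v <- object@values[object@mask@mask]
  if (any(is.na(v)) || any(v < 0))
    msg <- c(msg, "distances on the mask must be defined and non-negative")
  if (any(!is.na(object@values[!object@mask@mask])))
    msg <- c(msg, "values outside the mask must be NA")
  if (length(msg)) msg else TRUE
})

#' 12-parameter affine transform
#'
#' Physical-space mapping \code{T(x) = matrix \%*\% (x - center) + center +
#' translation} with 12 free parameters (9 matrix entries + 3 translations)
#' about a fixed rotation center.
#'
#' @slot matrix 3x3 real matrix (invertible).
#' @slot translation numeric(3), mm.
#' @slot center numeric(3), fixed rotation center, mm.
#' @export
setClass("AffineTransform12",
  representation(matrix = "matrix", translation = "numeric",
                 center = "numeric"),
  prototype(matrix = diag(3), translation = c(0, 0, 0),
            center = c(0, 0, 0)))

setValidity("AffineTransform12", function(object) {
  msg <- character()
  if (!all(dim(object@matrix) == c(3L, 3L)) || !all(is.finite(object@matrix)))
    msg <- c(msg, "matrix must be a finite 3x3 matrix")
  else if (abs(det(object@matrix)) < 1e-12)
    msg <- c(msg, "matrix must be invertible")
  if (length(object@translation) != 3L || any(!is.finite(object@translation)))
    msg <- c(msg, "translation must be 3 finite numbers")
  if (length(object@center) != 3L || any(!is.finite(object@center)))
    msg <- c(msg, "center must be 3 finite numbers")
  if (length(msg)) msg else TRUE
})

#' Cubic B-spline free-form deformation field
#'
#' A dense displacement field parameterized by a regular grid of control
#' points with uniform cubic B-spline (order 3) interpolation. Displacement
#' at physical point x is the tensor-product sum of the 4x4x4 surrounding
#' control coefficients; zero coefficients give the identity deformation.
#'
#' @slot origin numeric(3), physical location of control point (0,0,0), mm.
#' @slot spacing numeric(3), control-point spacing, mm.
#' @slot coefficients 4D array \code{[nx, ny, nz, 3]} of control-point
#'   displacements, mm.
#' @export
setClass("BSplineField",
  representation(origin = "numeric", spacing = "numeric",
                 coefficients = "array"))

setValidity("BSplineField", function(object) {
  msg <- character()
  d <- dim(object@coefficients)
  if (length(d) != 4L || d[4] != 3L)
    msg <- c(msg, "coefficients must be an [nx, ny, nz, 3] array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive numbers")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite numbers")
  if (length(msg)) msg else TRUE
})

#' Result of a registration stage
#'
#' @slot affine the \code{\linkS4class{AffineTransform12}} component.
#' @slot warp a \code{\linkS4class{BSplineField}} applied before the affine
#'   (composite \code{T(x) = affine(x + warp(x))}), or \code{NULL}.
#' @slot metricTrace numeric vector of accepted (improving) metric values.
#' @slot finalMetric final metric value.
#' @slot improved \code{TRUE} when the optimizer improved on its
#'   initialization; otherwise the initialization is returned with this flag
#'   set to \code{FALSE}.
#' @export
setClass("RegistrationResult",
  representation(affine = "AffineTransform12", warp = "ANY",
                 metricTrace = "numeric", finalMetric = "numeric",
                 improved = "logical"),
  prototype(warp = NULL, metricTrace = numeric(), finalMetric = NA_real_,
            improved = TRUE))

#' Voxel-wise reflectivity result
#'
#' Global percent reflectivity R = sum(I_i - g_i) / sum(g_i) x 100 over the
#' analysis mask, plus the per-voxel percent map (NA where flagged) and the
#' voxel count N that entered the sums.
#'
#' @slot globalPercent global reflectivity, percent.
#' @slot voxelMap numeric 3D array of per-voxel percent reflectivity,
#'   \code{NA} where flagged (invalid or control signal <= 0).
#' @slot nVoxels number of voxels contributing to the sums.
#' @slot provenance named list (water means, transform summary, masks used).
#' @export
setClass("ReflectivityResult",
  representation(globalPercent = "numeric", voxelMap = "array",
                 nVoxels = "integer", provenance = "list"))

setValidity("ReflectivityResult", function(object) {
  if (object@nVoxels < 1L) "nVoxels must be positive" else TRUE
})

#' Paired t-test result
#'
#' @slot statistic t statistic on the paired differences.
#' @slot df degrees of freedom (n - 1).
#' @slot pValue two-tailed p value from the exact Student-t distribution.
#' @export
setClass("TTestResult",
  representation(statistic = "numeric", df = "numeric", pValue = "numeric"))

#' Voxel-wise T1 map from an arrayed-TR spin-echo series
#'
#' Per-voxel saturation-recovery fit S(TR) = s0 (1 - exp(-TR/T1)); the
#' constant TE-decay factor is absorbed into s0.
#'
#' @slot t1 numeric 3D array, T1 in ms (NA outside \code{fitMask}).
#' @slot s0 numeric 3D array, equilibrium signal (NA outside \code{fitMask}).
#' @slot rmse numeric 3D array of fit residuals.
#' @slot fitMask logical array of voxels fitted.
#' @slot reason integer array of exclusion codes (0 fitted, 1 outside the
#'   requested mask, 2 degenerate/no TR dependence, 3 solver failure).
#' @export
setClass("T1Map",
  representation(t1 = "array", s0 = "array", rmse = "array",
                 fitMask = "array", reason = "array"))

#' Relaxivity regression
#'
#' Ordinary least squares of the relaxation rate R1 = 1/T1 (s^-1) against
#' contrast-agent concentration (mM): slope = r1 (mM^-1 s^-1), intercept =
#' diamagnetic rate of the matrix.
#'
#' @slot r1 relaxivity slope, mM^-1 s^-1.
#' @slot intercept diamagnetic relaxation rate, s^-1.
#' @slot rSquared coefficient of determination.
#' @slot n number of points fitted.
#' @export
setClass("RelaxivityFit",
  representation(r1 = "numeric", intercept = "numeric",
                 rSquared = "numeric", n = "integer"))

#' Xylenol-orange gadolinium calibration
#'
#' Calibration line ratio = slope x concentration + intercept, and the
#' inversion coefficients used as concentration = coeffA + coeffB x ratio.
#' In \code{inverse_consistent} mode coeffA = 1/slope and
#' coeffB = -intercept/slope, so forward and inverse compose to the
#' identity; in \code{as_printed} mode coeffA/coeffB are stored verbatim.
#'
#' @slot slope,intercept calibration line of absorbance ratio on
#'   concentration.
#' @slot coeffA,coeffB inversion coefficients.
#' @slot mode \code{"as_printed"} or \code{"inverse_consistent"}.
#' @export
setClass("GdCalibration",
  representation(slope = "numeric", intercept = "numeric",
                 coeffA = "numeric", coeffB = "numeric", mode = "character"))

setValidity("GdCalibration", function(object) {
  msg <- character()
  if (!object@mode %in% c("as_printed", "inverse_consistent"))
    msg <- c(msg, "mode must be as_printed or inverse_consistent")
  if (abs(object@slope) < 1e-15) msg <- c(msg, "slope must be nonzero")
  if (object@mode == "inverse_consistent") {
    if (abs(object@coeffA - 1 / object@slope) > 1e-10 ||
        abs(object@coeffB + object@intercept / object@slope) > 1e-10)
      msg <- c(msg,
        "inverse_consistent requires coeffA = 1/slope, coeffB = -intercept/slope")
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic tube specification
#'
#' One cylindrical tube in a phantom: geometry in physical mm plus either a
#' mean T1-weighted signal or (t1Ms, s0) for TR-series generation.
#'
#' @slot center numeric(3), cylinder center, mm.
#' @slot radius cylinder radius, mm (> 0).
#' @slot length cylinder length, mm (> 0).
#' @slot axis unit 3-vector along the cylinder axis.
#' @slot signal mean T1-weighted intensity, a.u. (may be NA if t1Ms given).
#' @slot t1Ms longitudinal relaxation time, ms (> 0 when present, else NA).
#' @slot s0 equilibrium signal for series generation (NA if unused).
#' @slot role \code{"test"}, \code{"control"} or \code{"water"}.
#' @export
setClass("TubeSpec",
  representation(center = "numeric", radius = "numeric", length = "numeric",
                 axis = "numeric", signal = "numeric", t1Ms = "numeric",
                 s0 = "numeric", role = "character"))

setValidity("TubeSpec", function(object) {
  msg <- character()
  if (object@radius <= 0) msg <- c(msg, "radius must be > 0")
  if (object@length <= 0) msg <- c(msg, "length must be > 0")
  if (abs(sqrt(sum(object@axis^2)) - 1) > 1e-8)
    msg <- c(msg, "axis must have unit norm")
  if (!is.na(object@t1Ms) && object@t1Ms <= 0)
    msg <- c(msg, "t1Ms must be > 0 when present")
  if (!object@role %in% c("test", "control", "water"))
    msg <- c(msg, "role must be test, control or water")
  if (length(msg)) msg else TRUE
})

#' Synthetic phantom specification
#'
#' @slot gridShape integer(3), voxels per axis.
#' @slot spacing numeric(3), mm per voxel (> 0).
#' @slot tubes list of \code{\linkS4class{TubeSpec}}.
#' @slot backgroundLevel background signal, a.u. (>= 0).
#' @slot noiseSigma Rician noise scale, same units (>= 0).
#' @slot appliedAffine \code{\linkS4class{AffineTransform12}} or \code{NULL}:
#'   known misalignment applied when sampling the scene.
#' @slot appliedWarp \code{\linkS4class{BSplineField}} or \code{NULL}.
#' @slot seed integer seed for the noise stream.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", spacing = "numeric", tubes = "list",
                 backgroundLevel = "numeric", noiseSigma = "numeric",
                 appliedAffine = "ANY", appliedWarp = "ANY",
                 seed = "integer"),
  prototype(appliedAffine = NULL, appliedWarp = NULL, seed = 1L))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    msg <- c(msg, "gridShape must be 3 positive integers")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive numbers")
  if (object@backgroundLevel < 0) msg <- c(msg, "backgroundLevel must be >= 0")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (!all(vapply(object@tubes, is, TRUE, "TubeSpec")))
    msg <- c(msg, "tubes must be a list of TubeSpec objects")
  if (length(msg)) msg else TRUE
})

#' Simulated tube phantom with ground truth
#'
#' @slot volume the noisy \code{\linkS4class{Volume3D}}.
#' @slot labels integer 3D array: 0 background, i for tube i in
#'   \code{spec@tubes} (evaluated through any applied deformation).
#' @slot spec the generating \code{\linkS4class{PhantomSpec}}.
#' @slot appliedAffine,appliedWarp the true applied transforms (or NULL);
#'   the scene was sampled as \code{scene(affine(x + warp(x)))}.
#' @export
setClass("TubePhantom",
  representation(volume = "Volume3D", labels = "array", spec = "PhantomSpec",
                 appliedAffine = "ANY", appliedWarp = "ANY"),
  prototype(appliedAffine = NULL, appliedWarp = NULL))
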