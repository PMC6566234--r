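#' Construct a 12-parameter affine transform
#'
#' \code{T(x) = matrix \%*\% (x - center) + center + translation}, all in
#' physical mm coordinates.
#'
#' @param matrix 3x3 matrix (default identity).
#' @param translation length-3 translation, mm.
#' @param center fixed rotation center, mm.
#' @return An \code{\linkS4class{AffineTransform12}}.
#' @export
affineTransform <- function(matrix = diag(3), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  new("AffineTransform12", matrix = matrix,
      translation = as.numeric(translation), center = as.numeric(center))
}

#' Rotation-scale-translation convenience constructor
#'
#' Builds an affine from Euler angles (degrees, applied z then y then x),
#' per-axis scales and a translation, about a given center.
#'
#' @param angles rotation angles in degrees about the x, y, z axes.
#' @param scales per-axis scale factors.
#' @param translation length-3 translation, mm.
#' @param center rotation center, mm.
#' @return An \code{\linkS4class{AffineTransform12}}.
#' @export
affineFromParams <- function(angles = c(0, 0, 0), scales = c(1, 1, 1),
                             translation = c(0, 0, 0), center = c(0, 0, 0)) {
  a <- angles * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])),
              c(0, sin(a[1]), cos(a[1])))
  Ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0),
              c(-sin(a[2]), 0, cos(a[2])))
  Rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0),
              c(0, 0, 1))
  affineTransform(Rx %*% Ry %*% Rz %*% diag(scales, 3), translation, center)
}

# 3x4 matrix [R | b] with T(x) = R x + b
.affine34 <- function(tf) {
  b <- tf@center + tf@translation - tf@matrix %*% tf@center
  cbind(tf@matrix, as.numeric(b))
}

.identity34 <- function() cbind(diag(3), c(0, 0, 0))

#' Apply an affine transform to physical points
#'
#' @param tf an \code{\linkS4class{AffineTransform12}}.
#' @param points n x 3 matrix of physical coordinates, mm.
#' @return n x 3 matrix of mapped coordinates.
#' @export
applyAffine <- function(tf, points) {
  points <- matrix(points, ncol = 3)
  A <- .affine34(tf)
  t(A %*% rbind(t(points), 1))
}

#' Invert an affine transform
#'
#' @param tf an \code{\linkS4class{AffineTransform12}}.
#' @return The inverse transform (same center).
#' @export
invertAffine <- function(tf) {
  A <- .affine34(tf)           # T(x) = R x + b
  Ri <- solve(A[, 1:3])
  bi <- as.numeric(-Ri %*% A[, 4])
  # express R^-1 y + bi about the same center c:
  # Mi (y - c) + c + ti  with  Mi = R^-1,  ti = bi - c + Mi c
  ctr <- tf@center
  affineTransform(Ri, bi - ctr + as.numeric(Ri %*% ctr), ctr)
}

#' Compose two affine transforms
#'
#' @param outer,inner transforms; the result maps x to
#'   \code{outer(inner(x))}.
#' @return The composed \code{\linkS4class{AffineTransform12}}, centered at
#'   \code{inner}'s center.
#' @export
composeAffine <- function(outer, inner) {
  Ao <- .affine34(outer)
  Ai <- .affine34(inner)
  R <- Ao[, 1:3] %*% Ai[, 1:3]
  b <- Ao[, 1:3] %*% Ai[, 4] + Ao[, 4]
  ctr <- inner@center
  affineTransform(R, as.numeric(b - (ctr - R %*% ctr)), ctr)
}

setMethod("show", "AffineTransform12", function(object) {
  cat("AffineTransform12\n  matrix:\n")
  print(round(object@matrix, 6))
  cat("  translation (mm):",
      paste(format(object@translation, digits = 5), collapse = ", "), "\n")
  cat("  center (mm):",
      paste(format(object@center, digits = 5), collapse = ", "), "\n")
})

#' Construct a cubic B-spline deformation field
#'
#' @param coefficients \code{[nx, ny, nz, 3]} array of control-point
#'   displacements (mm); \code{bsplineField(gridShape=...)} with no
#'   coefficients builds a zero (identity) field.
#' @param origin physical position of control point (0,0,0), mm.
#' @param spacing control-point spacing, mm.
#' @param gridShape integer(3); used with zero coefficients when
#'   \code{coefficients} is missing.
#' @return A \code{\linkS4class{BSplineField}}.
#' @export
bsplineField <- function(coefficients = NULL, origin, spacing,
                         gridShape = NULL) {
  if (is.null(coefficients)) {
    stopifnot(!is.null(gridShape))
    coefficients <- array(0, c(gridShape, 3))
  }
  new("BSplineField", origin = as.numeric(origin),
      spacing = as.numeric(spacing), coefficients = coefficients)
}

#' Evaluate a B-spline displacement field at physical points
#'
#' @param field a \code{\linkS4class{BSplineField}}.
#' @param points n x 3 matrix of physical coordinates, mm.
#' @return n x 3 matrix of displacements, mm.
#' @export
bsplineDisplacement <- function(field, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  d <- dim(field@coefficients)
  .ffd_displacement_cpp(points, as.numeric(field@coefficients),
                        as.integer(d[1:3]), field@origin, field@spacing)
}

setMethod("show", "BSplineField", function(object) {
  d <- dim(object@coefficients)
  mx <- max(abs(object@coefficients))
  cat(sprintf(
    "BSplineField: %d x %d x %d control points, spacing %s mm, max |coef| %.3f mm\n",
    d[1], d[2], d[3],
    paste(format(object@spacing, digits = 4), collapse = " x "), mx))
})

setMethod("show", "RegistrationResult", function(object) {
  cat("RegistrationResult\n")
  cat(sprintf("  final metric: %.6g (%s)\n", object@finalMetric,
              if (object@improved) "improved" else "initialization kept"))
  cat(sprintf("  trace length: %d\n", length(object@metricTrace)))
  if (!is.null(object@warp)) show(object@warp)
})

#' Serialize transforms to and from JSON
#'
#' Writes the affine parameters and (if present) the B-spline control grid
#' and coefficients as a JSON document.
#'
#' @param reg a \code{\linkS4class{RegistrationResult}},
#'   \code{\linkS4class{AffineTransform12}} or
#'   \code{\linkS4class{BSplineField}}.
#' @param path file to write / read.
#' @return \code{readTransform} returns a
#'   \code{\linkS4class{RegistrationResult}}.
#' @export
writeTransform <- function(reg, path) {
  if (is(reg, "AffineTransform12"))
    reg <- new("RegistrationResult", affine = reg)
  if (is(reg, "BSplineField"))
    reg <- new("RegistrationResult", affine = affineTransform(), warp = reg)
  doc <- list(
    affine = list(matrix = as.vector(reg@affine@matrix),
                  translation = reg@affine@translation,
                  center = reg@affine@center),
    finalMetric = reg@finalMetric, improved = reg@improved,
    metricTrace = reg@metricTrace)
  if (!is.null(reg@warp)) {
    doc$warp <- list(origin = reg@warp@origin, spacing = reg@warp@spacing,
                     gridShape = dim(reg@warp@coefficients)[1:3],
                     coefficients = as.vector(reg@warp@coefficients))
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  aff <- affineTransform(matrix(doc$affine$matrix, 3, 3),
                         doc$affine$translation, doc$affine$center)
  warp <- NULL
  if (!is.null(doc$warp)) {
    warp <- bsplineField(
      array(doc$warp$coefficients, c(doc$warp$gridShape, 3)),
      doc$warp$origin, doc$warp$spacing)
  }
  new("RegistrationResult", affine = aff, warp = warp,
      metricTrace = as.numeric(doc$metricTrace %||% numeric()),
      finalMetric = as.numeric(doc$finalMetric %||% NA_real_),
      improved = isTRUE(doc$improved))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
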