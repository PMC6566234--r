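#' Construct a Volume3D
#'
#' @param values 3D numeric array (NA marks invalid voxels).
#' @param spacing voxel spacing in mm, length 3.
#' @param origin physical coordinate of voxel (0,0,0) in mm, length 3.
#' @param direction 3x3 orthonormal direction matrix.
#' @param meta named list of metadata.
#' @param valid optional logical array; defaults to \code{!is.na(values)}
#'   when NAs are present, otherwise NULL (all valid).
#' @return A \code{\linkS4class{Volume3D}}.
#' @export
Volume3D <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     direction = diag(3), meta = list(), valid = NULL) {
  values <- as.array(values)
  storage.mode(values) <- "double"
  if (is.null(valid) && anyNA(values)) valid <- !is.na(values)
  new("Volume3D", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), direction = direction, meta = meta,
      valid = valid)
}

#' @describeIn Volume3D grid dimensions (voxels per axis).
#' @param x,object a \code{Volume3D}.
#' @export
setMethod("dim", "Volume3D", function(x) dim(x@values))

#' Accessors for Volume3D geometry and data
#'
#' @param x a \code{\linkS4class{Volume3D}} (or, where noted, a
#'   \code{\linkS4class{TubeVOI}}).
#' @return \code{voxelValues}: the value array; \code{voxelSpacing},
#'   \code{volumeOrigin}, \code{volumeDirection}: the geometry;
#'   \code{validMask}: a logical array (all-TRUE if no mask stored);
#'   \code{volumeMeta}: the metadata list.
#' @name volume-accessors
NULL

#' @rdname volume-accessors
#' @export
voxelValues <- function(x) x@values

#' @rdname volume-accessors
#' @export
voxelSpacing <- function(x) x@spacing

#' @rdname volume-accessors
#' @export
volumeOrigin <- function(x) x@origin

#' @rdname volume-accessors
#' @export
volumeDirection <- function(x) x@direction

#' @rdname volume-accessors
#' @export
volumeMeta <- function(x) x@meta

#' @rdname volume-accessors
#' @export
validMask <- function(x) {
  if (is.null(x@valid)) array(TRUE, dim(x@values)) else x@valid
}

setMethod("show", "Volume3D", function(object) {
  d <- dim(object@values)
  cat(sprintf("Volume3D: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 4), collapse = " x ")))
  cat(sprintf("  origin (mm): %s\n",
              paste(format(object@origin, digits = 4), collapse = ", ")))
  v <- object@values[validMask(object)]
  if (length(v))
    cat(sprintf("  signal range: [%.4g, %.4g], %d invalid voxels\n",
                min(v), max(v), sum(!validMask(object))))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
})

# 3x4 matrix mapping 0-based voxel index -> physical mm
.idx2phys <- function(x) {
  cbind(x@direction %*% diag(x@spacing, 3), x@origin)
}

# 3x4 matrix mapping physical mm -> 0-based continuous voxel index
.phys2idx <- function(x) {
  A <- x@direction %*% diag(x@spacing, 3)
  Ai <- solve(A)
  cbind(Ai, -Ai %*% x@origin)
}

#' Physical coordinates of voxel indices
#'
#' @param x a \code{\linkS4class{Volume3D}} or \code{\linkS4class{TubeVOI}}.
#' @param index n x 3 matrix (or length-3 vector) of 1-based voxel indices.
#' @return n x 3 matrix of physical coordinates in mm.
#' @export
voxelToPhysical <- function(x, index) {
  index <- matrix(index, ncol = 3)
  A <- .idx2phys(x)
  t(A %*% rbind(t(index - 1), 1))
}

#' Voxel (continuous, 1-based) indices of physical points
#'
#' @param x a \code{\linkS4class{Volume3D}} or \code{\linkS4class{TubeVOI}}.
#' @param points n x 3 matrix of physical coordinates, mm.
#' @return n x 3 matrix of continuous 1-based voxel indices.
#' @export
physicalToVoxel <- function(x, points) {
  points <- matrix(points, ncol = 3)
  A <- .phys2idx(x)
  t(A %*% rbind(t(points), 1)) + 1
}

# physical coordinates of all TRUE voxels of a logical array under the
# geometry of `geom` (any object with spacing/origin/direction slots)
.maskPhysical <- function(mask, geom) {
  idx <- which(mask, arr.ind = TRUE)
  A <- geom@direction %*% diag(geom@spacing, 3)
  sweep(t(A %*% t(idx - 1)), 2, geom@origin, "+")
}

# construct a TubeVOI from a logical mask + parent geometry
.makeTubeVOI <- function(mask, geom, role = "unknown") {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("tube mask is empty")
  bbox <- rbind(apply(idx, 2, min), apply(idx, 2, max))
  storage.mode(bbox) <- "integer"
  ctr <- colMeans(.maskPhysical(mask, geom))
  new("TubeVOI", mask = mask, role = role, bbox = bbox,
      centroid = as.numeric(ctr), voxelCount = as.integer(nrow(idx)),
      spacing = geom@spacing, origin = geom@origin,
      direction = geom@direction)
}

#' Accessors for TubeVOI
#'
#' @param x a \code{\linkS4class{TubeVOI}}.
#' @return \code{tubeMask}: the logical array; \code{tubeRole}: the role
#'   string; \code{tubeCentroid}: physical centroid (mm); \code{tubeBBox}:
#'   2x3 inclusive 1-based index ranges; \code{tubeVoxelCount}: the number
#'   of mask voxels.
#' @name tube-accessors
NULL

#' @rdname tube-accessors
#' @export
tubeMask <- function(x) x@mask

#' @rdname tube-accessors
#' @export
tubeRole <- function(x) x@role

#' @rdname tube-accessors
#' @export
tubeCentroid <- function(x) x@centroid

#' @rdname tube-accessors
#' @export
tubeBBox <- function(x) x@bbox

#' @rdname tube-accessors
#' @export
tubeVoxelCount <- function(x) x@voxelCount

setMethod("show", "TubeVOI", function(object) {
  cat(sprintf("TubeVOI (%s): %d voxels, centroid (%s) mm\n", object@role,
              object@voxelCount,
              paste(format(object@centroid, digits = 4), collapse = ", ")))
})

setMethod("show", "DistanceMap", function(object) {
  v <- object@values[object@mask@mask]
  cat(sprintf("DistanceMap on %d voxels, range [0, %.3f] mm\n",
              length(v), max(v)))
})
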