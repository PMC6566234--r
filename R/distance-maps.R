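#' Interior Euclidean distance map by fast marching
#'
#' Computes, for every mask voxel, the minimum Euclidean distance (mm) to
#' the object boundary by solving the unit-speed Eikonal equation with
#' first-order upwind fast marching on a min-heap front. The boundary set
#' is the mask voxels face-adjacent (6-connectivity) to background (the
#' grid border counts as background) and carries exactly 0; anisotropic
#' spacing is honored; heap ties break by lexicographic voxel index so runs
#' are deterministic.
#'
#' @param tube a \code{\linkS4class{TubeVOI}} (or logical mask array, in
#'   which case \code{spacing} must be given).
#' @param spacing voxel spacing in mm; defaults to the tube's.
#' @return A \code{\linkS4class{DistanceMap}}.
#' @export
interiorDistanceMap <- function(tube, spacing = NULL) {
  if (is.array(tube) && is.logical(tube)) {
    stopifnot(!is.null(spacing))
    geom <- new("Volume3D", values = array(0, dim(tube)),
                spacing = as.numeric(spacing), origin = c(0, 0, 0),
                direction = diag(3), valid = NULL, meta = list())
    tube <- .makeTubeVOI(tube, geom)
  }
  if (is.null(spacing)) spacing <- tube@spacing
  mask <- tube@mask
  d <- dim(mask)
  if (!any(mask)) stop("mask is empty")
  boundary <- array(.mask_boundary_cpp(as.logical(mask), as.integer(d)), d)
  vals <- .fmm_distance_cpp(as.logical(mask), as.logical(boundary),
                            as.integer(d), as.numeric(spacing))
  new("DistanceMap", values = array(vals, d), mask = tube)
}

#' Distance map as a dense image
#'
#' Embeds the interior distances in a dense array with 0 outside the mask
#' (the boundary itself is 0, so the extension is continuous); used as the
#' registration feature image.
#'
#' @param dm a \code{\linkS4class{DistanceMap}}.
#' @return A \code{\linkS4class{Volume3D}}.
#' @export
distanceMapVolume <- function(dm) {
  v <- dm@values
  v[is.na(v)] <- 0
  Volume3D(v, dm@mask@spacing, dm@mask@origin, dm@mask@direction,
           meta = list(description = "interior distance map (mm)"))
}

#' Export a distance map as NIfTI for inspection
#'
#' @param dm a \code{\linkS4class{DistanceMap}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeDistanceMap <- function(dm, path) {
  vol <- Volume3D(dm@values, dm@mask@spacing, dm@mask@origin,
                  dm@mask@direction)
  writeNiftiVolume(vol, path)
}
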