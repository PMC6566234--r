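#' Otsu threshold over a 256-bin histogram
#'
#' Global threshold maximizing the between-class variance of a 256-bin
#' histogram spanning the value range. Ties resolve to the lowest bin, and
#' the returned threshold is the upper edge of the chosen bin (foreground is
#' \code{values > threshold}).
#'
#' @param values numeric vector or array (NAs ignored).
#' @param nbins number of histogram bins.
#' @return The threshold value.
#' @export
otsuThreshold <- function(values, nbins = 256L) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("cannot threshold a constant volume")
  bin <- pmin(floor((v - lo) / (hi - lo) * nbins) + 1L, nbins)
  h <- tabulate(bin, nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  muT <- mu[nbins]
  sb <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb[-nbins]) # cut after bin k; which.max takes the first tie
  lo + k * (hi - lo) / nbins
}

#' Remove background by global thresholding
#'
#' Separates signal-bearing voxels from air/background with the Otsu
#' between-class-variance threshold; invalid voxels are never foreground.
#'
#' @param volume a \code{\linkS4class{Volume3D}} with at least two distinct
#'   intensities.
#' @return Logical foreground array with the threshold attached as
#'   attribute \code{"threshold"}.
#' @export
removeBackground <- function(volume) {
  keep <- validMask(volume)
  thr <- otsuThreshold(volume@values[keep])
  fg <- !is.na(volume@values) & volume@values > thr & keep
  attr(fg, "threshold") <- thr
  fg
}

#' 3D region growing
#'
#' Returns the 26-connected component containing the seed among voxels with
#' values in \code{[low, high]}.
#'
#' @param volume a \code{\linkS4class{Volume3D}}.
#' @param seed 1-based voxel index (length 3).
#' @param low,high inclusion band; the seed's value must lie inside it.
#' @return Logical mask array.
#' @export
growRegion3D <- function(volume, seed, low, high = Inf) {
  d <- dim(volume@values)
  seed <- as.integer(seed)
  if (length(seed) != 3L || any(seed < 1L) || any(seed > d))
    stop("seed must be a voxel index inside the grid")
  sv <- volume@values[seed[1], seed[2], seed[3]]
  if (is.na(sv) || sv < low || sv > high)
    stop(sprintf("seed value %g is outside the inclusion band [%g, %g]",
                 sv, low, high))
  vals <- volume@values
  if (!is.null(volume@valid)) vals[!volume@valid] <- NA_real_
  m <- .grow_region_cpp(as.numeric(vals), as.integer(d), seed - 1L,
                        low, high)
  array(m, d)
}

#' Detect tube VOIs in a scan
#'
#' Background removal followed by 26-connected component labelling; each
#' component with a voxel count in \code{[minVoxels, maxVoxels]} becomes a
#' \code{\linkS4class{TubeVOI}}. Tubes are sorted by centroid position
#' (x, then y, then z) and roles are assigned in that order from
#' \code{roles}, or from explicit \code{seeds} (one physical point per
#' role falling inside the tube).
#'
#' @param volume a \code{\linkS4class{Volume3D}}.
#' @param minVoxels,maxVoxels component size band.
#' @param roles character vector of roles assigned in sorted-centroid
#'   order (default all \code{"unknown"}).
#' @param seeds optional named list of physical points (mm), e.g.
#'   \code{list(water = c(20, 0, 0))}; overrides \code{roles} where given.
#' @return List of \code{\linkS4class{TubeVOI}} objects.
#' @export
detectTubes <- function(volume, minVoxels = 50L, maxVoxels = Inf,
                        roles = NULL, seeds = NULL) {
  fg <- removeBackground(volume)
  d <- dim(fg)
  lab <- array(.label_components_cpp(as.logical(fg), as.integer(d)), d)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minVoxels & sizes <= maxVoxels)
  if (length(keep) == 0L)
    stop(sprintf(paste0(
      "no connected components with size in [%d, %s] found ",
      "(threshold %.4g gave %d components); review threshold or size band"),
      as.integer(minVoxels), format(maxVoxels), attr(fg, "threshold"),
      length(sizes)))
  vois <- lapply(keep, function(li) .makeTubeVOI(lab == li, volume))
  ctr <- t(vapply(vois, tubeCentroid, numeric(3)))
  ord <- order(ctr[, 1], ctr[, 2], ctr[, 3])
  vois <- vois[ord]
  if (!is.null(roles)) {
    for (q in seq_along(vois))
      vois[[q]]@role <- if (q <= length(roles)) roles[q] else "unknown"
  }
  if (!is.null(seeds)) {
    for (rl in names(seeds)) {
      cidx <- round(physicalToVoxel(volume, seeds[[rl]]))
      for (q in seq_along(vois)) {
        m <- vois[[q]]@mask
        if (all(cidx >= 1) && all(cidx <= dim(m)) &&
            m[cidx[1], cidx[2], cidx[3]])
          vois[[q]]@role <- rl
      }
    }
  }
  vois
}

#' Extract a centered VOI subvolume around a tube
#'
#' Crops the tube's bounding box padded symmetrically by \code{pad} voxels
#' (clipped at the image border; clipping is recorded), updating the origin
#' so every voxel keeps its physical coordinate.
#'
#' @param volume a \code{\linkS4class{Volume3D}}.
#' @param tube a \code{\linkS4class{TubeVOI}} on the same grid.
#' @param pad padding in voxels per side.
#' @return A \code{\linkS4class{Volume3D}}; attributes \code{"cropRange"}
#'   (2x3 index matrix) and \code{"clipped"} record the crop.
#' @export
extractVOI <- function(volume, tube, pad = 4L) {
  d <- dim(volume@values)
  lo <- tube@bbox[1, ] - pad
  hi <- tube@bbox[2, ] + pad
  clipped <- any(lo < 1L) || any(hi > d)
  lo <- pmax(lo, 1L)
  hi <- pmin(hi, d)
  vals <- volume@values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  valid <- if (is.null(volume@valid)) NULL else
    volume@valid[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  origin <- as.numeric(voxelToPhysical(volume, lo))
  out <- Volume3D(vals, volume@spacing, origin, volume@direction,
                  meta = volume@meta, valid = valid)
  attr(out, "cropRange") <- rbind(lo, hi)
  attr(out, "clipped") <- clipped
  out
}

# crop a TubeVOI to the same range an extractVOI call used
.cropTubeVOI <- function(tube, cropRange) {
  lo <- cropRange[1, ]; hi <- cropRange[2, ]
  m <- tube@mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  geom <- new("Volume3D", values = array(0, dim(m)), spacing = tube@spacing,
              origin = as.numeric(voxelToPhysical(tube, lo)),
              direction = tube@direction, valid = NULL, meta = list())
  .makeTubeVOI(m, geom, tube@role)
}
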