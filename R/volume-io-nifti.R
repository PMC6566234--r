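#' Read a 3D NIfTI volume
#'
#' Values and geometry (spacing, origin, direction) are taken from the
#' NIfTI xform; \code{NaN} voxels become invalid. 4D or higher images are
#' rejected.
#'
#' @param path a .nii or .nii.gz file.
#' @return A \code{\linkS4class{Volume3D}}.
#' @export
readNiftiVolume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3D image, got %dD: %s", length(d), path))
  xf <- RNifti::xform(img)
  sp <- sqrt(colSums(xf[1:3, 1:3]^2))
  dir <- sweep(xf[1:3, 1:3], 2, sp, "/")
  values <- array(as.numeric(img), d)
  values[is.nan(values)] <- NA_real_
  Volume3D(values, sp, xf[1:3, 4], dir,
           meta = list(source = path))
}

#' Write a 3D volume as NIfTI
#'
#' Lossless round trip of values and geometry (invalid voxels are stored as
#' \code{NaN}).
#'
#' @param volume a \code{\linkS4class{Volume3D}}.
#' @param path output .nii or .nii.gz file.
#' @return \code{path}, invisibly.
#' @export
writeNiftiVolume <- function(volume, path) {
  values <- volume@values
  if (!is.null(volume@valid)) values[!volume@valid] <- NaN
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- volume@spacing
  xf <- rbind(cbind(volume@direction %*% diag(volume@spacing, 3),
                    volume@origin),
              c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a label mask as a NIfTI label map
#'
#' @param mask logical or integer 3D array.
#' @param geom a \code{\linkS4class{Volume3D}} or
#'   \code{\linkS4class{TubeVOI}} supplying the geometry.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeMaskNifti <- function(mask, geom, path) {
  vol <- Volume3D(array(as.numeric(mask), dim(mask)), geom@spacing,
                  geom@origin, geom@direction)
  writeNiftiVolume(vol, path)
}

#' Normalize a scan by its water-tube mean
#'
#' Every voxel is divided by the mean signal inside the water mask, making
#' the water region's mean exactly 1; the water mean is recorded in the
#' result's metadata. This is the scan-level normalization that makes
#' test/control scans acquired separately comparable.
#'
#' @param volume a \code{\linkS4class{Volume3D}}.
#' @param water a \code{\linkS4class{TubeVOI}} (or logical array) marking
#'   the water tube on the same grid.
#' @return The normalized \code{\linkS4class{Volume3D}} with
#'   \code{meta$waterMean} set.
#' @export
normalizeByWater <- function(volume, water) {
  mask <- if (is(water, "TubeVOI")) water@mask else water
  if (!identical(dim(mask), dim(volume@values)))
    stop("water mask grid does not match the volume grid")
  keep <- mask & validMask(volume)
  if (!any(keep)) stop("water mask is empty (no valid voxels)")
  wm <- mean(volume@values[keep])
  if (!is.finite(wm) || wm <= 0)
    stop(sprintf("water mean must be positive, got %g", wm))
  out <- volume
  out@values <- volume@values / wm
  out@meta$waterMean <- wm
  out
}
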