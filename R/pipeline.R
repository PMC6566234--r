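#' Pipeline configuration
#'
#' Tunable parameters of the end-to-end reflectivity pipeline.
#'
#' @param pad VOI padding in voxels around each tube bounding box.
#' @param minVoxels,maxVoxels component size band for tube detection.
#' @param sampleRule how the analysis tube and the water tube are told
#'   apart in each scan: \code{"leftmost-sample"} (analysis tube = smallest
#'   x centroid, water = largest) or \code{"seeds"} (use \code{seeds}).
#' @param seeds optional named list of physical seed points per scan role,
#'   e.g. \code{list(sample = c(-20, 0, 0), water = c(20, 0, 0))}.
#' @param registration run the two-stage registration (\code{TRUE}) or
#'   assume the scans are already voxel-matched (\code{FALSE}).
#' @param elasticMetric metric for the B-spline stage
#'   (\code{"meansq"} on distance maps, or \code{"mi"}).
#' @param elasticMaxit L-BFGS-B iteration cap per elastic stage.
#' @param bins MI histogram bins (affine stage).
#' @param erodeVoxels erosion depth (voxels) applied to the reference tube
#'   mask before the reflectivity sums — a partial-volume guard at the tube
#'   wall; 0 disables.
#' @param colorRange display range of the rendered color map, percent.
#' @return A named list of settings.
#' @export
pipelineConfig <- function(pad = 4L, minVoxels = 200L, maxVoxels = Inf,
                           sampleRule = c("leftmost-sample", "seeds"),
                           seeds = NULL, registration = TRUE,
                           elasticMetric = c("meansq", "mi"),
                           elasticMaxit = 30L, bins = 32L,
                           erodeVoxels = 1L, colorRange = c(-100, 100)) {
  list(pad = pad, minVoxels = minVoxels, maxVoxels = maxVoxels,
       sampleRule = match.arg(sampleRule), seeds = seeds,
       registration = registration,
       elasticMetric = match.arg(elasticMetric),
       elasticMaxit = elasticMaxit, bins = bins,
       erodeVoxels = erodeVoxels, colorRange = colorRange)
}

# identify (sample, water) tubes in one scan per the configured rule
.pickTubes <- function(scan, config) {
  vois <- detectTubes(scan, config$minVoxels, config$maxVoxels,
                      seeds = config$seeds)
  if (config$sampleRule == "seeds") {
    roles <- vapply(vois, tubeRole, "")
    si <- which(roles == "sample")
    wi <- which(roles == "water")
    if (length(si) != 1L || length(wi) != 1L)
      stop("seed points did not identify exactly one sample and one water tube")
  } else {
    if (length(vois) < 2L)
      stop(sprintf("expected at least 2 tubes per scan, found %d",
                   length(vois)))
    xs <- vapply(vois, function(v) tubeCentroid(v)[1], 0)
    si <- which.min(xs)
    wi <- which.max(xs)
  }
  list(sample = vois[[si]], water = vois[[wi]])
}

.erodeTimes <- function(mask, times) {
  d <- dim(mask)
  for (q in seq_len(times))
    mask <- array(.erode_mask_cpp(as.logical(mask), as.integer(d)), d)
  mask
}

#' End-to-end voxel-wise reflectivity pipeline
#'
#' Runs the full analysis on a test scan and a control scan, each holding
#' one analysis tube and one water tube: tube detection (background removal
#' + connected components), water normalization of each scan, VOI
#' extraction, interior distance maps, affine registration of the test tube
#' to the control tube by mutual information of the distance maps, B-spline
#' elastic refinement, resampling of the test VOI onto the control grid,
#' and the voxel-wise reflectivity with its color map. The control scan is
#' the reference: results live on the control VOI grid.
#'
#' @param testScan,controlScan \code{\linkS4class{Volume3D}} scans.
#' @param config settings from \code{\link{pipelineConfig}}.
#' @return A list with \code{result} (the
#'   \code{\linkS4class{ReflectivityResult}}), \code{colorMap},
#'   \code{registration} (a \code{\linkS4class{RegistrationResult}} or
#'   NULL), \code{tubes} (the detected VOIs) and \code{report} (a
#'   JSON-serializable provenance list with stage names, water means,
#'   masks and metric summaries).
#' @export
runPipeline <- function(testScan, controlScan, config = pipelineConfig()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  tubesT <- stage("detect-tubes/test", .pickTubes(testScan, config))
  tubesC <- stage("detect-tubes/control", .pickTubes(controlScan, config))

  testN <- stage("water-normalize/test",
                 normalizeByWater(testScan, tubesT$water))
  controlN <- stage("water-normalize/control",
                    normalizeByWater(controlScan, tubesC$water))

  voiT <- stage("extract-voi/test",
                extractVOI(testN, tubesT$sample, config$pad))
  voiC <- stage("extract-voi/control",
                extractVOI(controlN, tubesC$sample, config$pad))
  maskT <- .cropTubeVOI(tubesT$sample, attr(voiT, "cropRange"))
  maskC <- .cropTubeVOI(tubesC$sample, attr(voiC, "cropRange"))

  reg <- NULL
  if (isTRUE(config$registration)) {
    dmT <- stage("distance-map/test", interiorDistanceMap(maskT))
    dmC <- stage("distance-map/control", interiorDistanceMap(maskC))
    affine <- stage("register-affine",
                    registerAffine(dmC, dmT, bins = config$bins))
    reg <- stage("register-bspline",
                 registerBSpline(dmC, dmT, initial = affine@affine,
                                 metric = config$elasticMetric,
                                 maxit = config$elasticMaxit))
    reg@metricTrace <- c(affine@metricTrace, reg@metricTrace)
    testAligned <- stage("resample",
                         resampleVolume(voiT, voiC, affine = reg))
  } else {
    testAligned <- stage("resample", resampleVolume(voiT, voiC))
  }

  anaMask <- maskC@mask
  if (config$erodeVoxels > 0L)
    anaMask <- .erodeTimes(anaMask, config$erodeVoxels)
  if (!any(anaMask)) stop("[reflectivity] analysis mask is empty after erosion")

  result <- stage("reflectivity", reflectivityVoxelwise(
    testAligned, voiC, mask = anaMask,
    provenance = list(
      waterMeanTest = testN@meta$waterMean,
      waterMeanControl = controlN@meta$waterMean,
      erodeVoxels = config$erodeVoxels,
      registered = isTRUE(config$registration))))
  cmap <- stage("color-map", renderColorMap(result, config$colorRange))

  report <- list(
    stages = c("detect-tubes", "water-normalize", "extract-voi",
               if (isTRUE(config$registration))
                 c("distance-map", "register-affine", "register-bspline"),
               "resample", "reflectivity", "color-map"),
    waterMeans = list(test = testN@meta$waterMean,
                      control = controlN@meta$waterMean),
    tubeVoxels = list(test = tubeVoxelCount(tubesT$sample),
                      control = tubeVoxelCount(tubesC$sample)),
    analysisVoxels = result@nVoxels,
    globalReflectivityPercent = result@globalPercent,
    registration = if (!is.null(reg)) list(
      finalMetric = reg@finalMetric,
      affineMatrix = as.vector(reg@affine@matrix),
      affineTranslationMm = reg@affine@translation,
      maxWarpDisplacementMm = if (!is.null(reg@warp))
        max(abs(reg@warp@coefficients)) else 0),
    config = config[setdiff(names(config), "seeds")])

  list(result = result, colorMap = cmap, registration = reg,
       tubes = list(test = tubesT, control = tubesC), report = report)
}

#' Write a pipeline report bundle
#'
#' Writes the JSON provenance report, the voxel reflectivity map as NIfTI
#' and (when the png package is available) the mid-slice color map as PNG.
#'
#' @param pipeline result list from \code{\link{runPipeline}}.
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
writePipelineReport <- function(pipeline, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(pipeline$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res <- pipeline$result
  vol <- Volume3D(res@voxelMap, spacing = c(1, 1, 1))
  writeNiftiVolume(vol, file.path(dir, "reflectivity_map.nii.gz"))
  if (requireNamespace("png", quietly = TRUE))
    writeColorMapPNG(pipeline$colorMap, file.path(dir, "color_map.png"))
  invisible(dir)
}
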