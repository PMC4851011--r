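## The three-step identification workflow: select a vascular pattern in
## the preoperative volume, locate it in the pre-resection ultrasound
## volume, then use the located region as the new pattern for the
## post-resection volume.

#' Run the full vascular-segment identification workflow
#'
#' Step 1 is the user-supplied \code{roi} around a vessel in the
#' preoperative volume. Step 2 locates the segmented pattern in
#' \code{iceusStart}. Step 3 (when \code{iceusEnd} is supplied) takes the
#' region located in \code{iceusStart} as the new pattern — the detected
#' blood vessel itself, not the warped preoperative pattern, so the
#' second registration is same-modality — and locates it in
#' \code{iceusEnd}. If the first step fails, the second is not attempted
#' and the error is tagged with the failing step.
#'
#' @param ct1mr preoperative [Volume3D-class]
#' @param roi [RoiBox-class] enclosing the selected vessel in
#'   \code{ct1mr}
#' @param iceusStart pre-resection [Volume3D-class]
#' @param iceusEnd post-resection [Volume3D-class], or NULL
#' @param measure a [SimilarityMeasure-class]
#' @param params a [VesselnessParams-class]
#' @param keepLargest retain only the largest mask component per region
#' @return a named list of [IdentificationResult-class] objects
#'   (\code{$start}, and \code{$end} when \code{iceusEnd} is given)
#' @export
runIdentification <- function(ct1mr, roi, iceusStart, iceusEnd = NULL,
                              measure = similarityMeasure("NGF"),
                              params = VesselnessParams(),
                              keepLargest = TRUE) {
  resStart <- identifyPattern(ct1mr, roi, iceusStart, measure, params,
                              keepLargest = keepLargest, step = "start")
  out <- list(start = resStart)
  if (!is.null(iceusEnd)) {
    out$end <- identifyPattern(iceusStart, resStart@locatedBox, iceusEnd,
                               measure, params, keepLargest = keepLargest,
                               step = "end")
  }
  out
}

resultReferenceGrid <- function(result) {
  Volume3D(array(0, result@targetDim), spacing = result@targetSpacing,
           origin = result@targetOrigin)
}

#' Overlay a volume onto an identification target
#'
#' Applies the recovered rigid transform to the source volume (e.g. the
#' preoperative cT1MR) and resamples it onto the target volume's grid for
#' fused visualization — the transform-application step of brain-shift
#' correction.
#'
#' @param ct1mr the [Volume3D-class] to warp (any volume in the pattern's
#'   world space)
#' @param result an [IdentificationResult-class]
#' @param background fill value outside the source domain
#' @return a [Volume3D-class] on the target grid
#' @export
overlayTransform <- function(ct1mr, result, background = 0) {
  resampleRigid(ct1mr, result@transform, resultReferenceGrid(result),
                background = background)
}

#' Validation metrics for an identification result
#'
#' Resamples the segmented pattern mask through the recovered transform
#' onto the search-region grid (trilinear, binarized at 0.5) and scores
#' it against the segmented target mask with Dice and Hausdorff metrics.
#' The metrics are stored in the result's \code{metrics} list under the
#' measure name.
#'
#' @param result an [IdentificationResult-class]
#' @return the result with an added [ValidationReport-class] in
#'   \code{metrics}
#' @export
evaluateIdentification <- function(result) {
  warped <- resampleRigid(result@patternMask, result@transform,
                          result@targetMask, background = 0)
  warpedMask <- BinaryMask3D(warped@data > 0.5,
                             spacing = warped@spacing,
                             origin = warped@origin)
  rep <- validationReport(dice(warpedMask, result@targetMask),
                          hausdorffDistance(warpedMask, result@targetMask))
  result@metrics[[result@measure]] <- rep
  result
}

## ---- lossless JSON serialization of identification results ----------

maskToList <- function(m) {
  list(dim = dim(m@data), spacing = m@spacing, origin = m@origin,
       foreground = which(m@data != 0))
}

maskFromList <- function(x) {
  a <- array(0, unlist(x$dim))
  a[unlist(x$foreground)] <- 1
  BinaryMask3D(a, spacing = unlist(x$spacing), origin = unlist(x$origin))
}

transformToList <- function(t) {
  list(rotation_deg = t@rotation, translation_mm = t@translation,
       center_mm = t@center)
}

roiToList <- function(r) list(start = r@start, size = r@size)

#' Serialize / restore an identification result as JSON
#'
#' The full result (step, boxes, transform, score, both masks, target
#' grid geometry, metrics) round-trips losslessly.
#'
#' @param result an [IdentificationResult-class]
#' @param path JSON file path
#' @return \code{writeIdentificationResult} returns \code{path}
#'   invisibly; \code{readIdentificationResult} returns the restored
#'   [IdentificationResult-class]
#' @export
writeIdentificationResult <- function(result, path) {
  metrics <- lapply(result@metrics, function(m)
    list(dsi = m@dsi, hausdorff_mm = m@hausdorffMm,
         dsi_normalized = m@dsiNormalized,
         hausdorff_normalized = m@hausdorffNormalized,
         processing_time_s = m@processingTimeS))
  x <- list(step = result@step, measure = result@measure,
            score = result@score,
            located_box = roiToList(result@locatedBox),
            transform = transformToList(result@transform),
            pattern_roi = roiToList(result@patternRoi),
            search_region = list(box = roiToList(result@searchRegion@box),
                                 provenance =
                                   roiToList(result@searchRegion@provenance),
                                 clipped = result@searchRegion@clipped),
            pattern_mask = maskToList(result@patternMask),
            target_mask = maskToList(result@targetMask),
            target_dim = result@targetDim,
            target_spacing = result@targetSpacing,
            target_origin = result@targetOrigin,
            metrics = metrics)
  jsonlite::write_json(x, path, digits = I(17), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeIdentificationResult
#' @export
readIdentificationResult <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  roiFrom <- function(r) RoiBox(unlist(r$start), unlist(r$size))
  metrics <- lapply(x$metrics, function(m)
    new("ValidationReport", dsi = unlist(m$dsi),
        hausdorffMm = unlist(m$hausdorff_mm),
        dsiNormalized = as.numeric(unlist(m$dsi_normalized)),
        hausdorffNormalized = as.numeric(unlist(m$hausdorff_normalized)),
        processingTimeS = as.numeric(unlist(m$processing_time_s))))
  new("IdentificationResult", step = x$step, measure = x$measure,
      score = unlist(x$score),
      locatedBox = roiFrom(x$located_box),
      transform = RigidTransform3D(unlist(x$transform$rotation_deg),
                                   unlist(x$transform$translation_mm),
                                   unlist(x$transform$center_mm)),
      patternRoi = roiFrom(x$pattern_roi),
      searchRegion = new("SearchRegion", box = roiFrom(x$search_region$box),
                         provenance = roiFrom(x$search_region$provenance),
                         clipped = unlist(x$search_region$clipped)),
      patternMask = maskFromList(x$pattern_mask),
      targetMask = maskFromList(x$target_mask),
      targetDim = as.integer(unlist(x$target_dim)),
      targetSpacing = as.numeric(unlist(x$target_spacing)),
      targetOrigin = as.numeric(unlist(x$target_origin)),
      metrics = metrics)
}
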