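#' Construct a Volume3D
#'
#' @param data 3D numeric array
#' @param spacing voxel size in mm (length 3, recycled from length 1)
#' @param origin world position of voxel (0,0,0) in mm
#' @return a [Volume3D-class]
#' @examples
#' v <- Volume3D(array(rnorm(27), c(3, 3, 3)), spacing = c(1, 1, 1))
#' volDim(v)
#' @export
Volume3D <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("Volume3D", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a BinaryMask3D
#'
#' @param data 3D array coercible to 0/1 (logical or numeric)
#' @param spacing,origin grid geometry, as for [Volume3D()]
#' @return a [BinaryMask3D-class]
#' @export
BinaryMask3D <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  d <- array(as.numeric(data != 0), dim = dim(data))
  new("BinaryMask3D", data = d, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a RoiBox (0-based, half-open)
#'
#' @param start 0-based inclusive start indices (length 3)
#' @param size extents in voxels (length 3, all >= 1)
#' @return a [RoiBox-class]
#' @examples
#' RoiBox(c(10, 5, 0), c(50, 29, 8))
#' @export
RoiBox <- function(start, size) {
  new("RoiBox", start = as.integer(round(start)),
      size = as.integer(round(size)))
}

#' Construct a RigidTransform3D
#'
#' @param rotation Euler angles (x, y, z) in degrees; the rotation matrix
#'   is \code{Rz \%*\% Ry \%*\% Rx}
#' @param translation mm
#' @param center rotation center in world mm
#' @return a [RigidTransform3D-class]
#' @examples
#' t <- RigidTransform3D(rotation = c(0, 0, 10), translation = c(1, 2, 3))
#' rigidMatrix(t)
#' @export
RigidTransform3D <- function(rotation = c(0, 0, 0),
                             translation = c(0, 0, 0),
                             center = c(0, 0, 0)) {
  new("RigidTransform3D", rotation = as.numeric(rotation),
      translation = as.numeric(translation), center = as.numeric(center))
}

#' Construct vesselness filter parameters
#'
#' Defaults target vessels of diameter below 2 mm sampled at 1 mm
#' isotropic voxels: scales 0.5-2 mm, alpha1 = 0.5, alpha2 = 2.
#'
#' @param sigmas strictly increasing Gaussian scales in mm
#' @param alpha1,alpha2 dimensionless constants, 0 < alpha1 < alpha2
#' @return a [VesselnessParams-class]
#' @export
VesselnessParams <- function(sigmas = c(0.5, 1, 1.5, 2), alpha1 = 0.5,
                             alpha2 = 2) {
  new("VesselnessParams", sigmas = as.numeric(sigmas),
      alpha1 = as.numeric(alpha1), alpha2 = as.numeric(alpha2))
}

#' Construct a similarity-measure configuration
#'
#' @param name "NCC", "NMI" or "NGF" (case-insensitive)
#' @param bins NMI joint-histogram bins (default 32)
#' @param epsilon NGF gradient regularization (intensity/mm); NULL means
#'   1\% of the fixed image's intensity range at evaluation time
#' @param inputMode "vesselness" (default; measures see the vesselness
#'   image restricted to segmented support) or "binary" (0/1 masks)
#' @return a [SimilarityMeasure-class]
#' @examples
#' similarityMeasure("ngf")
#' similarityMeasure("NMI", bins = 64)
#' @export
similarityMeasure <- function(name, bins = 32, epsilon = NULL,
                              inputMode = c("vesselness", "binary")) {
  inputMode <- match.arg(inputMode)
  opts <- list(bins = as.integer(bins), inputMode = inputMode)
  if (!is.null(epsilon)) opts$epsilon <- as.numeric(epsilon)
  new("SimilarityMeasure", name = toupper(name), options = opts)
}

## ---- accessors -------------------------------------------------------

#' Accessors for volume and box geometry
#'
#' \code{volData} returns the raw array; \code{voxelSpacing} the per-axis
#' voxel size in mm; \code{worldOrigin} the world position of voxel
#' (0,0,0); \code{volDim} the grid dimensions; \code{roiStart} and
#' \code{roiSize} the 0-based start and extent of a box.
#'
#' @param x a [Volume3D-class] or [RoiBox-class]
#' @return numeric array or vector as appropriate
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @rdname accessors
#' @export
setMethod("volData", "Volume3D", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "Volume3D", function(x) x@spacing)

#' @rdname accessors
#' @export
setGeneric("worldOrigin", function(x) standardGeneric("worldOrigin"))
#' @rdname accessors
#' @export
setMethod("worldOrigin", "Volume3D", function(x) x@origin)

#' @rdname accessors
#' @export
setGeneric("volDim", function(x) standardGeneric("volDim"))
#' @rdname accessors
#' @export
setMethod("volDim", "Volume3D", function(x) dim(x@data))

#' @rdname accessors
#' @export
setGeneric("roiStart", function(x) standardGeneric("roiStart"))
#' @rdname accessors
#' @export
setMethod("roiStart", "RoiBox", function(x) x@start)

#' @rdname accessors
#' @export
setGeneric("roiSize", function(x) standardGeneric("roiSize"))
#' @rdname accessors
#' @export
setMethod("roiSize", "RoiBox", function(x) x@size)

## ---- show methods ----------------------------------------------------

setMethod("show", "Volume3D", function(object) {
  d <- dim(object@data)
  cat(class(object), sprintf("%d x %d x %d", d[1], d[2], d[3]),
      "| spacing (mm):", paste(signif(object@spacing, 4), collapse = " x "),
      "| origin (mm):", paste(signif(object@origin, 4), collapse = ", "),
      "\n")
  r <- range(object@data)
  cat("  intensity range:", signif(r[1], 6), "..", signif(r[2], 6), "\n")
})

setMethod("show", "BinaryMask3D", function(object) {
  d <- dim(object@data)
  cat(class(object), sprintf("%d x %d x %d", d[1], d[2], d[3]),
      "| spacing (mm):", paste(signif(object@spacing, 4), collapse = " x "),
      "\n  foreground voxels:", sum(object@data), "\n")
})

setMethod("show", "RoiBox", function(object) {
  cat("RoiBox start (0-based):", paste(object@start, collapse = ", "),
      "| size:", paste(object@size, collapse = " x "), "\n")
})

setMethod("show", "RigidTransform3D", function(object) {
  cat("RigidTransform3D\n",
      " rotation (deg): ", paste(signif(object@rotation, 5), collapse = ", "),
      "\n  translation (mm):",
      paste(signif(object@translation, 5), collapse = ", "),
      "\n  center (mm):     ",
      paste(signif(object@center, 5), collapse = ", "), "\n")
})

setMethod("show", "SimilarityMeasure", function(object) {
  cat("SimilarityMeasure:", object@name, "\n")
  if (length(object@options))
    cat("  options:", paste(names(object@options),
        vapply(object@options, function(x) paste(x, collapse = ","), ""),
        sep = "=", collapse = "; "), "\n")
})

setMethod("show", "RegistrationResult", function(object) {
  cat("RegistrationResult | score:", signif(object@score, 6),
      "| converged:", object@converged, "\n")
  show(object@transform)
  show(object@locatedBox)
})

setMethod("show", "IdentificationResult", function(object) {
  cat("IdentificationResult (step:", object@step, "| measure:",
      object@measure, ")\n  score:", signif(object@score, 6), "\n")
  show(object@locatedBox)
})

setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport | DSI:", signif(object@dsi, 4),
      "| Hausdorff (mm):", signif(object@hausdorffMm, 4), "\n")
  if (length(object@dsiNormalized))
    cat("  normalized vs reference: DSI", signif(object@dsiNormalized, 4),
        "| Hausdorff", signif(object@hausdorffNormalized, 4), "\n")
})

setMethod("show", "PhantomSet", function(object) {
  cat("PhantomSet (seed", object@seed, ")\n")
  cat("  ct1mr-like:      "); show(object@ct1mr)
  cat("  iceus-start-like:"); show(object@iceusStart)
  cat("  iceus-end-like:  "); show(object@iceusEnd)
  cat("  pattern ROI:     "); show(object@roi)
})
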