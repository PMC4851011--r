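#' @import methods
NULL

#' 3D scalar volume with voxel geometry
#'
#' A \code{Volume3D} holds a 3D scalar grid together with its voxel spacing
#' (mm per voxel, per axis) and the world position (mm) of voxel
#' \code{(0,0,0)}. The world coordinate of integer index \code{i} (0-based)
#' is \code{origin + i * spacing}, axis-wise. Axis order is (x, y, z)
#' throughout; file readers normalize header conventions to this order.
#'
#' @slot data three-dimensional numeric array
#' @slot spacing numeric(3), voxel size in mm, all > 0
#' @slot origin numeric(3), world position of voxel (0,0,0) in mm
#'
#' @seealso [Volume3D()], [readVolume()], [cropVolume()]
#' @export
setClass("Volume3D",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(data = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0)))

setValidity("Volume3D", function(object) {
  msg <- NULL
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  else if (any(dim(object@data) < 1L))
    msg <- c(msg, "each axis must have length >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite numbers")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite numbers")
  if (is.null(msg)) TRUE else msg
})

#' Binary 3D mask
#'
#' A \code{BinaryMask3D} is a [Volume3D-class] whose data are 0/1
#' (stored numeric for arithmetic convenience), sharing the grid geometry
#' of the volume it was derived from. An empty mask is allowed but most
#' operations that require foreground will signal an error on one.
#'
#' @seealso [BinaryMask3D()], [segmentVessels()], [dice()]
#' @export
setClass("BinaryMask3D", contains = "Volume3D")

setValidity("BinaryMask3D", function(object) {
  v <- unique(as.vector(object@data))
  if (!all(v %in% c(0, 1))) "mask data must contain only 0 and 1" else TRUE
})

#' Axis-aligned index-space box
#'
#' \code{RoiBox} selects a sub-volume by 0-based, half-open index ranges
#' \code{[start, start + size)} per axis. This is the region a user draws
#' around a vascular segment (the pattern region) or the derived search
#' region in a target volume.
#'
#' @slot start integer(3), 0-based inclusive start index
#' @slot size integer(3), extent in voxels, all >= 1
#'
#' @seealso [RoiBox()], [cropVolume()], [buildSearchRegion()]
#' @export
setClass("RoiBox", representation(start = "integer", size = "integer"),
         prototype(start = c(0L, 0L, 0L), size = c(1L, 1L, 1L)))

setValidity("RoiBox", function(object) {
  msg <- NULL
  if (length(object@start) != 3L || anyNA(object@start))
    msg <- c(msg, "start must be 3 integers")
  if (length(object@size) != 3L || anyNA(object@size) ||
      any(object@size < 1L))
    msg <- c(msg, "size must be 3 integers >= 1")
  if (is.null(msg)) TRUE else msg
})

#' Rigid 3D transform (6 degrees of freedom)
#'
#' Parameterized by three Euler angles (degrees, applied as
#' \code{Rz \%*\% Ry \%*\% Rx}), a translation (mm) and a rotation center
#' (world mm). The induced map is \code{T(p) = R (p - c) + c + t}. By
#' convention a transform maps points from the moving volume's world space
#' into the fixed/reference world space.
#'
#' @slot rotation numeric(3), Euler angles (x, y, z) in degrees
#' @slot translation numeric(3), mm
#' @slot center numeric(3), rotation center in world mm
#'
#' @seealso [RigidTransform3D()], [rigidMatrix()], [invertTransform()],
#'   [resampleRigid()]
#' @export
setClass("RigidTransform3D",
  representation(rotation = "numeric", translation = "numeric",
                 center = "numeric"),
  prototype(rotation = c(0, 0, 0), translation = c(0, 0, 0),
            center = c(0, 0, 0)))

setValidity("RigidTransform3D", function(object) {
  ok <- function(x) length(x) == 3L && all(is.finite(x))
  msg <- NULL
  if (!ok(object@rotation)) msg <- c(msg, "rotation must be 3 finite numbers")
  if (!ok(object@translation))
    msg <- c(msg, "translation must be 3 finite numbers")
  if (!ok(object@center)) msg <- c(msg, "center must be 3 finite numbers")
  if (is.null(msg)) TRUE else msg
})

#' Parameters of the multiscale vesselness filter
#'
#' Scales are Gaussian standard deviations in mm; the filter response is
#' the maximum over scales. \code{alpha1 < alpha2} control the asymmetric
#' penalty on the largest Hessian eigenvalue for the bright-tube model:
#' the response is damped faster where the intensity profile curves along
#' the would-be vessel axis (lambda1 <= 0 branch) than where it bulges
#' (lambda1 > 0 branch).
#'
#' @slot sigmas strictly increasing positive scales in mm
#' @slot alpha1 dimensionless, default 0.5
#' @slot alpha2 dimensionless, default 2
#'
#' @seealso [VesselnessParams()], [multiscaleVesselness()]
#' @export
setClass("VesselnessParams",
  representation(sigmas = "numeric", alpha1 = "numeric", alpha2 = "numeric"),
  prototype(sigmas = c(0.5, 1, 1.5, 2), alpha1 = 0.5, alpha2 = 2))

setValidity("VesselnessParams", function(object) {
  msg <- NULL
  s <- object@sigmas
  if (length(s) < 1L || any(!is.finite(s)) || any(s <= 0) ||
      is.unsorted(s, strictly = TRUE))
    msg <- c(msg, "sigmas must be non-empty, positive, strictly increasing")
  if (length(object@alpha1) != 1L || length(object@alpha2) != 1L ||
      !is.finite(object@alpha1) || !is.finite(object@alpha2) ||
      object@alpha1 <= 0 || object@alpha1 >= object@alpha2)
    msg <- c(msg, "need 0 < alpha1 < alpha2")
  if (is.null(msg)) TRUE else msg
})

#' Per-voxel Hessian eigenvalues
#'
#' Eigenvalues of the scale-space Hessian, sorted \code{lambda1 >=
#' lambda2 >= lambda3} at every voxel, plus the tubularity quantity
#' \code{lambdaC = min(-lambda2, -lambda3)} (positive inside bright
#' tubes, zero in flat regions).
#'
#' @slot lambda1,lambda2,lambda3 3D arrays, sorted descending voxel-wise
#' @slot lambdaC 3D array, \code{pmin(-lambda2, -lambda3)}
#' @export
setClass("HessianEigenvalues",
  representation(lambda1 = "array", lambda2 = "array", lambda3 = "array",
                 lambdaC = "array"))

#' Similarity measure configuration
#'
#' One of \code{"NCC"}, \code{"NMI"}, \code{"NGF"} plus measure-specific
#' options: \code{bins} (NMI joint-histogram bins, default 32),
#' \code{epsilon} (NGF gradient regularization in intensity/mm;
#' \code{NULL} means 1\% of the fixed image's intensity range),
#' \code{inputMode} (\code{"vesselness"}: measures see the vesselness
#' image restricted to the segmented support; \code{"binary"}: measures
#' see the 0/1 masks).
#'
#' @slot name character, one of NCC, NMI, NGF
#' @slot options named list of measure options
#' @seealso [similarityMeasure()], [registerRigid()]
#' @export
setClass("SimilarityMeasure",
  representation(name = "character", options = "list"),
  prototype(name = "NGF", options = list()))

setValidity("SimilarityMeasure", function(object) {
  msg <- NULL
  if (!(object@name %in% c("NCC", "NMI", "NGF")))
    msg <- c(msg, "name must be one of NCC, NMI, NGF")
  b <- object@options$bins
  if (!is.null(b) && (length(b) != 1L || b < 2))
    msg <- c(msg, "NMI bins must be >= 2")
  e <- object@options$epsilon
  if (!is.null(e) && (length(e) != 1L || !is.finite(e) || e <= 0))
    msg <- c(msg, "NGF epsilon must be > 0")
  m <- object@options$inputMode
  if (!is.null(m) && !(m %in% c("vesselness", "binary")))
    msg <- c(msg, "inputMode must be 'vesselness' or 'binary'")
  if (is.null(msg)) TRUE else msg
})

#' Search region derived from a pattern ROI
#'
#' The region of a target volume searched for the pattern: twice the
#' volume of the source ROI (each dimension scaled by 2^(1/3) and rounded),
#' centered on the same index position, clipped to the target bounds.
#'
#' @slot box [RoiBox-class] in the target volume
#' @slot provenance the source [RoiBox-class] it was derived from
#' @slot clipped logical, TRUE if clipping at the border reduced the volume
#' @export
setClass("SearchRegion",
  representation(box = "RoiBox", provenance = "RoiBox", clipped = "logical"),
  prototype(clipped = FALSE))

#' Result of a rigid registration
#'
#' @slot transform [RigidTransform3D-class] mapping pattern world
#'   coordinates into the search volume's world space
#' @slot score similarity value at \code{transform} (NCC/NMI: higher is
#'   better; NGF: the dc distance, lower is better)
#' @slot locatedBox [RoiBox-class] of the located pattern in the search
#'   volume's index space
#' @slot converged logical flag from the refinement stage
#' @slot trace numeric, best score after each stage (scan, refinement)
#' @slot scan data.frame of scanned integer offsets and their scores
#' @export
setClass("RegistrationResult",
  representation(transform = "RigidTransform3D", score = "numeric",
                 locatedBox = "RoiBox", converged = "logical",
                 trace = "numeric", scan = "data.frame"))

#' Vessel segmentation bundle
#'
#' Output of [segmentVessels()]: the binary mask together with the
#' vesselness image it was thresholded from and the Otsu threshold, kept
#' for inspection.
#'
#' @slot mask [BinaryMask3D-class]
#' @slot vesselness [Volume3D-class] multiscale vesselness response
#' @slot threshold numeric Otsu threshold applied as strict ">"
#' @export
setClass("VesselSegmentation",
  representation(mask = "BinaryMask3D", vesselness = "Volume3D",
                 threshold = "numeric"))

#' Result of one identification step
#'
#' One step of the identification workflow: the pattern (from cT1MR for
#' step "start", from the located region of iCEUS-start for step "end")
#' located inside a target volume.
#'
#' @slot step "start" or "end"
#' @slot locatedBox [RoiBox-class] of the pattern in the target volume
#' @slot transform [RigidTransform3D-class] pattern-world to target-world
#' @slot score similarity value at the optimum
#' @slot measure name of the similarity measure used
#' @slot patternMask,targetMask [BinaryMask3D-class] segmented pattern
#'   region and segmented search region (target-side)
#' @slot patternRoi [RoiBox-class] of the pattern in its source volume
#' @slot searchRegion [SearchRegion-class] used in the target
#' @slot targetDim,targetSpacing,targetOrigin grid geometry of the target
#'   volume (for overlay resampling)
#' @slot metrics list of per-measure validation metrics (filled by the
#'   metrics functions; may be empty)
#' @export
setClass("IdentificationResult",
  representation(step = "character", locatedBox = "RoiBox",
                 transform = "RigidTransform3D", score = "numeric",
                 measure = "character",
                 patternMask = "BinaryMask3D", targetMask = "BinaryMask3D",
                 patternRoi = "RoiBox", searchRegion = "SearchRegion",
                 targetDim = "integer", targetSpacing = "numeric",
                 targetOrigin = "numeric", metrics = "list"),
  prototype(metrics = list()))

#' Validation metrics report
#'
#' Dice similarity index, Hausdorff distance (mm), optional ratios
#' against a reference (e.g. expert) result, and processing time.
#'
#' @slot dsi Dice similarity index in [0, 1]
#' @slot hausdorffMm Hausdorff distance in mm, >= 0
#' @slot dsiNormalized,hausdorffNormalized ratios vs a reference report;
#'   length 0 until [normalizeVsReference()] fills them
#' @slot processingTimeS seconds, length 0 if not measured
#' @export
setClass("ValidationReport",
  representation(dsi = "numeric", hausdorffMm = "numeric",
                 dsiNormalized = "numeric", hausdorffNormalized = "numeric",
                 processingTimeS = "numeric"),
  prototype(dsiNormalized = numeric(0), hausdorffNormalized = numeric(0),
            processingTimeS = numeric(0)))

setValidity("ValidationReport", function(object) {
  msg <- NULL
  if (length(object@dsi) == 1L && (object@dsi < 0 || object@dsi > 1))
    msg <- c(msg, "dsi must lie in [0, 1]")
  if (length(object@hausdorffMm) == 1L && object@hausdorffMm < 0)
    msg <- c(msg, "hausdorffMm must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Synthetic tube specification
#'
#' A bright tubular structure defined by a densely sampled centerline
#' curve (world mm), a radius, a peak intensity and a Gaussian
#' cross-section width factor. With the default \code{profile =
#' 1/sqrt(2 log 2)} the half-maximum isosurface of the intensity profile
#' sits exactly at \code{radius}, so the rasterized truth mask matches
#' the nominal tube geometry.
#'
#' @slot centerline n x 3 matrix of points along the curve, world mm
#' @slot radius tube radius in mm, > 0
#' @slot peak peak intensity added on the centerline
#' @slot profile Gaussian cross-section width factor (sigma =
#'   profile * radius)
#' @seealso [straightTube()], [arcTube()], [helixTube()],
#'   [makeTubeVolume()]
#' @export
setClass("TubeSpec",
  representation(centerline = "matrix", radius = "numeric",
                 peak = "numeric", profile = "numeric"),
  prototype(radius = 0.8, peak = 100, profile = 1 / sqrt(2 * log(2))))

setValidity("TubeSpec", function(object) {
  msg <- NULL
  if (ncol(object@centerline) != 3L || nrow(object@centerline) < 2L)
    msg <- c(msg, "centerline must be an n x 3 matrix with n >= 2")
  if (object@radius <= 0) msg <- c(msg, "radius must be > 0")
  if (object@profile <= 0) msg <- c(msg, "profile must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' Phantom dataset with ground truth
#'
#' Three synthetic volumes sharing tube geometry — a cT1MR-like volume
#' (high SNR, bright tubes, bright tumor blob), an iCEUS-start-like
#' volume (rigidly displaced, speckle, tumor present) and an
#' iCEUS-end-like volume (further displaced, speckle, tumor replaced by
#' a bright resection-cavity rim) — together with per-volume truth masks
#' of the target vessel, the true rigid displacements, a suggested
#' pattern ROI, and the generating seed.
#'
#' @slot ct1mr,iceusStart,iceusEnd [Volume3D-class]
#' @slot maskCt1mr,maskStart,maskEnd [BinaryMask3D-class] truth masks of
#'   the target (curved) vessel
#' @slot toStart [RigidTransform3D-class] mapping ct1mr world coordinates
#'   of a structure to its iCEUS-start position
#' @slot toEnd [RigidTransform3D-class] mapping iCEUS-start coordinates to
#'   iCEUS-end
#' @slot roi [RoiBox-class] enclosing the target vessel in the ct1mr-like
#'   volume (what a surgeon would delineate)
#' @slot seed integer seed that regenerates the set exactly
#' @seealso [makePhantomSet()]
#' @export
setClass("PhantomSet",
  representation(ct1mr = "Volume3D", iceusStart = "Volume3D",
                 iceusEnd = "Volume3D",
                 maskCt1mr = "BinaryMask3D", maskStart = "BinaryMask3D",
                 maskEnd = "BinaryMask3D",
                 toStart = "RigidTransform3D", toEnd = "RigidTransform3D",
                 roi = "RoiBox", seed = "integer"))
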