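## Validation metrics: Dice similarity index, Hausdorff distance,
## expert-normalized scores and the paired comparison of measures.

#' Dice similarity index
#'
#' \code{2 |X intersect Y| / (|X| + |Y|)}: 1 for perfect overlap, 0 for
#' disjoint masks.
#'
#' @param x,y [BinaryMask3D-class] objects on the same grid, at least one
#'   non-empty
#' @return a value in [0, 1]
#' @examples
#' a <- array(0, c(4, 4, 4)); a[1:2, 1:2, 1:2] <- 1
#' dice(BinaryMask3D(a), BinaryMask3D(a))
#' @export
dice <- function(x, y) {
  if (!all(dim(x@data) == dim(y@data)))
    stop("masks must share a grid")
  nx <- sum(x@data); ny <- sum(y@data)
  if (nx + ny == 0)
    stop("degenerate input: both masks are empty")
  2 * sum(x@data * y@data) / (nx + ny)
}

maskWorldCoords <- function(m) {
  d <- dim(m@data)
  v <- which(m@data != 0)
  i <- cbind((v - 1L) %% d[1],
             ((v - 1L) %/% d[1]) %% d[2],
             (v - 1L) %/% (d[1] * d[2]))
  sweep(sweep(i, 2, m@spacing, "*"), 2, m@origin, "+")
}

directedMaxMin <- function(A, B, chunk = 256L) {
  dmin <- rep(Inf, nrow(A))
  for (j in seq(1, nrow(B), by = chunk)) {
    idx <- j:min(j + chunk - 1L, nrow(B))
    d2 <- outer(A[, 1], B[idx, 1], "-")^2 +
      outer(A[, 2], B[idx, 2], "-")^2 +
      outer(A[, 3], B[idx, 3], "-")^2
    dmin <- pmin(dmin, do.call(pmin, as.data.frame(d2)))
  }
  sqrt(max(dmin))
}

#' Hausdorff distance between masks
#'
#' Symmetric max-min Euclidean distance between foreground voxel centers
#' in world mm (spacing and origin applied): the worst-case disagreement
#' between the two point sets. Exact (all foreground voxels, no
#' percentile truncation).
#'
#' @param x,y non-empty [BinaryMask3D-class] objects with the same
#'   spacing
#' @return distance in mm, >= 0
#' @export
hausdorffDistance <- function(x, y) {
  if (max(abs(x@spacing - y@spacing)) > 1e-9)
    stop("masks must share voxel spacing")
  A <- maskWorldCoords(x)
  B <- maskWorldCoords(y)
  if (nrow(A) == 0L || nrow(B) == 0L)
    stop("degenerate input: empty mask")
  max(directedMaxMin(A, B), directedMaxMin(B, A))
}

#' Construct a validation report
#'
#' @param dsi Dice similarity index in [0, 1]
#' @param hausdorffMm Hausdorff distance in mm
#' @param processingTimeS optional processing time in seconds
#' @return a [ValidationReport-class]
#' @export
validationReport <- function(dsi, hausdorffMm,
                             processingTimeS = numeric(0)) {
  new("ValidationReport", dsi = dsi, hausdorffMm = hausdorffMm,
      processingTimeS = processingTimeS)
}

#' Normalize a report against a reference (expert) report
#'
#' Fills the normalized fields as ratios: \code{dsi / reference dsi} and
#' \code{hausdorff / reference hausdorff}.
#'
#' @param report,reference [ValidationReport-class] objects; the
#'   reference must have dsi > 0 and hausdorff > 0
#' @return \code{report} with normalized fields set
#' @export
normalizeVsReference <- function(report, reference) {
  if (length(reference@dsi) != 1L || reference@dsi <= 0)
    stop("degenerate reference: dsi must be > 0")
  if (length(reference@hausdorffMm) != 1L || reference@hausdorffMm <= 0)
    stop("degenerate reference: hausdorff must be > 0")
  report@dsiNormalized <- report@dsi / reference@dsi
  report@hausdorffNormalized <- report@hausdorffMm / reference@hausdorffMm
  report
}

#' Paired comparison of per-case DSI values between two measures
#'
#' Two-sided paired t-test on the per-case differences. If every
#' difference is zero the comparison is degenerate and p = 1 is returned
#' by convention; if the differences are constant but nonzero (infinite
#' t statistic) p = 0 is returned. Both cases carry a
#' \code{degenerate = TRUE} attribute.
#'
#' @param dsiA,dsiB numeric vectors of equal length >= 3 (paired by case)
#' @return the p-value, with attribute \code{degenerate}
#' @examples
#' compareMeasures(c(0.9, 0.8, 0.95, 0.85), c(0.5, 0.4, 0.55, 0.45))
#' @export
compareMeasures <- function(dsiA, dsiB) {
  if (length(dsiA) != length(dsiB))
    stop("paired comparison requires equal lengths")
  if (length(dsiA) < 3L)
    stop("need at least 3 paired cases")
  d <- dsiA - dsiB
  tol <- 1e-10 * max(abs(d), 1)
  if (all(abs(d) <= tol))
    return(structure(1, degenerate = TRUE))
  if (stats::sd(d) <= tol)
    return(structure(0, degenerate = TRUE))
  p <- stats::t.test(dsiA, dsiB, paired = TRUE)$p.value
  structure(p, degenerate = FALSE)
}
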