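## Registration similarity measures: normalized cross correlation,
## normalized mutual information, normalized gradient fields.

asArray3 <- function(x) if (is(x, "Volume3D")) x@data else x

#' Normalized cross correlation
#'
#' Mean-centered cross correlation divided by N and the population
#' standard deviations, so identical images score 1 and images related
#' by a negative affine map score -1. Intended for same-modality
#' comparison.
#'
#' @param fixed,moving [Volume3D-class] objects (or arrays) on the same
#'   grid, each with nonzero intensity variance
#' @return a score in [-1, 1]
#' @export
ncc <- function(fixed, moving) {
  x <- as.vector(asArray3(fixed))
  y <- as.vector(asArray3(moving))
  if (length(x) != length(y))
    stop("images must share a grid")
  mx <- mean(x); my <- mean(y)
  sx <- sqrt(mean((x - mx)^2)); sy <- sqrt(mean((y - my)^2))
  if (sx == 0 || sy == 0)
    stop("degenerate input: zero intensity variance")
  mean((x - mx) * (y - my)) / (sx * sy)
}

jointHistogram <- function(x, y, bins) {
  binOf <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) return(rep(1L, length(v)))
    edges <- seq(r[1], r[2], length.out = bins + 1L)
    pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), bins)
  }
  bx <- binOf(x); by <- binOf(y)
  counts <- tabulate((by - 1L) * bins + bx, bins * bins)
  matrix(counts, bins, bins)
}

entropyBits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Normalized mutual information
#'
#' \code{(H(X) + H(Y)) / H(X, Y)} with marginal and joint entropies
#' (base-2) estimated from a bins x bins joint histogram, each image
#' binned over its own intensity range. Ranges from 1 (independence) to
#' 2 (deterministic dependence); suited to multi-modality comparison.
#'
#' @param fixed,moving [Volume3D-class] objects (or arrays) on the same
#'   grid
#' @param bins histogram bins per axis (default 32)
#' @return a score in [1, 2]
#' @export
nmi <- function(fixed, moving, bins = 32L) {
  x <- as.vector(asArray3(fixed))
  y <- as.vector(asArray3(moving))
  if (length(x) != length(y))
    stop("images must share a grid")
  j <- jointHistogram(x, y, as.integer(bins)) / length(x)
  hxy <- entropyBits(as.vector(j))
  if (hxy == 0)
    stop("degenerate input: joint entropy is zero (both images constant)")
  (entropyBits(rowSums(j)) + entropyBits(colSums(j))) / hxy
}

centralGradient <- function(a, spacing) {
  list(x = (shiftClamp(a, 1L, 0L, 0L) - shiftClamp(a, -1L, 0L, 0L)) /
         (2 * spacing[1]),
       y = (shiftClamp(a, 0L, 1L, 0L) - shiftClamp(a, 0L, -1L, 0L)) /
         (2 * spacing[2]),
       z = (shiftClamp(a, 0L, 0L, 1L) - shiftClamp(a, 0L, 0L, -1L)) /
         (2 * spacing[3]))
}

#' Regularized normalized gradient field
#'
#' Per-voxel \code{n(I, x) = grad I / sqrt(|grad I|^2 + epsilon^2)}
#' (central differences in world mm). Where the gradient is exactly
#' zero the field is the zero vector. Small \code{epsilon} pushes the
#' field toward unit vectors wherever structure is present; gradients
#' far below \code{epsilon} (noise) are damped toward zero.
#'
#' @param vol a [Volume3D-class]
#' @param epsilon regularization constant in intensity/mm, > 0
#' @return list of 3D arrays \code{x, y, z}; the per-voxel vector has
#'   norm <= 1
#' @export
ngfField <- function(vol, epsilon) {
  if (length(epsilon) != 1L || !is.finite(epsilon) || epsilon <= 0)
    stop("epsilon must be a single positive number")
  g <- centralGradient(vol@data, vol@spacing)
  nrm <- sqrt(g$x^2 + g$y^2 + g$z^2 + epsilon^2)
  list(x = g$x / nrm, y = g$y / nrm, z = g$z / nrm)
}

defaultNgfEpsilon <- function(fixed) {
  r <- diff(range(asArray3(fixed)))
  if (r <= 0) 1e-6 else 0.01 * r
}

ngfVoxelwise <- function(nx, ny) {
  dot <- nx$x * ny$x + nx$y * ny$y + nx$z * ny$z
  cx <- nx$y * ny$z - nx$z * ny$y
  cy <- nx$z * ny$x - nx$x * ny$z
  cz <- nx$x * ny$y - nx$y * ny$x
  list(dc = cx^2 + cy^2 + cz^2, dd = dot^2)
}

#' Normalized gradient field distance
#'
#' Mean over voxels of the squared cross product of the two regularized
#' normalized gradient fields (\code{form = "cross"}, minimized at
#' alignment), or of the squared dot product (\code{form = "dot"},
#' maximized at alignment). On voxels where both fields are exactly unit
#' length the two forms are complementary: \code{dc + dd = 1}.
#'
#' @param fixed,moving [Volume3D-class] objects on the same grid
#' @param epsilon regularization constant; \code{NULL} uses 1\% of the
#'   fixed image's intensity range
#' @param form \code{"cross"} (default) or \code{"dot"}
#' @return mean distance (cross) or mean alignment (dot), >= 0
#' @export
ngfDistance <- function(fixed, moving, epsilon = NULL,
                        form = c("cross", "dot")) {
  form <- match.arg(form)
  if (!all(dim(fixed@data) == dim(moving@data)))
    stop("images must share a grid")
  if (is.null(epsilon)) epsilon <- defaultNgfEpsilon(fixed)
  v <- ngfVoxelwise(ngfField(fixed, epsilon), ngfField(moving, epsilon))
  if (form == "cross") mean(v$dc) else mean(v$dd)
}

## ---- measure evaluation harness (used by registration) --------------

## Precompute the fixed-image side of a measure evaluation. The
## registration objective evaluates one fixed pattern against thousands
## of candidate moving images, so everything that depends only on the
## fixed image (intensity vector, NMI bin assignment, NGF gradient
## field) is computed once here.
##
## Evaluation domains differ by measure on purpose: NCC and NMI are
## statistics of the joint intensity sample and are evaluated on the
## common support only (voxels where the transformed pattern actually
## overlaps the search region) — padding the moving image with a
## constant would manufacture spurious correlation/mutual information.
## NGF is evaluated on the full pattern grid with background 0 outside
## the search region, charging cost 1 for pattern structure the overlap
## fails to explain.
measureCache <- function(measure, fixedArr, spacing) {
  name <- measure@name
  cache <- list(name = name, fixed = fixedArr, spacing = spacing,
                xvec = as.vector(fixedArr))
  if (name == "NMI") {
    bins <- as.integer(measure@options$bins %||% 32L)
    cache$bins <- bins
    r <- range(fixedArr)
    cache$bx <- if (r[1] == r[2]) rep(1L, length(fixedArr)) else {
      edges <- seq(r[1], r[2], length.out = bins + 1L)
      pmin(pmax(findInterval(fixedArr, edges, rightmost.closed = TRUE),
                1L), bins)
    }
  } else if (name == "NGF") {
    cache$eps <- measure@options$epsilon %||% defaultNgfEpsilon(fixedArr)
    cache$field <- ngfField(Volume3D(fixedArr, spacing = spacing),
                            cache$eps)
  }
  cache
}

## Evaluate against a cached fixed image. `movingArr` is on the full
## pattern grid; `validIdx` (NULL = all) selects the common-support
## voxels for the intensity measures. Returns cost (lower is better) and
## the user-facing score, or NULL if degenerate (skipped in scans).
evalMeasureCached <- function(cache, movingArr, validIdx = NULL) {
  if (cache$name == "NCC") {
    x <- if (is.null(validIdx)) cache$xvec else cache$xvec[validIdx]
    y <- if (is.null(validIdx)) as.vector(movingArr)
         else as.vector(movingArr)[validIdx]
    xc <- x - mean(x); yc <- y - mean(y)
    sx <- sqrt(mean(xc^2)); sy <- sqrt(mean(yc^2))
    if (sx == 0 || sy == 0) return(NULL)
    sc <- mean(xc * yc) / (sx * sy)
    list(cost = -sc, score = sc)
  } else if (cache$name == "NMI") {
    bins <- cache$bins
    bx <- if (is.null(validIdx)) cache$bx else cache$bx[validIdx]
    y <- if (is.null(validIdx)) as.vector(movingArr)
         else as.vector(movingArr)[validIdx]
    r <- range(y)
    by <- if (r[1] == r[2]) rep(1L, length(y)) else {
      edges <- seq(r[1], r[2], length.out = bins + 1L)
      pmin(pmax(findInterval(y, edges, rightmost.closed = TRUE), 1L),
           bins)
    }
    j <- tabulate((by - 1L) * bins + bx, bins * bins) / length(y)
    jm <- matrix(j, bins, bins)
    hxy <- entropyBits(j)
    if (hxy == 0) return(NULL)
    sc <- (entropyBits(rowSums(jm)) + entropyBits(colSums(jm))) / hxy
    list(cost = -sc, score = sc)
  } else {
    mv <- Volume3D(array(movingArr, dim(cache$fixed)),
                   spacing = cache$spacing)
    v <- ngfVoxelwise(cache$field, ngfField(mv, cache$eps))
    # the optimizer minimizes mean(1 - dd): identical to the cross-form
    # distance on unit-gradient voxels, but structureless voxels cost 1
    # instead of a spurious 0, so empty overlaps cannot win the scan
    list(cost = mean(1 - v$dd), score = mean(v$dc))
  }
}

## One-shot convenience wrapper
evalMeasureArrays <- function(measure, fixedArr, movingArr, spacing) {
  evalMeasureCached(measureCache(measure, fixedArr, spacing), movingArr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Does a higher score mean a better match?
#'
#' TRUE for NCC and NMI, FALSE for NGF (whose score is the dc distance).
#'
#' @param measure a [SimilarityMeasure-class]
#' @return logical
#' @export
higherIsBetter <- function(measure) measure@name %in% c("NCC", "NMI")
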