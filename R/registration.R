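## ROI-constrained rigid registration: exhaustive integer-voxel
## translation scan over the search region followed by derivative-free
## (Nelder-Mead) refinement of all six rigid parameters.

#' Build the search region for a pattern ROI
#'
#' The region of the target volume in which the pattern is searched: it
#' has twice the volume of the source ROI (each dimension scaled by
#' 2^(1/3) and rounded to the nearest integer) and is centered on the
#' same index position, then clipped to the target bounds. If clipping
#' reduces the volume a warning is recorded in the \code{clipped} flag
#' (and emitted).
#'
#' @param sourceRoi the pattern [RoiBox-class] (defined in the
#'   preoperative volume)
#' @param target the [Volume3D-class] to be searched
#' @return a [SearchRegion-class]
#' @examples
#' v <- Volume3D(array(0, c(100, 100, 100)))
#' buildSearchRegion(RoiBox(c(40, 40, 40), c(20, 20, 20)), v)
#' @export
buildSearchRegion <- function(sourceRoi, target) {
  d <- dim(target@data)
  ctr <- roiCenter(sourceRoi)
  if (any(ctr < 0) || any(ctr > d - 1))
    stop("source ROI center lies outside the target volume")
  newSize <- pmax(1L, as.integer(round(sourceRoi@size * 2^(1 / 3))))
  start <- as.integer(round(ctr - (newSize - 1) / 2))
  startClip <- pmax(start, 0L)
  endClip <- pmin(start + newSize, d)
  sizeClip <- pmax(endClip - startClip, 1L)
  clipped <- any(sizeClip < newSize)
  if (clipped)
    warning("search region clipped at the target border; volume reduced")
  new("SearchRegion", box = RoiBox(startClip, sizeClip),
      provenance = sourceRoi, clipped = clipped)
}

patternCenterWorld <- function(pattern) {
  pattern@origin + (dim(pattern@data) - 1) / 2 * pattern@spacing
}

## Evaluate a similarity measure for a rigid transform mapping the
## pattern into the search volume: the search volume is sampled on the
## transformed pattern grid (background 0 outside its domain) and the
## measure computed on the full grids. Degenerate or low-overlap
## configurations get cost Inf.
similarityAtInternal <- function(pattern, search, measure, transform,
                                 minValidFrac = 0.25, gridWorld = NULL,
                                 cache = NULL) {
  if (is.null(gridWorld)) gridWorld <- refGridWorld(pattern)
  if (is.null(cache))
    cache <- measureCache(measure, pattern@data, pattern@spacing)
  q <- applyTransform(transform, gridWorld)
  s <- sampleTrilinear(search, q, background = 0)
  if (mean(s$valid) < minValidFrac)
    return(list(cost = Inf, score = NA_real_))
  validIdx <- if (cache$name == "NGF" || all(s$valid)) NULL
              else which(s$valid)
  r <- evalMeasureCached(cache, array(s$values, dim(pattern@data)),
                         validIdx)
  if (is.null(r)) return(list(cost = Inf, score = NA_real_))
  r
}

#' Evaluate a similarity measure at a given transform
#'
#' Re-evaluates the registration objective: the search volume is sampled
#' on the pattern grid mapped through \code{transform} and the measure is
#' computed between the pattern and the sampled values. This is exactly
#' the function [registerRigid()] optimizes, so re-evaluating at a
#' result's transform reproduces its score.
#'
#' @param pattern,search [Volume3D-class] objects with equal spacing
#' @param measure a [SimilarityMeasure-class]
#' @param transform a [RigidTransform3D-class] (pattern world to search
#'   world)
#' @return the similarity score (NCC/NMI value, or NGF dc distance)
#' @export
similarityAt <- function(pattern, search, measure, transform) {
  similarityAtInternal(pattern, search, measure, transform)$score
}

## Integer-offset scan. Returns list(best = c(dx,dy,dz), cost, score,
## table). Offsets keep at least half the pattern overlapping the search
## region per axis and at least a quarter of its volume overall. Each
## offset is scored with the same objective the refinement stage uses:
## the full pattern grid against the search content, voxels falling
## outside the search region set to the background value 0.
scanTranslations <- function(pattern, search, measure,
                             maxExhaustive = 1500L, cache = NULL) {
  if (is.null(cache))
    cache <- measureCache(measure, pattern@data, pattern@spacing)
  pd <- dim(pattern@data); sd <- dim(search@data)
  minov <- pmax(1L, ceiling(pd / 2))
  lo <- as.integer(minov - pd)
  hi <- as.integer(sd - minov)
  ranges <- lapply(1:3, function(a) lo[a]:hi[a])
  evalOffset <- function(d) {
    pLo <- pmax(0L, -d); pHi <- pmin(pd, sd - d)
    if (any(pHi - pLo < 1L)) return(NULL)
    full <- all(pHi - pLo == pd)
    if (prod(pHi - pLo) < 0.25 * prod(pd)) return(NULL)
    sLo <- pLo + d; sHi <- pHi + d
    mov <- array(0, pd)
    mov[(pLo[1] + 1):pHi[1], (pLo[2] + 1):pHi[2], (pLo[3] + 1):pHi[3]] <-
      search@data[(sLo[1] + 1):sHi[1], (sLo[2] + 1):sHi[2],
                  (sLo[3] + 1):sHi[3]]
    validIdx <- if (cache$name == "NGF" || full) NULL else
      as.vector(outer(outer((pLo[1] + 1):pHi[1],
                            ((pLo[2] + 1):pHi[2] - 1L) * pd[1], "+"),
                      ((pLo[3] + 1):pHi[3] - 1L) * pd[1] * pd[2], "+"))
    evalMeasureCached(cache, mov, validIdx)
  }
  evalGrid <- function(offsets) {
    res <- vector("list", nrow(offsets))
    for (i in seq_len(nrow(offsets))) {
      r <- evalOffset(offsets[i, ])
      res[[i]] <- if (is.null(r)) c(NA_real_, NA_real_)
                  else c(r$cost, r$score)
    }
    cbind(offsets, do.call(rbind, res))
  }
  fullGrid <- function(rs) as.matrix(expand.grid(dx = rs[[1]],
                                                 dy = rs[[2]],
                                                 dz = rs[[3]]))
  nTotal <- prod(vapply(ranges, length, 1L))
  # intensity measures are cheap per offset and their optima can be
  # arbitrarily narrow, so they are scanned exhaustively; the NGF
  # objective is costlier but smooth on segmented structures, where a
  # coarse-to-fine scan is reliable
  if (cache$name != "NGF") maxExhaustive <- max(maxExhaustive, 50000L)
  if (nTotal <= maxExhaustive) {
    tab <- evalGrid(fullGrid(ranges))
  } else {
    # coarse stride-2 pass, then stride-1 refinement around the best
    # few coarse candidates (the objective can be sharply peaked, so a
    # single neighborhood may straddle the wrong local plateau)
    coarse <- lapply(ranges, function(r) r[seq(1, length(r), by = 2)])
    tab <- evalGrid(fullGrid(coarse))
    ok <- which(is.finite(tab[, 4]))
    if (length(ok)) {
      okTab <- tab[ok, , drop = FALSE]
      ord <- order(okTab[, 4])
      top <- okTab[ord[seq_len(min(5L, length(ord)))], , drop = FALSE]
      for (r in seq_len(nrow(top))) {
        fine <- lapply(1:3, function(a)
          intersect((top[r, a] - 2):(top[r, a] + 2), ranges[[a]]))
        tab <- rbind(tab, evalGrid(fullGrid(fine)))
      }
    }
  }
  ok <- which(is.finite(tab[, 4]))
  if (length(ok) == 0L)
    stop("no overlap with usable structure at any scan position")
  best <- bestScanRow(tab[ok, , drop = FALSE])
  colnames(tab) <- c("dx", "dy", "dz", "cost", "score")
  list(offset = as.integer(best[1:3]), cost = best[4], score = best[5],
       table = as.data.frame(tab))
}

## smallest cost wins; ties broken by smaller translation norm, then
## lexicographically
bestScanRow <- function(tab) {
  o <- order(tab[, 4], tab[, 1]^2 + tab[, 2]^2 + tab[, 3]^2,
             tab[, 1], tab[, 2], tab[, 3])
  tab[o[1], ]
}

#' Rigid registration of a pattern inside a search region
#'
#' Two-stage 6-DOF optimization: (1) an exhaustive integer-voxel
#' translation scan over the search region (for large offset spaces, a
#' stride-2 coarse pass followed by a stride-1 local pass); (2)
#' Nelder-Mead refinement of all six parameters (translation in mm,
#' rotation in degrees, bounded by \code{rotationBound}) starting from
#' the best scanned offset. The refinement objective never degrades
#' relative to its starting point, and the returned score is the
#' objective re-evaluated at the returned transform.
#'
#' @param pattern a [Volume3D-class]; the (prepared) pattern image, no
#'   larger than the search region in any dimension and not constant
#' @param search a [Volume3D-class] with the same voxel spacing
#' @param measure a [SimilarityMeasure-class]
#' @param init optional [RigidTransform3D-class] used as an additional
#'   refinement start if it beats the scan
#' @param refine if FALSE, stop after the translation scan
#' @param rotationBound rotation bound in degrees for refinement
#'   (default 15; craniotomy geometry makes larger rotations implausible)
#' @param maxit Nelder-Mead iteration cap
#' @param maxExhaustive offset-count threshold above which the scan
#'   switches from exhaustive to coarse-to-fine
#' @return a [RegistrationResult-class]
#' @export
registerRigid <- function(pattern, search, measure, init = NULL,
                          refine = TRUE, rotationBound = 15,
                          maxit = 250L, maxExhaustive = 1500L) {
  if (max(abs(pattern@spacing - search@spacing)) > 1e-6)
    stop("pattern and search region must share voxel spacing")
  pd <- dim(pattern@data); sd <- dim(search@data)
  if (any(pd > sd))
    stop("pattern must not exceed the search region in any dimension")
  if (diff(range(pattern@data)) == 0)
    stop("degenerate input: pattern is constant (empty pattern mask)")
  ctr <- patternCenterWorld(pattern)
  cache <- measureCache(measure, pattern@data, pattern@spacing)
  scan <- scanTranslations(pattern, search, measure, cache = cache,
                           maxExhaustive = maxExhaustive)
  t0 <- (search@origin - pattern@origin) + scan$offset * pattern@spacing
  par0 <- c(t0, 0, 0, 0)
  gridWorld <- refGridWorld(pattern)
  costFn <- function(par) {
    if (any(abs(par[4:6]) > rotationBound)) return(1e10)
    tr <- RigidTransform3D(rotation = par[4:6], translation = par[1:3],
                           center = ctr)
    cst <- similarityAtInternal(pattern, search, measure, tr,
                                gridWorld = gridWorld, cache = cache)$cost
    if (!is.finite(cst)) 1e10 else cst
  }
  if (!is.null(init)) {
    # fold the initializer into the same parameterization
    Mi <- rigidMatrix(init)
    R <- Mi[1:3, 1:3]
    ti <- Mi[1:3, 4] - ctr + as.numeric(R %*% ctr)
    parI <- c(ti, eulerZYXFromMatrix(R))
    if (costFn(parI) < costFn(par0)) par0 <- parI
  }
  converged <- TRUE
  parBest <- par0
  if (refine) {
    opt <- stats::optim(par0, costFn, method = "Nelder-Mead",
                        control = list(maxit = maxit,
                                       parscale = c(pattern@spacing, 2, 2, 2)))
    if (opt$value <= costFn(par0)) parBest <- opt$par
    converged <- opt$convergence == 0
  }
  transform <- RigidTransform3D(rotation = parBest[4:6],
                                translation = parBest[1:3], center = ctr)
  final <- similarityAtInternal(pattern, search, measure, transform,
                                gridWorld = gridWorld, cache = cache)
  qc <- applyTransform(transform, ctr)
  ctrIdx <- (qc - search@origin) / search@spacing
  start <- as.integer(round(ctrIdx - (pd - 1) / 2))
  start <- pmin(pmax(start, 0L), pmax(sd - pd, 0L))
  new("RegistrationResult", transform = transform, score = final$score,
      locatedBox = RoiBox(start, pd), converged = converged,
      trace = c(scan = unname(scan$score), refined = unname(final$score)),
      scan = scan$table)
}

prepareRepresentation <- function(seg, inputMode) {
  if (inputMode == "binary") {
    Volume3D(seg@mask@data, spacing = seg@mask@spacing,
             origin = seg@mask@origin)
  } else {
    Volume3D(seg@vesselness@data * seg@mask@data,
             spacing = seg@mask@spacing, origin = seg@mask@origin)
  }
}

#' Identify a pattern vessel inside a target volume
#'
#' Pipeline composition for one identification step: crop the pattern
#' ROI, segment its vessels, build and crop the search region in the
#' target, segment it, and rigidly register the two segmented
#' representations. The representation the measure sees is controlled by
#' the measure's \code{inputMode} option (vesselness image restricted to
#' the segmented support, or the binary masks).
#'
#' @param patternVol the volume the ROI was drawn in (cT1MR-like)
#' @param patternRoi a [RoiBox-class] enclosing the vessel
#' @param target the volume searched (iCEUS-like)
#' @param measure a [SimilarityMeasure-class]
#' @param params a [VesselnessParams-class]
#' @param keepLargest retain only the largest component of the pattern
#'   mask (default TRUE; suppresses speckle islands). The search-region
#'   mask is never pruned: it may contain several structures and the
#'   largest need not be the target.
#' @param step label stored in the result ("start" or "end")
#' @return an [IdentificationResult-class]
#' @export
identifyPattern <- function(patternVol, patternRoi, target, measure,
                            params = VesselnessParams(),
                            keepLargest = TRUE, step = "start") {
  patReg <- cropVolume(patternVol, patternRoi)
  segP <- tryCatch(
    segmentVessels(patReg, params, keepLargest = keepLargest),
    error = function(e) stop("pattern segmentation failed (step ", step,
                             "): ", conditionMessage(e), call. = FALSE))
  sr <- buildSearchRegion(patternRoi, target)
  searchReg <- cropVolume(target, sr@box)
  # no component pruning on the search side: the region may legitimately
  # contain several structures and the largest need not be the target
  segS <- tryCatch(
    segmentVessels(searchReg, params, keepLargest = FALSE),
    error = function(e) stop("search-region segmentation failed (step ",
                             step, "): ", conditionMessage(e),
                             call. = FALSE))
  inputMode <- measure@options$inputMode %||% "vesselness"
  pRep <- prepareRepresentation(segP, inputMode)
  sRep <- prepareRepresentation(segS, inputMode)
  reg <- registerRigid(pRep, sRep, measure)
  d <- dim(target@data)
  start <- sr@box@start + reg@locatedBox@start
  start <- pmin(pmax(start, 0L), pmax(d - patternRoi@size, 0L))
  new("IdentificationResult", step = step,
      locatedBox = RoiBox(start, patternRoi@size),
      transform = reg@transform, score = reg@score,
      measure = measure@name,
      patternMask = segP@mask, targetMask = segS@mask,
      patternRoi = patternRoi, searchRegion = sr,
      targetDim = as.integer(d), targetSpacing = target@spacing,
      targetOrigin = target@origin, metrics = list())
}
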