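## Synthetic phantoms: bright tubular structures (straight, arc, helix)
## with Gaussian cross-sections in a noisy background, paired volumes
## related by known rigid displacements, and ultrasound-like speckle.
## These emulate sub-2 mm vessels at ~1 mm isotropic voxels so every
## pipeline stage is testable with exact ground truth.

sampleCurve <- function(fn, t0, t1, step) {
  # oversample the parameter, then resample at ~step arc-length spacing
  tt <- seq(t0, t1, length.out = 512)
  pts <- fn(tt)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                         pts[-nrow(pts), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  si <- unique(c(seq(0, s[length(s)], by = step), s[length(s)]))
  cbind(stats::approx(s, pts[, 1], xout = si)$y,
        stats::approx(s, pts[, 2], xout = si)$y,
        stats::approx(s, pts[, 3], xout = si)$y)
}

#' Tube constructors
#'
#' Build a [TubeSpec-class] with a straight, circular-arc or helical
#' centerline. Coordinates are world mm; the centerline is densely
#' sampled (about every \code{step} mm).
#'
#' @param from,to endpoints of a straight segment (mm)
#' @param center arc/helix center (mm)
#' @param arcRadius,helixRadius curve radius in mm
#' @param angles angular range in degrees, length 2
#' @param normal plane normal of the arc (need not be unit length)
#' @param axis helix axis direction
#' @param pitch helix advance per turn (mm)
#' @param radius tube radius in mm (default 0.8: a sub-2 mm-diameter
#'   vessel)
#' @param peak centerline intensity added above background
#' @param profile Gaussian cross-section width factor; the default
#'   \code{1/sqrt(2 log 2)} puts the half-maximum surface at
#'   \code{radius}
#' @param step centerline sampling step in mm
#' @return a [TubeSpec-class]
#' @export
straightTube <- function(from, to, radius = 0.8, peak = 100,
                         profile = 1 / sqrt(2 * log(2)), step = 0.25) {
  fn <- function(t) cbind(from[1] + t * (to[1] - from[1]),
                          from[2] + t * (to[2] - from[2]),
                          from[3] + t * (to[3] - from[3]))
  new("TubeSpec", centerline = sampleCurve(fn, 0, 1, step),
      radius = radius, peak = peak, profile = profile)
}

orthoBasis <- function(normal) {
  n <- normal / sqrt(sum(normal^2))
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  list(u = u, v = v)
}

#' @rdname straightTube
#' @export
arcTube <- function(center, arcRadius, angles = c(0, 150),
                    normal = c(0, 0, 1), radius = 0.8, peak = 100,
                    profile = 1 / sqrt(2 * log(2)), step = 0.25) {
  b <- orthoBasis(normal)
  fn <- function(t) {
    th <- t * pi / 180
    cbind(center[1] + arcRadius * (cos(th) * b$u[1] + sin(th) * b$v[1]),
          center[2] + arcRadius * (cos(th) * b$u[2] + sin(th) * b$v[2]),
          center[3] + arcRadius * (cos(th) * b$u[3] + sin(th) * b$v[3]))
  }
  new("TubeSpec", centerline = sampleCurve(fn, angles[1], angles[2], step),
      radius = radius, peak = peak, profile = profile)
}

#' @rdname straightTube
#' @export
helixTube <- function(center, helixRadius, pitch, angles = c(0, 720),
                      axis = c(0, 0, 1), radius = 0.8, peak = 100,
                      profile = 1 / sqrt(2 * log(2)), step = 0.25) {
  b <- orthoBasis(axis)
  n <- axis / sqrt(sum(axis^2))
  fn <- function(t) {
    th <- t * pi / 180
    adv <- pitch * th / (2 * pi)
    cbind(center[1] + helixRadius * (cos(th) * b$u[1] + sin(th) * b$v[1]) +
            adv * n[1],
          center[2] + helixRadius * (cos(th) * b$u[2] + sin(th) * b$v[2]) +
            adv * n[2],
          center[3] + helixRadius * (cos(th) * b$u[3] + sin(th) * b$v[3]) +
            adv * n[3])
  }
  new("TubeSpec", centerline = sampleCurve(fn, angles[1], angles[2], step),
      radius = radius, peak = peak, profile = profile)
}

transformTube <- function(tube, transform) {
  tube@centerline <- applyTransform(transform, tube@centerline)
  tube
}

## minimum distance from each listed voxel (world coords matrix) to the
## centerline point set
minDistToCurve <- function(coords, pts) {
  dmin <- rep(Inf, nrow(coords))
  for (i in seq_len(nrow(pts))) {
    d2 <- (coords[, 1] - pts[i, 1])^2 + (coords[, 2] - pts[i, 2])^2 +
      (coords[, 3] - pts[i, 3])^2
    dmin <- pmin(dmin, d2)
  }
  sqrt(dmin)
}

#' Rasterize tubes into a volume
#'
#' Intensity is \code{background + sum over tubes of peak *
#' exp(-d^2 / (2 (profile * radius)^2))} with \code{d} the distance to
#' the tube centerline. The mask marks voxels where any single tube's
#' contribution reaches half its peak.
#'
#' @param shape voxel grid dimensions (length 3)
#' @param spacing voxel size in mm (length 1 or 3)
#' @param tubes list of [TubeSpec-class] objects, all fitting inside the
#'   volume with a margin of at least twice their radius
#' @param background background intensity
#' @param origin world origin of the grid
#' @return list with elements \code{volume} ([Volume3D-class]),
#'   \code{mask} ([BinaryMask3D-class], union over tubes) and
#'   \code{masks} (per-tube list)
#' @export
makeTubeVolume <- function(shape, spacing, tubes, background = 0,
                           origin = c(0, 0, 0)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  shape <- as.integer(shape)
  lim0 <- origin
  lim1 <- origin + (shape - 1) * spacing
  arr <- array(background, shape)
  masks <- vector("list", length(tubes))
  xs <- origin[1] + (seq_len(shape[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(shape[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(shape[3]) - 1) * spacing[3]
  for (ti in seq_along(tubes)) {
    tube <- tubes[[ti]]
    pts <- tube@centerline
    m <- 2 * tube@radius
    if (any(apply(pts, 2, min) - m < lim0) ||
        any(apply(pts, 2, max) + m > lim1))
      stop("tube ", ti, " does not fit inside the volume with a 2*radius",
           " margin")
    w <- tube@profile * tube@radius
    cut <- 4 * w + max(spacing)
    sel1 <- which(xs >= min(pts[, 1]) - cut & xs <= max(pts[, 1]) + cut)
    sel2 <- which(ys >= min(pts[, 2]) - cut & ys <= max(pts[, 2]) + cut)
    sel3 <- which(zs >= min(pts[, 3]) - cut & zs <= max(pts[, 3]) + cut)
    coords <- as.matrix(expand.grid(x = xs[sel1], y = ys[sel2],
                                    z = zs[sel3]))
    d <- minDistToCurve(coords, pts)
    contrib <- tube@peak * exp(-d^2 / (2 * w^2))
    contrib[d > cut] <- 0
    sub <- array(contrib, c(length(sel1), length(sel2), length(sel3)))
    arr[sel1, sel2, sel3] <- arr[sel1, sel2, sel3] + sub
    mk <- array(0, shape)
    mk[sel1, sel2, sel3] <- as.numeric(sub >= tube@peak / 2)
    masks[[ti]] <- BinaryMask3D(mk, spacing = spacing, origin = origin)
  }
  union <- array(0, shape)
  for (mk in masks) union <- pmax(union, mk@data)
  list(volume = Volume3D(arr, spacing = spacing, origin = origin),
       mask = BinaryMask3D(union, spacing = spacing, origin = origin),
       masks = masks)
}

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed",
                                envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Add multiplicative ultrasound-like speckle
#'
#' First-order speckle model: \code{out = vol * (1 + strength * (R -
#' mu_R) / sd_R)} with \code{R} Rayleigh(1)-distributed, clipped at 0.
#' The noise factor has mean 1, so image mean is preserved in
#' expectation. Deterministic for a given seed; the caller's RNG state
#' is untouched.
#'
#' @param vol a [Volume3D-class]
#' @param strength noise strength >= 0 (0 returns the input unchanged)
#' @param seed integer seed
#' @return a [Volume3D-class]
#' @export
addSpeckle <- function(vol, strength, seed) {
  if (strength < 0) stop("strength must be >= 0")
  if (strength == 0) return(vol)
  n <- length(vol@data)
  r <- withSeed(seed, sqrt(-2 * log(runif(n))))
  muR <- sqrt(pi / 2)
  sdR <- sqrt(2 - pi / 2)
  fac <- pmax(1 + strength * (r - muR) / sdR, 0)
  Volume3D(array(vol@data * fac, dim(vol@data)), spacing = vol@spacing,
           origin = vol@origin)
}

gaussianBlob <- function(shape, spacing, origin, center, radius, peak) {
  xs <- origin[1] + (seq_len(shape[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(shape[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(shape[3]) - 1) * spacing[3]
  d2 <- outer(outer((xs - center[1])^2, (ys - center[2])^2, "+"),
              (zs - center[3])^2, "+")
  peak * exp(-d2 / (2 * (radius / 1.5)^2))
}

shellBlob <- function(shape, spacing, origin, center, radius, thickness,
                      peak) {
  xs <- origin[1] + (seq_len(shape[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(shape[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(shape[3]) - 1) * spacing[3]
  d <- sqrt(outer(outer((xs - center[1])^2, (ys - center[2])^2, "+"),
                  (zs - center[3])^2, "+"))
  peak * exp(-(d - radius)^2 / (2 * thickness^2))
}

phantomDefaults <- function() {
  list(shape = c(64L, 64L, 64L), spacing = c(1, 1, 1),
       backgroundCt1mr = 10, backgroundIceus = 20,
       peakCt1mr = 100, peakIceus = 80,
       tubeRadius = 0.8,
       arcRadius = 12, arcAngles = c(10, 160),
       arcNormal = c(0.25, 0.25, 1),
       tumorOffset = c(8, -6, 4), tumorRadius = 6,
       tumorPeakCt1mr = 60, tumorPeakIceus = 50,
       cavityThickness = 1.5, cavityPeak = 60,
       noiseCt1mr = 2, speckle = 0.3,
       maxShiftMm = 5, maxRotDeg = 5,
       translationStart = NULL, rotationStart = NULL,
       translationEnd = NULL, rotationEnd = NULL,
       decoy = FALSE, decoyOffset = c(0, 7, 0))
}

#' Generate a phantom dataset with known ground truth
#'
#' Builds three volumes sharing tube geometry: a cT1MR-like volume (high
#' SNR, bright curved target vessel, bright tumor blob), an
#' iCEUS-start-like volume (the same anatomy rigidly displaced, speckle,
#' tumor present) and an iCEUS-end-like volume (further displaced,
#' speckle, tumor replaced by a bright resection-cavity rim — a shell
#' that can be mistaken for a vessel). Displacements default to at most
#' 5 mm translation and 5 degrees rotation per axis (brain-shift scale),
#' sampled from the seed unless given explicitly in \code{config}
#' (\code{translationStart}, \code{rotationStart}, \code{translationEnd},
#' \code{rotationEnd}). \code{config$decoy = TRUE} adds a straight decoy
#' tube near the target vessel in the displaced volumes. Regenerating
#' with the same seed reproduces identical volumes.
#'
#' @param seed integer seed
#' @param config named list overriding entries of the default scene
#'   (grid, intensities, tube geometry, noise, displacement bounds)
#' @return a [PhantomSet-class]
#' @examples
#' set <- makePhantomSet(seed = 0,
#'                       config = list(translationStart = c(2, -1, 1),
#'                                     rotationStart = c(0, 0, 2)))
#' set@roi
#' @export
makePhantomSet <- function(seed = 0L, config = list()) {
  cfg <- utils::modifyList(phantomDefaults(), config)
  shape <- as.integer(cfg$shape)
  spacing <- if (length(cfg$spacing) == 1L) rep(cfg$spacing, 3)
             else cfg$spacing
  ctrWorld <- (shape - 1) / 2 * spacing
  draws <- withSeed(seed, list(
    tStart = stats::runif(3, -cfg$maxShiftMm, cfg$maxShiftMm),
    rStart = stats::runif(3, -cfg$maxRotDeg, cfg$maxRotDeg),
    tEnd = stats::runif(3, -cfg$maxShiftMm, cfg$maxShiftMm),
    rEnd = stats::runif(3, -cfg$maxRotDeg, cfg$maxRotDeg)))
  toStart <- RigidTransform3D(
    rotation = cfg$rotationStart %||% draws$rStart,
    translation = cfg$translationStart %||% draws$tStart,
    center = ctrWorld)
  toEnd <- RigidTransform3D(
    rotation = cfg$rotationEnd %||% draws$rEnd,
    translation = cfg$translationEnd %||% draws$tEnd,
    center = ctrWorld)
  target0 <- arcTube(center = ctrWorld, arcRadius = cfg$arcRadius,
                     angles = cfg$arcAngles, normal = cfg$arcNormal,
                     radius = cfg$tubeRadius, peak = cfg$peakCt1mr)
  tumor0 <- ctrWorld + cfg$tumorOffset
  ## --- cT1MR-like ---
  ras <- makeTubeVolume(shape, spacing, list(target0),
                        background = cfg$backgroundCt1mr)
  arr <- ras$volume@data +
    gaussianBlob(shape, spacing, c(0, 0, 0), tumor0, cfg$tumorRadius,
                 cfg$tumorPeakCt1mr)
  if (cfg$noiseCt1mr > 0)
    arr <- arr + withSeed(seed + 11L,
                          array(stats::rnorm(prod(shape), 0, cfg$noiseCt1mr),
                                shape))
  ct1mr <- Volume3D(arr, spacing = spacing)
  maskCt <- ras$mask
  ## --- iCEUS-start-like ---
  targetS <- transformTube(target0, toStart)
  targetS@peak <- cfg$peakIceus
  tubesS <- list(targetS)
  if (isTRUE(cfg$decoy)) {
    ends0 <- target0@centerline[c(1, nrow(target0@centerline)), ]
    chord <- ends0[2, ] - ends0[1, ]
    off <- cfg$decoyOffset
    decoyS <- straightTube(ends0[1, ] + off - 0.25 * chord,
                           ends0[2, ] + off + 0.25 * chord,
                           radius = cfg$tubeRadius, peak = cfg$peakIceus)
    tubesS <- c(tubesS, list(transformTube(decoyS, toStart)))
  }
  rasS <- makeTubeVolume(shape, spacing, tubesS,
                         background = cfg$backgroundIceus)
  tumorS <- applyTransform(toStart, tumor0)
  arrS <- rasS$volume@data +
    gaussianBlob(shape, spacing, c(0, 0, 0), tumorS, cfg$tumorRadius,
                 cfg$tumorPeakIceus)
  volS <- addSpeckle(Volume3D(arrS, spacing = spacing), cfg$speckle,
                     seed + 12L)
  maskS <- rasS$masks[[1]]
  ## --- iCEUS-end-like ---
  tubesE <- lapply(tubesS, transformTube, transform = toEnd)
  rasE <- makeTubeVolume(shape, spacing, tubesE,
                         background = cfg$backgroundIceus)
  tumorE <- applyTransform(toEnd, tumorS)
  arrE <- rasE$volume@data +
    shellBlob(shape, spacing, c(0, 0, 0), tumorE, cfg$tumorRadius,
              cfg$cavityThickness, cfg$cavityPeak)
  volE <- addSpeckle(Volume3D(arrE, spacing = spacing), cfg$speckle,
                     seed + 13L)
  maskE <- rasE$masks[[1]]
  ## --- suggested pattern ROI: truth-mask bounding box + margin ---
  v <- which(maskCt@data != 0)
  d <- shape
  i <- cbind((v - 1L) %% d[1],
             ((v - 1L) %/% d[1]) %% d[2],
             (v - 1L) %/% (d[1] * d[2]))
  lo <- pmax(apply(i, 2, min) - 3L, 0L)
  hi <- pmin(apply(i, 2, max) + 3L, d - 1L)
  roi <- RoiBox(lo, hi - lo + 1L)
  new("PhantomSet", ct1mr = ct1mr, iceusStart = volS, iceusEnd = volE,
      maskCt1mr = maskCt, maskStart = maskS, maskEnd = maskE,
      toStart = toStart, toEnd = toEnd, roi = roi,
      seed = as.integer(seed))
}
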