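## Geometric operations on volumes: index/world mapping, cropping,
## rigid resampling with trilinear interpolation.

#' Convert between voxel indices and world coordinates
#'
#' Indices are 0-based; the world coordinate of index \code{i} is
#' \code{origin + i * spacing}, per axis.
#'
#' @param vol a [Volume3D-class]
#' @param index numeric vector of length 3 or n x 3 matrix (may be
#'   fractional)
#' @param world numeric vector of length 3 or n x 3 matrix, mm
#' @return the mapped coordinates, same shape as the input
#' @export
indexToWorld <- function(vol, index) {
  if (is.null(dim(index)))
    vol@origin + index * vol@spacing
  else
    sweep(sweep(index, 2, vol@spacing, "*"), 2, vol@origin, "+")
}

#' @rdname indexToWorld
#' @export
worldToIndex <- function(vol, world) {
  if (is.null(dim(world)))
    (world - vol@origin) / vol@spacing
  else
    sweep(sweep(world, 2, vol@origin), 2, vol@spacing, "/")
}

#' Center of an ROI box
#'
#' The (possibly half-integer) 0-based index of the box center,
#' \code{start + (size - 1) / 2}.
#'
#' @param roi a [RoiBox-class]
#' @return numeric(3)
#' @export
roiCenter <- function(roi) {
  roi@start + (roi@size - 1) / 2
}

roiInside <- function(roi, dims) {
  all(roi@start >= 0L) && all(roi@start + roi@size <= dims)
}

#' Crop a volume to an ROI box
#'
#' The output grid equals \code{roiSize(roi)} and the origin is shifted
#' so world coordinates of the retained voxels are unchanged.
#'
#' @param vol a [Volume3D-class] (or [BinaryMask3D-class], preserved)
#' @param roi a [RoiBox-class] lying fully inside \code{vol}
#' @return a volume of the same class as \code{vol}
#' @examples
#' v <- Volume3D(array(1:343, c(7, 7, 7)))
#' cropVolume(v, RoiBox(c(1, 2, 3), c(4, 3, 2)))
#' @export
cropVolume <- function(vol, roi) {
  d <- dim(vol@data)
  if (!roiInside(roi, d))
    stop("ROI box [", paste(roi@start, collapse = ","), "]+[",
         paste(roi@size, collapse = ","), "] exceeds volume bounds ",
         paste(d, collapse = "x"))
  s <- roi@start
  e <- s + roi@size
  out <- vol
  out@data <- vol@data[(s[1] + 1):e[1], (s[2] + 1):e[2], (s[3] + 1):e[3],
                       drop = FALSE]
  out@origin <- vol@origin + s * vol@spacing
  out
}

## Trilinear sampling of a volume at arbitrary world coordinates.
## Returns list(values, valid): out-of-domain points get `background`
## and valid = FALSE.
sampleTrilinear <- function(vol, world, background = 0) {
  d <- dim(vol@data)
  j <- worldToIndex(vol, world)
  valid <- j[, 1] >= 0 & j[, 1] <= d[1] - 1 &
           j[, 2] >= 0 & j[, 2] <= d[2] - 1 &
           j[, 3] >= 0 & j[, 3] <= d[3] - 1
  vals <- rep(background, nrow(j))
  if (any(valid)) {
    jv <- j[valid, , drop = FALSE]
    f1 <- pmin(floor(jv[, 1]), d[1] - 2); f1 <- pmax(f1, 0)
    f2 <- pmin(floor(jv[, 2]), d[2] - 2); f2 <- pmax(f2, 0)
    f3 <- pmin(floor(jv[, 3]), d[3] - 2); f3 <- pmax(f3, 0)
    w1 <- jv[, 1] - f1; w2 <- jv[, 2] - f2; w3 <- jv[, 3] - f3
    n1 <- d[1]; n12 <- d[1] * d[2]
    base <- f1 + f2 * n1 + f3 * n12 + 1
    a <- vol@data
    v000 <- a[base];             v100 <- a[base + 1]
    v010 <- a[base + n1];        v110 <- a[base + n1 + 1]
    v001 <- a[base + n12];       v101 <- a[base + n12 + 1]
    v011 <- a[base + n1 + n12];  v111 <- a[base + n1 + n12 + 1]
    vals[valid] <-
      (1 - w3) * ((1 - w2) * ((1 - w1) * v000 + w1 * v100) +
                  w2 * ((1 - w1) * v010 + w1 * v110)) +
      w3 * ((1 - w2) * ((1 - w1) * v001 + w1 * v101) +
            w2 * ((1 - w1) * v011 + w1 * v111))
  }
  list(values = vals, valid = valid)
}

refGridWorld <- function(reference) {
  d <- dim(reference@data)
  i1 <- rep.int(seq_len(d[1]) - 1L, d[2] * d[3])
  i2 <- rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3])
  i3 <- rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  cbind(reference@origin[1] + i1 * reference@spacing[1],
        reference@origin[2] + i2 * reference@spacing[2],
        reference@origin[3] + i3 * reference@spacing[3])
}

#' Resample a volume through a rigid transform
#'
#' Produces the moving volume on the reference grid: each reference voxel
#' at world position x receives the trilinearly interpolated value of
#' \code{moving} at \code{transform^{-1}(x)} (the transform maps moving
#' world coordinates into reference world coordinates). Voxels mapping
#' outside the moving domain are set to \code{background}.
#'
#' @param moving a [Volume3D-class]
#' @param transform a [RigidTransform3D-class], moving-world to
#'   reference-world
#' @param reference a [Volume3D-class] supplying the output grid
#' @param background fill value for out-of-domain voxels (default 0)
#' @return a [Volume3D-class] on the reference grid
#' @export
resampleRigid <- function(moving, transform, reference, background = 0) {
  inv <- invertTransform(transform)
  world <- applyTransform(inv, refGridWorld(reference))
  s <- sampleTrilinear(moving, world, background = background)
  Volume3D(array(s$values, dim = dim(reference@data)),
           spacing = reference@spacing, origin = reference@origin)
}
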