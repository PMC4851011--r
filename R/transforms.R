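## Rigid transform arithmetic. The map is T(p) = R (p - c) + c + t with
## R = Rz(rz) %*% Ry(ry) %*% Rx(rx), angles in degrees, p/c/t in world mm.

rotationMatrixZYX <- function(rotationDeg) {
  a <- rotationDeg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

eulerZYXFromMatrix <- function(R) {
  ry <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(ry)) > 1e-10) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {
    # gimbal lock: fold the z rotation into x
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  c(rx, ry, rz) * 180 / pi
}

#' Homogeneous matrix of a rigid transform
#'
#' Returns the 4x4 matrix M such that, in homogeneous world coordinates,
#' \code{M \%*\% c(p, 1)} equals \code{R (p - c) + c + t}. The 3x3 block
#' is orthonormal with determinant +1.
#'
#' @param transform a [RigidTransform3D-class]
#' @return 4x4 numeric matrix
#' @export
rigidMatrix <- function(transform) {
  R <- rotationMatrixZYX(transform@rotation)
  off <- transform@center + transform@translation -
    R %*% transform@center
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- off
  M
}

#' Apply a rigid transform to points
#'
#' @param transform a [RigidTransform3D-class]
#' @param points numeric vector of length 3 or an n x 3 matrix, world mm
#' @return transformed points, same shape
#' @export
applyTransform <- function(transform, points) {
  single <- is.null(dim(points))
  p <- if (single) matrix(points, 1, 3) else points
  R <- rotationMatrixZYX(transform@rotation)
  out <- sweep(p, 2, transform@center) %*% t(R)
  out <- sweep(out, 2, transform@center + transform@translation, "+")
  if (single) drop(out) else out
}

#' Invert a rigid transform
#'
#' The inverse keeps the same rotation center; composing a transform with
#' its inverse yields the identity map.
#'
#' @param transform a [RigidTransform3D-class]
#' @return a [RigidTransform3D-class]
#' @export
invertTransform <- function(transform) {
  R <- rotationMatrixZYX(transform@rotation)
  Ri <- t(R)
  RigidTransform3D(rotation = eulerZYXFromMatrix(Ri),
                   translation = as.numeric(-Ri %*% transform@translation),
                   center = transform@center)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying \code{second} first and
#' \code{first} afterwards: \code{T(p) = first(second(p))}. The result
#' uses \code{first}'s rotation center.
#'
#' @param first,second [RigidTransform3D-class] objects
#' @return a [RigidTransform3D-class]
#' @export
composeTransform <- function(first, second) {
  M <- rigidMatrix(first) %*% rigidMatrix(second)
  R <- M[1:3, 1:3]
  c0 <- first@center
  # off = c + t - R c  =>  t = off - c + R c
  t0 <- M[1:3, 4] - c0 + as.numeric(R %*% c0)
  RigidTransform3D(rotation = eulerZYXFromMatrix(R), translation = t0,
                   center = c0)
}

#' Identity transform
#'
#' @param center rotation center in world mm (irrelevant for the identity
#'   map but carried for later composition)
#' @return a [RigidTransform3D-class]
#' @export
identityTransform <- function(center = c(0, 0, 0)) {
  RigidTransform3D(center = center)
}

#' Read / write a rigid transform as JSON
#'
#' Serialized as \code{{"rotation_deg": [..], "translation_mm": [..],
#' "center_mm": [..]}}.
#'
#' @param path file path
#' @param transform a [RigidTransform3D-class]
#' @return \code{readTransformJson} returns a [RigidTransform3D-class];
#'   \code{writeTransformJson} returns \code{path} invisibly
#' @export
readTransformJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  RigidTransform3D(rotation = x$rotation_deg,
                   translation = x$translation_mm,
                   center = x$center_mm)
}

#' @rdname readTransformJson
#' @export
writeTransformJson <- function(transform, path) {
  jsonlite::write_json(list(rotation_deg = transform@rotation,
                            translation_mm = transform@translation,
                            center_mm = transform@center),
                       path, digits = I(17), auto_unbox = FALSE)
  invisible(path)
}

#' Read / write an ROI box as JSON
#'
#' Serialized as \code{{"start": [..], "size": [..]}} with 0-based start.
#'
#' @param path file path
#' @param roi a [RoiBox-class]
#' @return \code{readRoiJson} returns a [RoiBox-class];
#'   \code{writeRoiJson} returns \code{path} invisibly
#' @export
readRoiJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  RoiBox(x$start, x$size)
}

#' @rdname readRoiJson
#' @export
writeRoiJson <- function(roi, path) {
  jsonlite::write_json(list(start = roi@start, size = roi@size), path,
                       digits = I(17), auto_unbox = FALSE)
  invisible(path)
}
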