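## Multiscale Hessian-based tubular-structure enhancement.
##
## The scale-space Hessian is computed by Gaussian smoothing (separable
## convolution, kernel width scaled per axis by the voxel spacing so
## sigma is in mm) followed by central finite differences in world units
## (intensity / mm^2). Eigenvalues are obtained voxel-wise from the
## closed-form trigonometric solution for symmetric 3x3 matrices. No
## gamma-normalization is applied across scales: responses at different
## sigma are compared raw and the per-voxel maximum is kept.

reflectIndex <- function(q, n) {
  # symmetric (edge-including) reflection of out-of-range indices
  if (n == 1L) return(rep(1L, length(q)))
  period <- 2L * n
  q <- ((q - 1L) %% period) + 1L
  ifelse(q > n, period - q + 1L, q)
}

convolveAxis <- function(a, kernel, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  n <- d[axis]
  m <- prod(d[-axis])
  dim(ap) <- c(n, m)
  K <- length(kernel)
  r <- (K - 1L) %/% 2L
  pad <- ap[reflectIndex((1L - r):(n + r), n), , drop = FALSE]
  out <- matrix(0, n, m)
  for (j in seq_len(K))
    out <- out + kernel[j] * pad[j:(j + n - 1L), , drop = FALSE]
  dim(out) <- d[perm]
  aperm(out, order(perm))
}

gaussianKernel1D <- function(sigmaVox) {
  r <- max(1L, as.integer(ceiling(4 * sigmaVox)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigmaVox^2))
  k / sum(k)
}

#' Gaussian smoothing in world units
#'
#' Separable Gaussian convolution with reflect (symmetric) boundary
#' handling. \code{sigma} is in mm: the 1D kernel on each axis uses
#' \code{sigma / spacing[axis]} voxels, so anisotropic grids are smoothed
#' isotropically in world space. Constant volumes are unchanged (the
#' discrete kernel is normalized to unit sum).
#'
#' @param vol a [Volume3D-class]
#' @param sigma Gaussian standard deviation in mm, > 0
#' @return a [Volume3D-class] on the same grid
#' @export
gaussianSmooth <- function(vol, sigma) {
  if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("sigma must be a single positive number (mm)")
  out <- vol@data
  for (axis in 1:3)
    out <- convolveAxis(out, gaussianKernel1D(sigma / vol@spacing[axis]),
                        axis)
  Volume3D(out, spacing = vol@spacing, origin = vol@origin)
}

shiftClamp <- function(a, dx, dy, dz) {
  d <- dim(a)
  ix <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
  iy <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
  iz <- pmin(pmax(seq_len(d[3]) + dz, 1L), d[3])
  a[ix, iy, iz, drop = FALSE]
}

#' Scale-space Hessian field
#'
#' All six distinct second derivatives of the sigma-smoothed image, in
#' intensity/mm^2, computed by central differences on the smoothed
#' volume (edge-clamped at the boundary). The per-voxel matrix is
#' symmetric by construction.
#'
#' @param vol a [Volume3D-class] with at least 5 voxels per axis
#' @param sigma Gaussian scale in mm
#' @return named list of 3D arrays \code{xx, yy, zz, xy, xz, yz} with
#'   attributes \code{sigma} and \code{spacing}
#' @export
hessianField <- function(vol, sigma) {
  if (any(dim(vol@data) < 5L))
    stop("volume must have at least 5 voxels per axis")
  s <- gaussianSmooth(vol, sigma)@data
  h <- vol@spacing
  d2 <- function(axis) {
    dx <- c(0L, 0L, 0L); dx[axis] <- 1L
    (shiftClamp(s, dx[1], dx[2], dx[3]) - 2 * s +
       shiftClamp(s, -dx[1], -dx[2], -dx[3])) / h[axis]^2
  }
  dcross <- function(a1, a2) {
    dp <- c(0L, 0L, 0L); dp[a1] <- 1L
    dq <- c(0L, 0L, 0L); dq[a2] <- 1L
    (shiftClamp(s, dp[1] + dq[1], dp[2] + dq[2], dp[3] + dq[3]) -
       shiftClamp(s, dp[1] - dq[1], dp[2] - dq[2], dp[3] - dq[3]) -
       shiftClamp(s, dq[1] - dp[1], dq[2] - dp[2], dq[3] - dp[3]) +
       shiftClamp(s, -dp[1] - dq[1], -dp[2] - dq[2], -dp[3] - dq[3])) /
      (4 * h[a1] * h[a2])
  }
  structure(list(xx = d2(1), yy = d2(2), zz = d2(3),
                 xy = dcross(1, 2), xz = dcross(1, 3), yz = dcross(2, 3)),
            sigma = sigma, spacing = h)
}

#' Eigenvalues of a symmetric 3x3 field
#'
#' Voxel-wise eigenvalues of the Hessian, sorted \code{lambda1 >=
#' lambda2 >= lambda3}, via the closed-form trigonometric solution
#' (vectorized over voxels), plus \code{lambdaC = min(-lambda2,
#' -lambda3)}.
#'
#' @param hessian the list returned by [hessianField()]
#' @return a [HessianEigenvalues-class]
#' @export
hessianEigenvalues <- function(hessian) {
  a11 <- hessian$xx; a22 <- hessian$yy; a33 <- hessian$zz
  a12 <- hessian$xy; a13 <- hessian$xz; a23 <- hessian$yz
  q <- (a11 + a22 + a33) / 3
  p1 <- a12^2 + a13^2 + a23^2
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  deg <- p2 <= 0
  p <- sqrt(pmax(p2, .Machine$double.xmin) / 6)
  b11 <- (a11 - q) / p; b22 <- (a22 - q) / p; b33 <- (a33 - q) / p
  b12 <- a12 / p; b13 <- a13 / p; b23 <- a23 / p
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  l1[deg] <- q[deg]; l2[deg] <- q[deg]; l3[deg] <- q[deg]
  dm <- dim(a11)
  new("HessianEigenvalues",
      lambda1 = array(l1, dm), lambda2 = array(l2, dm),
      lambda3 = array(l3, dm), lambdaC = array(pmin(-l2, -l3), dm))
}

#' Single-scale Sato vesselness response
#'
#' The bright-tube enhancement filter on sorted Hessian eigenvalues:
#' zero where \code{lambdaC = min(-lambda2, -lambda3)} is zero,
#' otherwise \code{exp(-lambda1^2 / (2 (alpha lambdaC)^2)) * lambdaC}
#' with \code{alpha = alpha1} where \code{lambda1 <= 0} and
#' \code{alpha = alpha2} where \code{lambda1 > 0}. Voxels with
#' \code{lambdaC < 0} (not a bright tube: lambda2 or lambda3 positive)
#' are set to zero, so the response is non-negative everywhere.
#'
#' @param ev a [HessianEigenvalues-class]
#' @param params a [VesselnessParams-class]
#' @return 3D array of responses, same shape as the eigenvalue arrays
#' @export
satoResponse <- function(ev, params) {
  validObject(params)
  l1 <- ev@lambda1
  lc <- ev@lambdaC
  alpha <- ifelse(l1 <= 0, params@alpha1, params@alpha2)
  v <- exp(-l1^2 / (2 * (alpha * lc)^2)) * lc
  v[lc <= 0] <- 0
  array(v, dim(l1))
}

#' Multiscale vesselness image
#'
#' Computes the Sato response at each scale in \code{params@sigmas} and
#' keeps the per-voxel maximum. The output is non-negative and shares
#' the input grid geometry.
#'
#' @param vol a [Volume3D-class]
#' @param params a [VesselnessParams-class]
#' @return a [Volume3D-class] of vesselness responses
#' @examples
#' tube <- straightTube(c(4, 16, 16), c(28, 16, 16), radius = 1)
#' v <- makeTubeVolume(c(32, 32, 32), 1, list(tube))$volume
#' vi <- multiscaleVesselness(v, VesselnessParams())
#' @export
multiscaleVesselness <- function(vol, params = VesselnessParams()) {
  validObject(params)
  best <- NULL
  for (s in params@sigmas) {
    v <- satoResponse(hessianEigenvalues(hessianField(vol, s)), params)
    best <- if (is.null(best)) v else pmax(best, v)
  }
  Volume3D(array(best, dim(vol@data)), spacing = vol@spacing,
           origin = vol@origin)
}
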