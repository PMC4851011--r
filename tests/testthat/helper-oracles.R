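# Independent oracles and small fixture builders used across tests.

# dense (non-separable) Gaussian convolution with symmetric padding:
# brute-force oracle for the separable implementation
denseGaussianSmooth <- function(arr, sigmaVox) {
  r <- max(1L, as.integer(ceiling(4 * sigmaVox)))
  ax <- -r:r
  k1 <- exp(-ax^2 / (2 * sigmaVox^2))
  k1 <- k1 / sum(k1)
  k3 <- outer(outer(k1, k1), k1)
  d <- dim(arr)
  refl <- function(q, n) {
    per <- 2L * n
    q <- ((q - 1L) %% per) + 1L
    ifelse(q > n, per - q + 1L, q)
  }
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    sub <- arr[refl(i + ax, d[1]), refl(j + ax, d[2]), refl(k + ax, d[3])]
    out[i, j, k] <- sum(sub * k3)
  }
  out
}

# exhaustive between-class-variance search over the same histogram
# definition otsuThreshold uses
otsuOracle <- function(x, nbins = 256L) {
  rng <- range(x)
  edges <- seq(rng[1], rng[2], length.out = nbins + 1L)
  bin <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L),
              nbins)
  counts <- tabulate(bin, nbins)
  mids <- (edges[-1] + edges[-(nbins + 1L)]) / 2
  sb <- rep(-Inf, nbins - 1L)
  for (k in 1:(nbins - 1L)) {
    c0 <- counts[1:k]; c1 <- counts[(k + 1):nbins]
    w0 <- sum(c0); w1 <- sum(c1)
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(c0 * mids[1:k]) / w0
    mu1 <- sum(c1 * mids[(k + 1):nbins]) / w1
    sb[k] <- w0 * w1 * (mu0 - mu1)^2
  }
  # documented tie-break: the middle edge of a maximizing plateau
  cand <- which(sb >= max(sb) - 1e-9 * max(abs(max(sb)), 1))
  edges[cand[(length(cand) + 1L) %/% 2L] + 1L]
}

# brute-force all-pairs Hausdorff on world coordinates of two masks
hausdorffOracle <- function(x, y) {
  co <- function(m) {
    d <- dim(volData(m))
    v <- which(volData(m) != 0)
    i <- cbind((v - 1) %% d[1], ((v - 1) %/% d[1]) %% d[2],
               (v - 1) %/% (d[1] * d[2]))
    sweep(sweep(i, 2, voxelSpacing(m), "*"), 2, worldOrigin(m), "+")
  }
  A <- co(x); B <- co(y)
  dm <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A)))
    dm[i, ] <- sqrt(colSums((t(B) - A[i, ])^2))
  max(max(apply(dm, 1, min)), max(apply(dm, 2, min)))
}

# a reproducible noisy test volume with smooth large-scale structure
noisyVolume <- function(d = c(16, 16, 16), seed = 1, spacing = c(1, 1, 1)) {
  set.seed(seed)
  xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
  base <- outer(outer(sin(xs / 3), cos(ys / 4)), sin(zs / 5)) * 10
  Volume3D(base + array(rnorm(prod(d)), d), spacing = spacing)
}

randomMask <- function(d = c(10, 10, 10), n = 30, seed = 1,
                       spacing = c(1, 1, 1)) {
  set.seed(seed)
  a <- array(0, d)
  a[sample(prod(d), n)] <- 1
  BinaryMask3D(a, spacing = spacing)
}

# displacement discrepancy between two transforms, evaluated at a point:
# convention-free localization error in world mm
errAt <- function(tr, truth, pt) {
  sqrt(sum((applyTransform(tr, pt) - applyTransform(truth, pt))^2))
}

roiCenterPoint <- function(roi, spacing = c(1, 1, 1)) {
  (roiStart(roi) + (roiSize(roi) - 1) / 2) * spacing
}
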