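## Vessel extraction: Otsu thresholding of the vesselness image, with
## optional largest-connected-component cleanup.

#' Otsu threshold of a volume
#'
#' Builds an \code{nbins}-bin histogram over the intensity range and
#' returns the bin edge maximizing the between-class variance. The
#' threshold is intended to be applied as a strict \code{>}.
#' Deterministic; when several consecutive edges attain the maximum (an
#' empty gap between well-separated modes makes the criterion flat
#' there), the middle edge of the plateau is returned, placing the
#' threshold mid-gap.
#'
#' @param vol a [Volume3D-class] or numeric vector/array with at least
#'   two distinct values
#' @param nbins histogram bin count (default 256)
#' @return the threshold intensity (a bin edge)
#' @examples
#' otsuThreshold(c(rep(1, 3), rep(10, 3)))
#' @export
otsuThreshold <- function(vol, nbins = 256L) {
  x <- if (is(vol, "Volume3D")) as.vector(vol@data) else as.vector(vol)
  rng <- range(x)
  if (!all(is.finite(rng)) || rng[1] == rng[2])
    stop("degenerate input: volume has fewer than 2 distinct values")
  nbins <- max(2L, as.integer(nbins))
  edges <- seq(rng[1], rng[2], length.out = nbins + 1L)
  bin <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L),
              nbins)
  counts <- tabulate(bin, nbins)
  mids <- (edges[-1] + edges[-(nbins + 1L)]) / 2
  w0 <- cumsum(counts)
  w1 <- sum(counts) - w0
  m0 <- cumsum(counts * mids)
  mu0 <- m0 / w0
  mu1 <- (m0[nbins] - m0) / w1
  sb <- w0 * w1 * (mu0 - mu1)^2
  sb[w0 == 0 | w1 == 0] <- -Inf
  sb <- sb[-nbins]  # split after bin k; the last split is empty
  cand <- which(sb >= max(sb) - 1e-9 * max(abs(max(sb)), 1))
  k <- cand[(length(cand) + 1L) %/% 2L]
  edges[k + 1L]
}

#' Segment vessels by multiscale vesselness plus Otsu thresholding
#'
#' Computes the multiscale vesselness image of \code{vol} (intended to be
#' a limited region of interest, not a whole head volume), thresholds it
#' with [otsuThreshold()] applied as strict \code{>}, and optionally
#' keeps only the largest 26-connected component to suppress speckle
#' islands.
#'
#' @param vol a [Volume3D-class] (typically a cropped ROI / search region)
#' @param params a [VesselnessParams-class]
#' @param nbins Otsu histogram bins (default 256)
#' @param keepLargest if TRUE, retain only the largest 26-connected
#'   foreground component
#' @return a [VesselSegmentation-class] holding the mask, the vesselness
#'   image and the threshold
#' @examples
#' tube <- straightTube(c(4, 16, 16), c(28, 16, 16), radius = 1)
#' v <- makeTubeVolume(c(32, 32, 32), 1, list(tube))$volume
#' seg <- segmentVessels(v)
#' sum(volData(seg@mask))
#' @export
segmentVessels <- function(vol, params = VesselnessParams(), nbins = 256L,
                           keepLargest = FALSE) {
  vi <- multiscaleVesselness(vol, params)
  r <- range(vi@data)
  if (r[1] == r[2])
    stop("degenerate input: vesselness image is constant (no structure)")
  thr <- otsuThreshold(vi, nbins)
  mask <- BinaryMask3D(vi@data > thr, spacing = vol@spacing,
                       origin = vol@origin)
  if (keepLargest && sum(mask@data) > 0)
    mask <- largestComponent(mask)
  new("VesselSegmentation", mask = mask, vesselness = vi, threshold = thr)
}

## Label 26-connected components of a mask; returns integer array
## (0 = background) built from an igraph decomposition of the
## foreground-voxel adjacency graph.
labelComponents26 <- function(mask) {
  d <- dim(mask@data)
  fg <- which(mask@data != 0)
  lab <- array(0L, d)
  if (length(fg) == 0L) return(lab)
  id <- integer(prod(d))
  id[fg] <- seq_along(fg)
  # voxel coordinates (1-based) of foreground
  i1 <- ((fg - 1L) %% d[1]) + 1L
  i2 <- (((fg - 1L) %/% d[1]) %% d[2]) + 1L
  i3 <- ((fg - 1L) %/% (d[1] * d[2])) + 1L
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[offs$dx != 0 | offs$dy != 0 | offs$dz != 0, ]
  # half of the 26 neighbors (positive lexicographic direction) suffices
  offs <- offs[offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
               (offs$dz == 0 & offs$dy == 0 & offs$dx > 0), ]
  edges <- NULL
  for (r in seq_len(nrow(offs))) {
    j1 <- i1 + offs$dx[r]; j2 <- i2 + offs$dy[r]; j3 <- i3 + offs$dz[r]
    ok <- j1 >= 1L & j1 <= d[1] & j2 >= 1L & j2 <= d[2] &
          j3 >= 1L & j3 <= d[3]
    nb <- (j3[ok] - 1L) * d[1] * d[2] + (j2[ok] - 1L) * d[1] + j1[ok]
    hit <- id[nb] > 0L
    if (any(hit))
      edges <- rbind(edges, cbind(id[fg[ok]][hit], id[nb][hit]))
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  lab[fg] <- comp
  lab
}

#' Keep the largest 26-connected component
#'
#' Ties on size are broken by the component whose minimal voxel index is
#' lexicographically smallest in (x, y, z).
#'
#' @param mask a non-empty [BinaryMask3D-class]
#' @return a [BinaryMask3D-class] with a single component
#' @export
largestComponent <- function(mask) {
  if (sum(mask@data) == 0)
    stop("empty mask: no components to select")
  lab <- labelComponents26(mask)
  fg <- which(lab > 0L)
  sizes <- tabulate(lab[fg])
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    d <- dim(mask@data)
    base <- max(d) + 1
    key <- vapply(best, function(cc) {
      v <- which(lab == cc)
      x <- ((v - 1L) %% d[1])
      y <- (((v - 1L) %/% d[1]) %% d[2])
      z <- ((v - 1L) %/% (d[1] * d[2]))
      o <- order(x, y, z)[1]
      x[o] * base^2 + y[o] * base + z[o]
    }, numeric(1))
    best <- best[which.min(key)]
  }
  BinaryMask3D(lab == best, spacing = mask@spacing, origin = mask@origin)
}
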