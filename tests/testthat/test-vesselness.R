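test_that("Gaussian smoothing preserves constants and normalization", {
  v <- Volume3D(array(7, c(10, 10, 10)))
  s <- gaussianSmooth(v, 1.5)
  expect_lt(max(abs(volData(s) - 7)), 1e-6)
  expect_error(gaussianSmooth(v, 0), "positive")
  expect_error(gaussianSmooth(v, -1), "positive")
  # interior impulse: total intensity conserved by the normalized kernel
  imp <- Volume3D(array(0, c(15, 15, 15)))
  imp@data[8, 8, 8] <- 100
  sm <- gaussianSmooth(imp, 1)
  expect_lt(abs(sum(volData(sm)) - 100), 1e-4 * 100)
})

test_that("separable smoothing matches a dense convolution oracle", {
  set.seed(11)
  arr <- array(rnorm(9^3), c(9, 9, 9))
  got <- gaussianSmooth(Volume3D(arr), 1)
  expect_equal(volData(got), denseGaussianSmooth(arr, 1),
               tolerance = 1e-10)
  # centered impulse: center value equals the discretized G(0) weight
  imp <- array(0, c(9, 9, 9)); imp[5, 5, 5] <- 1
  smi <- gaussianSmooth(Volume3D(imp), 1)
  r <- 4L; ax <- -r:r
  k1 <- exp(-ax^2 / 2); k1 <- k1 / sum(k1)
  expect_equal(volData(smi)[5, 5, 5], k1[r + 1]^3, tolerance = 1e-12)
})

test_that("smoothing works in world units on anisotropic grids", {
  # same world-space field sampled at two grids must smooth consistently
  imp <- array(0, c(21, 9, 9)); imp[11, 5, 5] <- 1
  fine <- gaussianSmooth(Volume3D(imp, spacing = c(0.5, 1, 1)), 1)
  along <- volData(fine)[11 + 2, 5, 5] / volData(fine)[11, 5, 5]
  # 2 voxels at 0.5 mm = 1 mm: ratio should match exp(-1/2) closely
  expect_equal(along, exp(-1 / 2), tolerance = 0.01)
})

test_that("Hessian of polynomial fields matches analytic derivatives", {
  d <- c(11, 11, 11)
  xs <- 0:10
  X <- array(rep(xs, times = 121), d)
  h <- hessianField(Volume3D(X^2), 1)
  expect_equal(h$xx[6, 6, 6], 2, tolerance = 1e-8)
  expect_lt(max(abs(c(h$xy[6, 6, 6], h$xz[6, 6, 6], h$yz[6, 6, 6],
                      h$yy[6, 6, 6], h$zz[6, 6, 6]))), 1e-8)
  hxy <- hessianField(Volume3D(outer(outer(xs, xs), rep(1, 11))), 0.8)
  expect_equal(hxy$xy[6, 6, 6], 1, tolerance = 1e-8)
  hc <- hessianField(Volume3D(array(4, d)), 1)
  expect_true(all(abs(unlist(hc)) < 1e-10))
  expect_error(hessianField(Volume3D(array(0, c(4, 8, 8))), 1),
               "at least 5")
})

test_that("Hessian derivatives respect voxel spacing", {
  # grid large enough that the smoothing kernel stays off the boundary
  xs <- (0:16) * 0.5  # world coordinate with 0.5 mm spacing
  X <- array(rep(xs, times = 17 * 17), c(17, 17, 17))
  h <- hessianField(Volume3D(X^2, spacing = c(0.5, 1, 1)), 0.6)
  expect_equal(h$xx[9, 9, 9], 2, tolerance = 1e-6)
})

test_that("closed-form eigenvalues match the dense eigensolver", {
  set.seed(1)
  for (i in 1:100) {
    A <- matrix(rnorm(9), 3); A <- (A + t(A)) / 2
    hf <- list(xx = array(A[1, 1], c(1, 1, 1)),
               yy = array(A[2, 2], c(1, 1, 1)),
               zz = array(A[3, 3], c(1, 1, 1)),
               xy = array(A[1, 2], c(1, 1, 1)),
               xz = array(A[1, 3], c(1, 1, 1)),
               yz = array(A[2, 3], c(1, 1, 1)))
    ev <- hessianEigenvalues(hf)
    ref <- sort(eigen(A, symmetric = TRUE, only.values = TRUE)$values,
                decreasing = TRUE)
    got <- c(ev@lambda1[1], ev@lambda2[1], ev@lambda3[1])
    expect_equal(got, ref, tolerance = 1e-9)
    expect_true(got[1] >= got[2] && got[2] >= got[3])
    expect_equal(ev@lambdaC[1], min(-got[2], -got[3]), tolerance = 1e-9)
  }
})

satoOne <- function(l1, l2, l3, params = VesselnessParams()) {
  ev <- new("HessianEigenvalues",
            lambda1 = array(l1, c(1, 1, 1)),
            lambda2 = array(l2, c(1, 1, 1)),
            lambda3 = array(l3, c(1, 1, 1)),
            lambdaC = array(min(-l2, -l3), c(1, 1, 1)))
  satoResponse(ev, params)[1]
}

test_that("tube-filter response follows its case split", {
  expect_equal(satoOne(0, 0, 0), 0)
  # bright-line profile: lambda1 = 0, lambda2 = lambda3 = -2
  expect_equal(satoOne(0, -2, -2), 2, tolerance = 1e-12)
  # bulging profile: lambda1 > 0 branch uses alpha2 = 2
  expect_equal(satoOne(1, -2, -2), exp(-1 / (2 * 16)) * 2,
               tolerance = 1e-12)
  # lambda1 < 0 branch uses alpha1 = 0.5
  expect_equal(satoOne(-1, -2, -2), exp(-1 / (2 * 1)) * 2,
               tolerance = 1e-12)
  # not a bright tube (lambdaC < 0): clamped to zero
  expect_equal(satoOne(2, 2, -1), 0)
})

test_that("multiscale vesselness enhances tubes over background", {
  expect_true(all(volData(multiscaleVesselness(
    Volume3D(array(3, c(12, 12, 12))))) == 0))
  tube <- straightTube(c(4, 16, 16), c(28, 16, 16), radius = 1,
                       peak = 100)
  v <- makeTubeVolume(c(32, 32, 32), 1, list(tube), background = 5)$volume
  vi <- multiscaleVesselness(v)
  expect_gt(mean(volData(vi)[8:24, 17, 17]),
            mean(volData(vi)[8:24, 28, 28]) + 1)
  expect_true(all(volData(vi) >= 0))
  # a single-scale list reduces to the per-scale response
  p1 <- VesselnessParams(sigmas = 1)
  one <- multiscaleVesselness(v, p1)
  direct <- satoResponse(hessianEigenvalues(hessianField(v, 1)), p1)
  expect_equal(volData(one), direct, tolerance = 1e-12)
})

test_that("vesselness is shift-invariant and scales linearly in intensity", {
  tube <- straightTube(c(4, 16, 16), c(28, 16, 16), radius = 1,
                       peak = 100)
  v <- makeTubeVolume(c(32, 32, 32), 1, list(tube), background = 0)$volume
  vi <- multiscaleVesselness(v)
  shifted <- Volume3D(volData(v) + 55, spacing = voxelSpacing(v))
  expect_equal(volData(multiscaleVesselness(shifted)), volData(vi),
               tolerance = 1e-6)
  scaled <- Volume3D(volData(v) * 3, spacing = voxelSpacing(v))
  expect_equal(volData(multiscaleVesselness(scaled)), 3 * volData(vi),
               tolerance = 1e-6)
})

test_that("relative response at coarse scales grows with tube radius", {
  # without scale normalization the raw response always decays with
  # sigma, so the absolute argmax cannot track the radius; what the
  # filter does guarantee is that thicker tubes retain relatively more
  # response at coarser scales
  ratio <- sapply(c(0.5, 1, 2), function(r) {
    tb <- straightTube(c(6, 20, 20), c(34, 20, 20), radius = r,
                       peak = 100)
    vv <- makeTubeVolume(c(40, 40, 40), 1, list(tb))$volume
    resp <- sapply(c(0.5, 2), function(s) {
      mean(satoResponse(hessianEigenvalues(hessianField(vv, s)),
                        VesselnessParams())[10:30, 21, 21])
    })
    resp[2] / resp[1]
  })
  expect_true(all(diff(ratio) > 0))
})
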