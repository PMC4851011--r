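test_that("volumes round-trip through all supported formats", {
  v <- Volume3D(array(rnorm(5 * 6 * 7), c(5, 6, 7)),
                spacing = c(0.422, 0.422, 1.0), origin = c(3, -2, 1))
  for (ext in c(".nii.gz", ".nii", ".mha", ".mhd")) {
    f <- withr::local_tempfile(fileext = ext)
    writeVolume(v, f)
    v2 <- readVolume(f)
    expect_equal(volData(v2), volData(v), tolerance = 1e-12, info = ext)
    # NIfTI stores pixdim as float32; MetaImage headers are exact
    expect_equal(voxelSpacing(v2), voxelSpacing(v), tolerance = 1e-6,
                 info = ext)
    expect_equal(worldOrigin(v2), worldOrigin(v), tolerance = 1e-5,
                 info = ext)
  }
})

test_that("zero volume written and re-read is identical", {
  v <- Volume3D(array(0, c(5, 5, 5)))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolume(v, f)
  v2 <- readVolume(f)
  expect_identical(dim(volData(v2)), dim(volData(v)))
  expect_true(all(volData(v2) == 0))
  expect_equal(voxelSpacing(v2), c(1, 1, 1))
})

test_that("masks round-trip as 8-bit volumes", {
  m <- randomMask(c(6, 6, 6), n = 20, seed = 4)
  for (ext in c(".nii.gz", ".mha")) {
    f <- withr::local_tempfile(fileext = ext)
    writeVolume(m, f)
    expect_equal(volData(readVolume(f)), volData(m), info = ext)
  }
})

test_that("reader rejects non-3D images and unknown formats", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(matrix(1:20, 4, 5))
  RNifti::writeNifti(img, f)
  expect_error(readVolume(f), "3D")
  expect_error(readVolume(tempfile(fileext = ".nii")), "not found")
  g <- withr::local_tempfile(fileext = ".png")
  writeLines("x", g)
  expect_error(readVolume(g), "unsupported")
  expect_error(writeVolume(Volume3D(array(0, c(2, 2, 2))),
                           tempfile(fileext = ".png")), "unsupported")
})

test_that("cropping preserves world coordinates and data layout", {
  v <- Volume3D(array(seq_len(60 * 40 * 20), c(60, 40, 20)),
                spacing = c(1, 1, 2), origin = c(5, 5, 5))
  roi <- RoiBox(c(4, 7, 6), c(50, 29, 8))
  cv <- cropVolume(v, roi)
  expect_identical(dim(volData(cv)), c(50L, 29L, 8L))
  expect_equal(volData(cv)[1, 1, 1], volData(v)[5, 8, 7])
  expect_equal(worldOrigin(cv), c(5, 5, 5) + c(4, 7, 6) * c(1, 1, 2))
  # full-volume crop is the identity
  full <- cropVolume(v, RoiBox(c(0, 0, 0), dim(volData(v))))
  expect_equal(volData(full), volData(v))
  expect_error(cropVolume(v, RoiBox(c(11, 12, 13), c(50, 29, 8))),
               "bounds")
})

test_that("nested crops compose like a single crop", {
  v <- noisyVolume(c(20, 20, 20), seed = 2)
  outer <- RoiBox(c(2, 3, 4), c(14, 12, 10))
  inner <- RoiBox(c(3, 2, 1), c(6, 5, 4))
  twice <- cropVolume(cropVolume(v, outer), inner)
  once <- cropVolume(v, RoiBox(roiStart(outer) + roiStart(inner),
                               roiSize(inner)))
  expect_equal(volData(twice), volData(once))
  expect_equal(worldOrigin(twice), worldOrigin(once))
})

test_that("rigid transforms satisfy group identities", {
  t1 <- RigidTransform3D(rotation = c(3, -4, 5), translation = c(1, 2, -3),
                         center = c(10, 10, 10))
  id <- composeTransform(t1, invertTransform(t1))
  expect_lt(max(abs(id@rotation)), 1e-9)
  expect_lt(max(abs(id@translation)), 1e-9)
  R <- rigidMatrix(t1)[1:3, 1:3]
  expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-9)
  expect_equal(det(R), 1, tolerance = 1e-9)
  # composition matches matrix product on points
  t2 <- RigidTransform3D(rotation = c(-1, 2, 7), translation = c(0.5, 0, 1))
  p <- matrix(rnorm(30), 10, 3)
  expect_equal(applyTransform(composeTransform(t1, t2), p),
               applyTransform(t1, applyTransform(t2, p)),
               tolerance = 1e-10)
})

test_that("ROI boxes and transforms serialize to JSON and back", {
  roi <- RoiBox(c(10, 5, 0), c(50, 29, 8))
  f <- withr::local_tempfile(fileext = ".json")
  writeRoiJson(roi, f)
  roi2 <- readRoiJson(f)
  expect_identical(roiStart(roi2), roiStart(roi))
  expect_identical(roiSize(roi2), roiSize(roi))
  tr <- RigidTransform3D(c(1.5, -2, 0.25), c(3.125, 0, -1), c(16, 16, 8))
  g <- withr::local_tempfile(fileext = ".json")
  writeTransformJson(tr, g)
  tr2 <- readTransformJson(g)
  expect_equal(tr2@rotation, tr@rotation)
  expect_equal(tr2@translation, tr@translation)
  expect_equal(tr2@center, tr@center)
})

test_that("rigid resampling is exact for identity and integer shifts", {
  v <- noisyVolume(c(9, 9, 9), seed = 3, spacing = c(0.5, 0.5, 1))
  same <- resampleRigid(v, identityTransform(), v)
  expect_equal(volData(same), volData(v), tolerance = 1e-12)
  sh <- resampleRigid(v, RigidTransform3D(translation = c(0.5, 0, 0)), v)
  expect_equal(volData(sh)[2:9, , ], volData(v)[1:8, , ],
               tolerance = 1e-12)
  expect_true(all(volData(sh)[1, , ] == 0))
})

test_that("half-voxel translation splits an impulse by trilinear weights", {
  imp <- Volume3D(array(0, c(9, 9, 9)))
  imp@data[5, 5, 5] <- 2
  hs <- resampleRigid(imp, RigidTransform3D(translation = c(0.5, 0, 0)),
                      imp)
  expect_equal(volData(hs)[5, 5, 5], 1)
  expect_equal(volData(hs)[6, 5, 5], 1)
  expect_equal(sum(volData(hs)), 2)
})

test_that("resampling forth and back reproduces the interior", {
  # a smooth field: trilinear interpolation error scales with the local
  # curvature, so the contract is stated for structures above the voxel
  # scale
  tube <- straightTube(c(5, 12, 12), c(20, 13, 11), radius = 1.5,
                       peak = 100)
  raw <- makeTubeVolume(c(24, 24, 24), 1, list(tube),
                        background = 10)$volume
  v <- gaussianSmooth(raw, 3)
  tr <- RigidTransform3D(rotation = c(0.25, -0.15, 0.2),
                         translation = c(0.15, -0.1, 0.05),
                         center = c(12, 12, 12))
  back <- resampleRigid(resampleRigid(v, tr, v), invertTransform(tr), v)
  core <- 5:20
  dyn <- diff(range(volData(v)))
  expect_lt(max(abs(volData(back)[core, core, core] -
                      volData(v)[core, core, core])), 0.02 * dyn)
})

test_that("volume and box validity checks reject malformed objects", {
  expect_error(Volume3D(array(0, c(2, 2, 2)), spacing = c(1, -1, 1)),
               "spacing")
  expect_error(Volume3D(array(0, c(2, 2))), "3D")
  expect_error(RoiBox(c(0, 0, 0), c(0, 1, 1)), "size")
  expect_error(VesselnessParams(sigmas = c(2, 1)), "increasing")
  expect_error(VesselnessParams(alpha1 = 3, alpha2 = 2), "alpha")
})
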