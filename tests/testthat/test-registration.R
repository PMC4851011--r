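test_that("the search region doubles the ROI volume around its center", {
  target <- Volume3D(array(0, c(100, 100, 100)))
  roi <- RoiBox(c(40, 40, 40), c(20, 20, 20))
  sr <- buildSearchRegion(roi, target)
  expect_identical(roiSize(sr@box), c(25L, 25L, 25L))
  ratio <- prod(roiSize(sr@box)) / prod(roiSize(roi))
  expect_gte(ratio, 1.95)
  expect_lte(ratio, 2.05)
  expect_lte(max(abs(roiCenter(sr@box) - roiCenter(roi))), 0.5)
  expect_false(sr@clipped)
  # anisotropic ROI
  roi2 <- RoiBox(c(10, 20, 30), c(50, 29, 8))
  sr2 <- buildSearchRegion(roi2, target)
  expect_identical(roiSize(sr2@box),
                   as.integer(round(c(50, 29, 8) * 2^(1 / 3))))
})

test_that("search regions clip at borders and handle tiny ROIs", {
  target <- Volume3D(array(0, c(30, 30, 30)))
  expect_warning(sr <- buildSearchRegion(RoiBox(c(0, 12, 12),
                                                c(8, 8, 8)), target),
                 "clipped")
  expect_true(sr@clipped)
  expect_true(all(roiStart(sr@box) >= 0))
  expect_true(all(roiStart(sr@box) + roiSize(sr@box) <= c(30, 30, 30)))
  tiny <- buildSearchRegion(RoiBox(c(10, 10, 10), c(1, 1, 1)), target)
  expect_true(all(roiSize(tiny@box) >= 1))
  expect_error(buildSearchRegion(RoiBox(c(40, 10, 10), c(4, 4, 4)),
                                 target), "outside")
})

test_that("the translation scan equals a brute-force offset evaluation", {
  v <- noisyVolume(c(24, 24, 24), seed = 20)
  pattern <- cropVolume(v, RoiBox(c(8, 8, 8), c(8, 8, 8)))
  search <- cropVolume(v, RoiBox(c(4, 4, 4), c(16, 16, 16)))
  for (nm in c("NCC", "NMI", "NGF")) {
    m <- similarityMeasure(nm)
    reg <- registerRigid(pattern, search, m, refine = FALSE,
                         maxExhaustive = 6000L)
    tab <- reg@scan
    # independent brute force over the 9x9x9 fully-inside offset grid,
    # replaying the padded-overlay objective directly from public ops
    for (d in list(c(0, 0, 0), c(4, 4, 4), c(8, 8, 8), c(1, 5, 2),
                   c(6, 0, 7), c(3, 3, 3))) {
      sub <- volData(search)[(d[1] + 1):(d[1] + 8),
                             (d[2] + 1):(d[2] + 8),
                             (d[3] + 1):(d[3] + 8)]
      ref <- switch(nm,
        NCC = ncc(volData(pattern), sub),
        NMI = nmi(volData(pattern), sub, 32),
        NGF = ngfDistance(Volume3D(volData(pattern)), Volume3D(sub),
                          epsilon = 0.01 * diff(range(volData(pattern)))))
      # the scan offset pairs pattern voxel i with search voxel i + d,
      # exactly the correspondence of the cropped sub-box
      row <- tab[tab$dx == d[1] & tab$dy == d[2] & tab$dz == d[3], ]
      expect_equal(nrow(row) >= 1, TRUE)
      expect_equal(row$score[1], ref, tolerance = 1e-9,
                   info = paste(nm, paste(d, collapse = ",")))
    }
    # the self-position (pattern cut at search offset (4,4,4), i.e. the
    # same world position) must win: world translation is zero
    expect_equal(reg@transform@rotation, c(0, 0, 0))
    expect_equal(reg@transform@translation, c(0, 0, 0),
                 tolerance = 1e-12)
  }
})

test_that("a noise-free embedded pattern is recovered exactly", {
  # smooth structured volume: every measure should have a basin around
  # the exact-match offset
  v <- gaussianSmooth(noisyVolume(c(32, 32, 32), seed = 21), 1.2)
  search <- cropVolume(v, RoiBox(c(2, 2, 2), c(26, 26, 26)))
  pattern <- cropVolume(v, RoiBox(c(10, 12, 9), c(10, 10, 10)))
  for (nm in c("NCC", "NMI", "NGF")) {
    reg <- registerRigid(pattern, search, similarityMeasure(nm))
    # truth: identity map (pattern cut from the same world position)
    ctr <- worldOrigin(pattern) + 4.5
    err <- errAt(reg@transform, identityTransform(), ctr)
    expect_lt(err, 0.5, label = paste(nm, "translation error"))
    expect_lt(max(abs(reg@transform@rotation)), 1,
              label = paste(nm, "rotation error"))
  }
})

test_that("a speckled tube shifted by (3,2,1) voxels is recovered", {
  tube <- straightTube(c(6, 16, 14), c(26, 15, 18), radius = 1, peak = 80)
  made <- makeTubeVolume(c(32, 32, 32), 1, list(tube), background = 20)
  fixed <- addSpeckle(made$volume, 0.25, seed = 7)
  shifted <- arcShift <- tube
  arcShift@centerline <- sweep(tube@centerline, 2, c(3, 2, 1), "+")
  made2 <- makeTubeVolume(c(32, 32, 32), 1, list(arcShift),
                          background = 20)
  moving <- addSpeckle(made2$volume, 0.25, seed = 8)
  pattern <- cropVolume(fixed, RoiBox(c(3, 10, 10), c(26, 12, 12)))
  # register the representations the pipeline uses: vesselness images
  # restricted to their segmented support
  segP <- segmentVessels(pattern, keepLargest = TRUE)
  segS <- segmentVessels(moving)
  reg <- registerRigid(
    Volume3D(volData(segP@vesselness) * volData(segP@mask),
             origin = worldOrigin(pattern)),
    Volume3D(volData(segS@vesselness) * volData(segS@mask)),
    similarityMeasure("NGF"))
  ctr <- worldOrigin(pattern) + (c(26, 12, 12) - 1) / 2
  err <- errAt(reg@transform,
               RigidTransform3D(translation = c(3, 2, 1)), ctr)
  expect_lt(err, 1)
})

test_that("registration scores are reproducible and monotone", {
  v <- noisyVolume(c(28, 28, 28), seed = 22)
  pattern <- cropVolume(v, RoiBox(c(9, 9, 9), c(9, 9, 9)))
  search <- cropVolume(v, RoiBox(c(5, 5, 5), c(17, 17, 17)))
  for (nm in c("NCC", "NGF")) {
    m <- similarityMeasure(nm)
    reg <- registerRigid(pattern, search, m)
    # re-evaluation reproduces the reported score
    expect_equal(similarityAt(pattern, search, m, reg@transform),
                 reg@score, tolerance = 1e-9)
    # refinement never degrades the scan optimum
    if (higherIsBetter(m))
      expect_gte(reg@trace["refined"] + 1e-12, reg@trace["scan"])
    else
      expect_lte(reg@trace["refined"] - 1e-12, reg@trace["scan"])
    # determinism: identical inputs give identical results
    reg2 <- registerRigid(pattern, search, m)
    expect_identical(reg2@transform@translation,
                     reg@transform@translation)
    expect_identical(reg2@score, reg@score)
  }
})

test_that("degenerate registration inputs are rejected", {
  search <- noisyVolume(c(16, 16, 16), seed = 23)
  flat <- Volume3D(array(1, c(8, 8, 8)))
  expect_error(registerRigid(flat, search, similarityMeasure("NCC")),
               "degenerate")
  big <- noisyVolume(c(20, 20, 20), seed = 24)
  expect_error(registerRigid(big, search, similarityMeasure("NCC")),
               "exceed")
})

test_that("identifyPattern locates a displaced vessel across modalities", {
  set <- makePhantomSet(seed = 3)
  p0 <- roiCenterPoint(set@roi)
  res <- identifyPattern(set@ct1mr, set@roi, set@iceusStart,
                         similarityMeasure("NGF"))
  expect_lt(errAt(res@transform, set@toStart, p0), 1)
  # located box center within 1 voxel of the truth-displaced ROI center
  truthCtr <- applyTransform(set@toStart, p0)
  boxCtr <- roiCenterPoint(res@locatedBox)
  expect_lt(sqrt(sum((boxCtr - truthCtr)^2)), 1.5)
  expect_equal(res@measure, "NGF")
  expect_identical(roiSize(res@locatedBox), roiSize(set@roi))
})

test_that("identifying a pattern in its own volume returns the identity", {
  set <- makePhantomSet(seed = 5,
                        config = list(translationStart = c(0, 0, 0),
                                      rotationStart = c(0, 0, 0)))
  res <- identifyPattern(set@ct1mr, set@roi, set@ct1mr,
                         similarityMeasure("NCC"))
  p0 <- roiCenterPoint(set@roi)
  expect_lt(errAt(res@transform, identityTransform(), p0), 0.5)
  expect_lte(max(abs(roiStart(res@locatedBox) - roiStart(set@roi))), 1)
})

test_that("NGF resists a straight decoy next to the curved vessel", {
  set <- makePhantomSet(seed = 301, config = list(decoy = TRUE))
  p0 <- roiCenterPoint(set@roi)
  res <- identifyPattern(set@ct1mr, set@roi, set@iceusStart,
                         similarityMeasure("NGF"))
  expect_lt(errAt(res@transform, set@toStart, p0), 2)
})

test_that("a supplied initializer is folded into the optimization", {
  v <- gaussianSmooth(noisyVolume(c(28, 28, 28), seed = 9), 1)
  search <- cropVolume(v, RoiBox(c(2, 2, 2), c(24, 24, 24)))
  pattern <- cropVolume(v, RoiBox(c(8, 9, 10), c(9, 9, 9)))
  init <- RigidTransform3D(translation = c(0.4, -0.3, 0.2),
                           center = worldOrigin(pattern) + 4)
  reg <- registerRigid(pattern, search, similarityMeasure("NCC"),
                       init = init)
  expect_lt(errAt(reg@transform, identityTransform(),
                  worldOrigin(pattern) + 4), 0.5)
  expect_equal(reg@score, 1, tolerance = 1e-6)
})
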