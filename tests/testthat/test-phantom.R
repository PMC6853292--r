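test_that("sphere phantoms carry exact closed-form surface and volume", {
  s <- makeSphere(1)
  expect_equal(svRatio(s), 3)
  expect_equal(analyticVolume(makeSphere(2)), 33.510, tolerance = 1e-4)
  expect_equal(analyticSurface(makeSphere(2)), 4 * pi * 4)
  expect_error(makeSphere(0), "invalid parameter")
  expect_error(makeSphere(-1), "invalid parameter")
})

test_that("capsule degenerates to a sphere and approaches the cylinder limit", {
  r <- 0.7
  expect_equal(analyticSurface(makeCapsule(r, 0)), analyticSurface(makeSphere(r)))
  expect_equal(analyticVolume(makeCapsule(r, 0)), analyticVolume(makeSphere(r)))
  # long-cylinder limit: S/V -> 2/r within 1% for L >= 200 r
  expect_equal(svRatio(makeCapsule(0.5, 100)), 4, tolerance = 0.01)
  # the reported penetrating-group S/V corresponds to a thin tube of
  # radius 2/3.32 = 0.6024 in the infinite-cylinder limit
  expect_equal(svRatio(makeCapsule(0.6024, 5000)), 3.32, tolerance = 0.005)
  expect_error(makeCapsule(0.5, -1), "invalid parameter")
  expect_error(makeCapsule(-0.5, 1), "invalid parameter")
})

test_that("tube-with-bulb matches its degenerate cases and a profile oracle", {
  # bulb radius equal to the shaft radius: exactly a capsule
  tb <- makeTubeWithBulb(0.4, 3, 0.4)
  cp <- makeCapsule(0.4, 3)
  expect_equal(analyticSurface(tb), analyticSurface(cp), tolerance = 1e-9)
  expect_equal(analyticVolume(tb), analyticVolume(cp), tolerance = 1e-9)
  # dense profile-revolution oracle on the swollen fusing geometry
  tb2 <- makeTubeWithBulb(0.3, 5, 2)
  orc <- tubeProfileOracle(0.3, 5, 2)
  expect_equal(analyticSurface(tb2), orc$S, tolerance = 0.005)
  expect_equal(analyticVolume(tb2), orc$V, tolerance = 0.005)
  # bulb dominating: S/V tends to the sphere value 3/R
  big <- makeTubeWithBulb(0.1, 1, 10)
  expect_equal(svRatio(big), 3 / 10, tolerance = 1e-9)
  expect_error(makeTubeWithBulb(0.5, 3, 0.3), "invalid parameter")
  # partial-overlap geometry is rejected, not silently mis-measured
  expect_error(makeTubeWithBulb(0.3, 2, 2.1), "unsupported geometry")
})

test_that("radius calibration inverts the closed-form S/V in every family", {
  expect_equal(calibrateRadiusForSV(3, "sphere"), 1, tolerance = 1e-7)
  # the fusing-group mean as a sphere: r = 3/1.39
  expect_equal(calibrateRadiusForSV(1.39, "sphere"), 2.1583, tolerance = 1e-4)
  r <- calibrateRadiusForSV(3.32, "capsule", list(L = 50))
  expect_equal(svRatio(makeCapsule(r, 50)), 3.32, tolerance = 1e-7)
  R <- calibrateRadiusForSV(1.39, "tube_with_bulb",
                            list(rShaft = 0.3, L = 5))
  expect_equal(svRatio(makeTubeWithBulb(0.3, 5, R)), 1.39, tolerance = 1e-7)
  expect_error(calibrateRadiusForSV(-1, "sphere"), "invalid parameter")
  expect_error(
    calibrateRadiusForSV(0.1, "tube_with_bulb", list(rShaft = 0.3, L = 2)),
    "no solution")
  expect_error(
    calibrateRadiusForSV(100, "tube_with_bulb", list(rShaft = 0.3, L = 2)),
    "no solution")
})

test_that("voxelization recovers analytic volume and is deterministic", {
  sc <- sceneSpec(list(makeSphere(0.5, c(0.7, 0.7, 0.7))), 1L,
                  bounds = c(0, 1.4, 0, 1.4, 0, 1.4))
  st <- voxelize(sc, rep(0.5 / 100, 3), roles = "axon_penetrating")
  expect_equal(volumeFromLabels(st, 1L), analyticVolume(makeSphere(0.5)),
               tolerance = 0.01)
  st2 <- voxelize(sc, rep(0.5 / 100, 3), roles = "axon_penetrating")
  expect_identical(stackData(st), stackData(st2))
  # coarser sampling: 3% at r/50
  st3 <- voxelize(sc, rep(0.5 / 50, 3))
  expect_equal(volumeFromLabels(st3, 1L), analyticVolume(makeSphere(0.5)),
               tolerance = 0.03)
})

test_that("a phantom outside the bounds rasterizes to an all-background stack", {
  expect_warning(
    sc <- sceneSpec(list(makeSphere(0.3, c(5, 5, 5))), 1L,
                    bounds = c(0, 1, 0, 1, 0, 1)),
    "outside")
  st <- voxelize(sc, c(0.05, 0.05, 0.1))
  expect_true(all(stackData(st) == 0L))
  expect_length(labelLegend(st), 0L)
})

test_that("undersampling relative to the smallest radius warns", {
  sc <- sceneSpec(list(makeSphere(0.04, c(0.5, 0.5, 0.5))), 1L,
                  bounds = c(0, 1, 0, 1, 0, 1))
  expect_warning(voxelize(sc, c(0.05, 0.05, 0.05)), "undersamples")
})

test_that("cohort ground truth hits the calibration targets", {
  coh <- generateCohort(nPen = 3, nFus = 2, cv = 0, seed = 5)
  expect_equal(coh$truth$sv_true[coh$truth$phenotype == "penetrating"],
               rep(3.32, 3), tolerance = 1e-7)
  expect_equal(coh$truth$sv_true[coh$truth$phenotype == "fusing_mixed"],
               rep(1.39, 2), tolerance = 1e-7)
  # reproducible from seed
  coh2 <- generateCohort(nPen = 3, nFus = 2, cv = 0, seed = 5)
  expect_identical(coh$truth, coh2$truth)
  # with biological variation the group means stay near target
  coh3 <- generateCohort(nPen = 23, nFus = 20, cv = 0.1, seed = 17)
  tr <- coh3$truth
  expect_equal(mean(tr$sv_true[tr$phenotype == "penetrating"]), 3.32,
               tolerance = 0.05)
  expect_equal(mean(tr$sv_true[tr$phenotype == "fusing_mixed"]), 1.39,
               tolerance = 0.05)
  # pore diameters share one distribution across phenotypes: same lognormal
  # parameters, so group means agree loosely even at these n
  expect_gt(min(tr$pore_diameter_true), 0.5)
})
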