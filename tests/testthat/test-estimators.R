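mkTally <- function(I, P) {
  methods::new("CountTally", I = as.integer(I), P = as.integer(P),
               nArcs = 1L, restricted = FALSE,
               perArc = data.frame(arc = 1L, I = as.integer(I),
                                   P = as.integer(P)))
}

test_that("the surface density formula is 2 sum(I) / (lp sum(P))", {
  expect_equal(estimateSV(mkTally(10, 5), lp = 2), 2)
  expect_equal(estimateSV(mkTally(0, 7), lp = 1), 0)
  expect_equal(estimateSV(list(mkTally(3, 2), mkTally(7, 3)), lp = 2), 2)
  expect_error(estimateSV(mkTally(5, 0), lp = 1), "undefined estimate")
  expect_error(estimateSV(mkTally(5, 2), lp = 0), "invalid parameter")
})

test_that("ratio-of-sums beats mean-of-ratios in variance on shared tallies", {
  set.seed(31)
  # per-section expected counts vary with slice width, as across a stack
  pooled <- mor <- numeric(100)
  for (r in 1:100) {
    w <- runif(5, 0.1, 1)
    I <- rpois(5, 40 * w + 15); P <- rpois(5, 50 * w + 2)
    pooled[r] <- 2 * sum(I) / sum(P)
    mor[r] <- mean(2 * I / pmax(P, 1))
  }
  expect_lt(var(pooled), var(mor))
})

test_that("random section selection is uniform over visible sections", {
  arr <- array(0L, dim = c(2, 2, 20))
  arr[1, 1, 10:19] <- 1L
  st <- tinyStack(arr, legend = c(`1` = "axon_penetrating"))
  draws <- vapply(1:10000, function(i) selectSection(st, 1L, seed = i),
                  numeric(1))
  freq <- table(factor(draws, levels = 10:19)) / 10000
  expect_true(all(abs(freq - 0.1) < 0.01))
  chi <- suppressWarnings(chisq.test(table(draws)))
  expect_gt(chi$p.value, 1e-4)
  # deterministic from seed, and a single visible section is forced
  expect_identical(selectSection(st, 1L, seed = 99),
                   selectSection(st, 1L, seed = 99))
  arr1 <- array(0L, dim = c(2, 2, 5)); arr1[1, 1, 3] <- 1L
  st1 <- tinyStack(arr1, legend = c(`1` = "axon_penetrating"))
  expect_equal(selectSection(st1, 1L, seed = 1), 3)
  expect_error(selectSection(st, 2L), "not found")
})

test_that("label volumes are voxel counts times voxel volume and additive", {
  arr <- array(0L, dim = c(20, 10, 10))
  arr[1:10, 1:10, 1] <- 1L         # 100 voxels
  arr[1:30 %% 7 + 1, 5, 5] <- 2L   # a few label-2 voxels
  st <- tinyStack(arr, spacing = c(0.01, 0.01, 0.1),
                  legend = c(`1` = "axon_penetrating", `2` = "axon_fusing"))
  v1 <- volumeFromLabels(st, 1L)
  v2 <- volumeFromLabels(st, 2L)
  expect_equal(v1, sum(arr == 1L) * 0.01 * 0.01 * 0.1)
  expect_equal(volumeFromLabels(st, c(1L, 2L)), v1 + v2)
  expect_warning(v3 <- volumeFromLabels(st, 9L), "absent")
  expect_equal(v3, 0)
})

test_that("pore diameter is the max Feret diameter, rotation-stable", {
  mkEllipseStack <- function(a, b, ang = 0, n = 300L, dx = 0.01) {
    xs <- (seq_len(n) - 0.5) * dx
    c0 <- n * dx / 2
    co <- cos(ang); si <- sin(ang)
    m <- outer(xs, xs, function(x, y) {
      u <- (x - c0) * co + (y - c0) * si
      v <- -(x - c0) * si + (y - c0) * co
      ifelse((u / a)^2 + (v / b)^2 <= 1, 3L, 0L)
    })
    arr <- array(0L, dim = c(n, n, 1))
    arr[, , 1] <- m
    tinyStack(arr, spacing = c(dx, dx, 0.1), legend = c(`3` = "pore"))
  }
  st <- mkEllipseStack(1, 0.5)
  expect_equal(poreDiameter(st), 2, tolerance = 0.011)  # within ~1 px
  for (ang in c(37, 85, 142) * pi / 180) {
    str <- mkEllipseStack(1, 0.5, ang)
    expect_equal(poreDiameter(str), poreDiameter(st), tolerance = 0.015)
    # never below the equivalent-circle diameter of the same region
    areaPx <- sum(stackData(str) == 3L)
    dEq <- 2 * sqrt(areaPx * 0.01^2 / pi)
    expect_gte(poreDiameter(str), dEq)
  }
  # growing ellipse across sections: the largest section wins
  arrs <- lapply(c(0.4, 0.7, 1), function(a) stackData(mkEllipseStack(a, 0.3)))
  arr3 <- array(0L, dim = c(300, 300, 3))
  for (k in 1:3) arr3[, , k] <- arrs[[k]]
  st3 <- tinyStack(arr3, spacing = c(0.01, 0.01, 0.1), legend = c(`3` = "pore"))
  expect_equal(poreDiameter(st3), 2, tolerance = 0.011)
  noPore <- tinyStack(array(0L, dim = c(4, 4, 2)), legend = character())
  expect_error(poreDiameter(noPore, 3L), "not found")
})

test_that("bundles classify by fusing-axon connectivity through a pore", {
  # a stack with only penetrating axons is penetrating
  arr <- array(0L, dim = c(10, 10, 3)); arr[3:6, 3:6, 2] <- 1L
  stPen <- tinyStack(arr, legend = c(`1` = "axon_penetrating"))
  expect_equal(classifyBundle(stPen), "penetrating")
  # the generator's fusing phantom classifies fusing_mixed by construction
  coh <- generateCohort(nPen = 0, nFus = 1, svFus = 2, shaftRadius = 0.2,
                        shaftLength = 2, seed = 3,
                        spacing = c(0.02, 0.02, 0.1))
  st <- voxelize(coh$scenes[[1]], coh$spacing, roles = "axon_fusing")
  expect_equal(classifyBundle(st), "fusing_mixed")
  # fusing label separated from the epithelium by intact lamina (the pore
  # sits far from the bundle): penetrating
  R <- coh$truth$radius[1]
  sep <- local({
    tube <- makeTubeWithBulb(0.2, 2, R,
                             list(rotation = diag(3),
                                  translation = c(0.45, 0.3 + R, 1.7)))
    sceneSpec(list(tube), 1L,
              bounds = c(0, 8, 0, 0.4 + 2 * R + 0.6, 0, 2 * R + 0.4),
              lamina = list(y0 = 0.3 + 2 * R + 0.15, thickness = 0.08,
                            label = 2L),
              pores = data.frame(cx = 6.5, cz = 1.7, a = 0.8, b = 0.6,
                                 label = 3L),
              epithelium = list(label = 4L), seed = 1L)
  })
  stSep <- voxelize(sep, c(0.02, 0.02, 0.1), roles = "axon_fusing")
  expect_equal(classifyBundle(stSep), "penetrating")
  noNerve <- tinyStack(array(0L, dim = c(4, 4, 2)), legend = character())
  expect_error(classifyBundle(noNerve), "not found")
})

test_that("morphometry scales covariantly with physical voxel size", {
  coh <- generateCohort(nPen = 1, nFus = 0, lPen = 2, seed = 9,
                        spacing = c(0.02, 0.02, 0.1))
  st1 <- voxelize(coh$scenes[[1]], coh$spacing, roles = "axon_penetrating")
  k <- 3
  st2 <- cycloidSV:::newLabelStack(stackData(st1), spacing(st1) * k,
                                   labelLegend(st1))
  m1 <- bundleMorphometry(st1, "axon_penetrating", lp = 1, casts = 2,
                          seed = 12)
  m2 <- bundleMorphometry(st2, "axon_penetrating", lp = k, casts = 2,
                          seed = 12)
  expect_equal(m2$volume_bundle, m1$volume_bundle * k^3, tolerance = 1e-10)
  expect_equal(m2$pore_diameter, m1$pore_diameter * k, tolerance = 1e-10)
  expect_equal(m2$sv_hat, m1$sv_hat / k, tolerance = 1e-10)
  expect_identical(m2$sum_I, m1$sum_I)
  expect_identical(m2$sum_P, m1$sum_P)
})

test_that("section annotation extracts lamina trace, pore chord and centroid", {
  coh <- generateCohort(nPen = 1, nFus = 0, lPen = 2, seed = 21,
                        spacing = c(0.02, 0.02, 0.1))
  st <- voxelize(coh$scenes[[1]], coh$spacing, roles = "axon_penetrating")
  po <- coh$scenes[[1]]@pores
  kPore <- round(po$cz / 0.1 + 0.5)  # section through the pore centre
  sp <- sectionFromStack(st, kPore)
  expect_gt(nrow(sp@laminaTrace), 10)
  expect_equal(laminaOrientation(sp), 0, tolerance = 1e-6)
  expect_equal(nrow(sp@poreEndpoints), 2L)
  # chord length close to the pore width in that section
  chord <- sqrt(sum((sp@poreEndpoints[1, ] - sp@poreEndpoints[2, ])^2))
  expect_equal(chord, 2 * po$a, tolerance = 0.1)
  # epithelium lies above the lamina
  expect_gt(sp@epiCentroid[2], mean(sp@laminaTrace[, 2]))
})
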