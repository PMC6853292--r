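test_that("cycloid arcs have length 8 r_c and tile the plane periodically", {
  lp <- 1.2
  g <- buildGrid(lp, 0, c(0.05, 0.11), extent = c(0, 4, 0, 4))
  rc <- lp / 8
  lens <- vapply(g@arcs, function(a) sum(sqrt(rowSums(diff(a)^2))),
                 numeric(1))
  expect_true(all(abs(lens - 8 * rc) / (8 * rc) < 0.001))
  expect_equal(g@lp, 8 * g@arcScale)
  # arc length per unit area equals lp / (area per point): count the arcs
  # whose tile lies fully inside a large window
  W <- g@tile[1]; H <- g@tile[2]
  # orientation pi/2 puts the grid frame axis-aligned with the image
  gBig <- buildGrid(lp, pi / 2, c(0, 0), extent = c(0, 20 * W, 0, 10 * H))
  mids <- t(vapply(gBig@arcs, function(a) a[ceiling(nrow(a) / 2), ],
                   numeric(2)))
  inside <- mids[, 1] >= W - 1e-9 & mids[, 1] < 19 * W - 1e-9 &
            mids[, 2] >= H - 1e-9 & mids[, 2] < 9 * H - 1e-9
  areaWindow <- 18 * W * 8 * H
  lengthDensity <- sum(lens[1] * inside) / areaWindow
  areaPerPoint <- W * H / 2
  expect_equal(lengthDensity, lp / areaPerPoint, tolerance = 0.005)
})

test_that("a phase shift of one full tile reproduces the same grid", {
  lp <- 1
  W <- 2 * pi * lp / 8; H <- 4 * lp / 8
  ext <- c(0, 5, 0, 5)
  g1 <- buildGrid(lp, 0.4, c(0.03, 0.07), ext)
  g2 <- buildGrid(lp, 0.4, c(0.03 + W, 0.07), ext)
  p1 <- g1@points[order(round(g1@points[, 1], 9), round(g1@points[, 2], 9)), ]
  p2 <- g2@points[order(round(g2@points[, 1], 9), round(g2@points[, 2], 9)), ]
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("rotating the grid orientation by pi leaves the arc set unchanged", {
  # the two-arc tile is point-symmetric: rotating the pattern by pi about
  # the origin equals translating it by half a tile, so orientation + pi
  # with the matching phase gives an identical test system
  lp <- 0.9
  W <- 2 * pi * lp / 8
  phase <- c(0.04, 0.02)
  ext <- c(0, 4, 0, 4)
  g1 <- buildGrid(lp, 0.3, phase, ext)
  g2 <- buildGrid(lp, 0.3 + pi, -phase - c(W / 2, 0), ext)
  p1 <- g1@points[order(round(g1@points[, 1], 8), round(g1@points[, 2], 8)), ]
  p2 <- g2@points[order(round(g2@points[, 1], 8), round(g2@points[, 2], 8)), ]
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("lamina orientation is the total-least-squares direction", {
  mkTrace <- function(ang, n = 200, sd = 0) {
    s <- seq(0, 3, length.out = n)
    cbind(s * cos(ang) + rnorm(n, 0, sd), s * sin(ang) + rnorm(n, 0, sd))
  }
  horiz <- sectionPlane(matrix(0L, 4, 4), c(1, 1), laminaTrace = mkTrace(0))
  expect_equal(laminaOrientation(horiz), 0)
  for (ang in c(0.3, 1.2, 2.9)) {
    sp <- sectionPlane(matrix(0L, 4, 4), c(1, 1),
                       laminaTrace = mkTrace(ang))
    expect_equal(laminaOrientation(sp), ang %% pi, tolerance = 1e-6)
  }
  # noisy trace: 1 px noise on a 30-degree line stays within 2 degrees
  set.seed(41)
  errs <- replicate(50, {
    sp <- sectionPlane(matrix(0L, 4, 4), c(1, 1),
                       laminaTrace = mkTrace(pi / 6, sd = 0.01))
    abs(laminaOrientation(sp) - pi / 6)
  })
  expect_lt(max(errs), 2 * pi / 180)
  deg <- sectionPlane(matrix(0L, 4, 4), c(1, 1),
                      laminaTrace = cbind(rep(1, 5), rep(2, 5)))
  expect_error(laminaOrientation(deg), "degenerate")
  one <- sectionPlane(matrix(0L, 4, 4), c(1, 1),
                      laminaTrace = matrix(c(1, 2), 1, 2))
  expect_error(laminaOrientation(one), "at least 2")
})

test_that("the restriction line orients its stromal side away from the epithelium", {
  img <- matrix(0L, 10, 10)
  sp <- sectionPlane(img, c(1, 1),
                     poreEndpoints = rbind(c(0, 0), c(4, 0)),
                     epiCentroid = c(2, -3))
  rl <- restrictionLine(sp)
  expect_gt(cycloidSV:::stromalSide(rl, matrix(c(2, 1), 1, 2)), 0)
  expect_lt(cycloidSV:::stromalSide(rl, matrix(c(2, -1), 1, 2)), 0)
  noPore <- sectionPlane(img, c(1, 1), epiCentroid = c(2, -3))
  expect_error(restrictionLine(noPore), "no pore")
})

test_that("a straight test line through a disc crosses its boundary twice", {
  sp <- discSection(n = 200, dx = 0.01, rho = 0.6)
  g <- lineGrid(0, 1, 2, 1, point = c(1, 1))  # horizontal line through centre
  tal <- countGrid(g, sp, 1L)
  expect_equal(tal@I, 2L)
  expect_equal(tal@P, 1L)  # the point at the centre lies inside
  # empty mask: zero counts with a warning, not an error
  empty <- sectionPlane(matrix(0L, 50, 50), c(0.01, 0.01))
  expect_warning(tal0 <- countGrid(g, empty, 1L), "absent")
  expect_equal(tal0@I, 0L)
  expect_equal(tal0@P, 0L)
})

test_that("polygon-intersection counts match a dense-sampling oracle", {
  set.seed(7)
  mismatches <- 0L
  for (i in 1:100) {
    rho <- runif(1, 0.2, 0.7)
    cx <- runif(1, 0.8, 1.2); cy <- runif(1, 0.8, 1.2)
    sp <- discSection(n = 200, dx = 0.01, rho = rho, cx = cx, cy = cy)
    g <- buildGrid(0.9, runif(1, 0, pi), runif(2), extent = c(0, 2, 0, 2))
    tal <- countGrid(g, sp, 1L)
    oracle <- bruteCrossings(g, sp, 1L, samples = 1e4)
    if (tal@I != oracle) mismatches <- mismatches + 1L
  }
  expect_equal(mismatches, 0L)
})

test_that("point counting is an unbiased area estimator over random phases", {
  # rectangle mask of known area, 500 random phases
  dx <- 0.01
  img <- matrix(0L, 220, 180)
  img[31:190, 41:140] <- 1L  # 160 x 100 px = 1.6 x 1.0 um
  sp <- sectionPlane(img, c(dx, dx))
  lp <- 0.9
  areaPerPoint <- pi * lp^2 / 16
  set.seed(11)
  P <- replicate(500, castGrid(sp, 1L, lp = lp)@P)
  expect_equal(mean(P) * areaPerPoint, 1.6 * 1.0, tolerance = 0.02)
})

test_that("closed boundaries inside the extent yield even crossing counts", {
  sp <- discSection(n = 250, dx = 0.01, rho = 0.8)
  mask <- sp@image == 1L
  field <- cycloidSV:::boxSmooth(mask + 0, 2L)
  set.seed(13)
  for (i in 1:20) {
    g <- buildGrid(1.1, runif(1, 0, pi), runif(2) * 2, extent = c(0, 2.5, 0, 2.5))
    tal <- countGrid(g, sp, 1L)
    ends <- t(vapply(g@arcs, function(a) c(a[1, ], a[nrow(a), ]), numeric(4)))
    endsIn <- cycloidSV:::bilinearAt(field, 0.01, 0.01, ends[, 1], ends[, 2]) > 0.5 |
              cycloidSV:::bilinearAt(field, 0.01, 0.01, ends[, 3], ends[, 4]) > 0.5
    expect_true(all(tal@perArc$I[!endsIn] %% 2 == 0))
  }
})

test_that("counting is invariant under integer-tile phase translation", {
  sp <- discSection(n = 200, dx = 0.01, rho = 0.6)
  lp <- 1
  W <- 2 * pi * lp / 8; H <- 4 * lp / 8
  g1 <- buildGrid(lp, 0.2, c(0.03, 0.05), extent = c(0, 2, 0, 2))
  g2 <- buildGrid(lp, 0.2, c(0.03 + 2 * W, 0.05 - H), extent = c(0, 2, 0, 2))
  t1 <- countGrid(g1, sp, 1L); t2 <- countGrid(g2, sp, 1L)
  expect_equal(t1@I, t2@I)
  expect_equal(t1@P, t2@P)
})

test_that("restricted counts partition the unrestricted tally across the line", {
  # disc straddling the restriction line; counting each side separately
  # must recover the whole
  sp0 <- discSection(n = 220, dx = 0.01, rho = 0.7, cx = 1.1, cy = 1.0)
  mkSide <- function(epiY) sectionPlane(sp0@image, c(0.01, 0.01),
                                        poreEndpoints = rbind(c(0, 1.0), c(2.2, 1.0)),
                                        epiCentroid = c(1.1, epiY))
  spA <- mkSide(2.0)   # stromal side is y < 1
  spB <- mkSide(0.1)   # stromal side is y > 1
  set.seed(23)
  for (i in 1:10) {
    g <- buildGrid(0.8, runif(1, 0, pi), runif(2), extent = c(0, 2.2, 0, 2.2))
    full <- countGrid(g, spA, 1L)
    below <- countGrid(g, spA, 1L, restricted = TRUE)
    above <- countGrid(g, spB, 1L, restricted = TRUE)
    expect_equal(below@I + above@I, full@I)
    expect_equal(below@P + above@P, full@P)
    expect_lte(below@I, full@I)  # restricted never exceeds unrestricted
  }
  # mask entirely on the epithelial side: restricted counts vanish
  img <- matrix(0L, 200, 200)
  img[80:120, 150:190] <- 1L
  spC <- sectionPlane(img, c(0.01, 0.01),
                      poreEndpoints = rbind(c(0, 1.0), c(2.0, 1.0)),
                      epiCentroid = c(1.0, 1.8))
  g <- buildGrid(0.8, 0, c(0.1, 0.1), extent = c(0, 2, 0, 2))
  ral <- countGrid(g, spC, 1L, restricted = TRUE)
  expect_equal(ral@I, 0L)
  expect_equal(ral@P, 0L)
})
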