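test_that("pooled t test behaves at its conventions and extremes", {
  same <- compareSV(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same@statValue, 0)
  expect_equal(same@pValue, 1)
  set.seed(5)
  sep <- compareSV(3 + rnorm(4, 0, 0.01), 1 + rnorm(4, 0, 0.01))
  expect_lt(sep@pValue, 1e-4)
  expect_equal(sep@details$df, 6)
  a <- c(3.1, 3.5, 2.9, 3.2); b <- c(1.2, 1.6, 1.4, 1.1)
  ab <- compareSV(a, b); ba <- compareSV(b, a)
  expect_equal(ab@statValue, -ba@statValue)
  expect_equal(ab@pValue, ba@pValue)
  # matches the reference pooled t implementation
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(ab@statValue, unname(ref$statistic))
  expect_equal(ab@pValue, ref$p.value)
  expect_error(compareSV(1, c(1, 2)), "insufficient data")
})

test_that("Mann-Whitney exact p equals full enumeration and wilcox reference", {
  r <- comparePores(c(1, 2), c(3, 4))
  expect_equal(r@statValue, 0)
  expect_equal(r@pValue, 1 / 3, tolerance = 1e-12)
  expect_true(r@details$exact)
  # identical multisets: U1 = U2 = n^2 / 2
  tie <- comparePores(c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_equal(tie@details$U1, 8)
  expect_equal(tie@details$U2, 8)
  # U1 + U2 = n1 n2 on random inputs
  set.seed(8)
  for (i in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- runif(n1); y <- runif(n2)
    rr <- comparePores(x, y)
    expect_equal(rr@details$U1 + rr@details$U2, n1 * n2)
  }
  # exact p agrees with the independent exact reference for all tie-free
  # inputs with combined n <= 10
  set.seed(9)
  for (i in 1:30) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(seq(0.1, 9.9, by = 0.1), n1)
    y <- setdiff(seq(0.1, 9.9, by = 0.1), x)[seq_len(n2)]
    rr <- comparePores(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(rr@pValue, ref$p.value, tolerance = 1e-12)
    expect_equal(rr@statValue, unname(ref$statistic))
  }
  # large samples switch to the corrected normal approximation
  set.seed(10)
  big <- comparePores(runif(23), runif(20))
  expect_false(big@details$exact)
  expect_true(big@pValue > 0 && big@pValue <= 1)
  expect_error(comparePores(1, c(1, 2)), "insufficient data")
})

test_that("fusion frequency reproduces the printed central-cornea proportion", {
  phen <- rep(c("fusing_mixed", "penetrating"), c(9, 12))
  expect_equal(fusionFrequency(phen), 42.9)
  expect_equal(fusionFrequency(rep("penetrating", 21)), 0)
  expect_equal(fusionFrequency(rep("fusing_mixed", 21)), 100)
  expect_error(fusionFrequency(character()), "insufficient data")
})

test_that("volume fractions reproduce the printed reconstruction shares", {
  expect_equal(volumeFraction(75.42, c(75.42, 24.64)), 0.75, tolerance = 0.01)
  expect_equal(volumeFraction(0, c(1, 2)), 0)
  expect_equal(volumeFraction(5, 5), 1)
  expect_error(volumeFraction(0, c(0, 0)), "undefined")
  expect_error(volumeFraction(-1, c(1)), "non-negative")
})

test_that("the pooled t test holds its nominal size on null cohorts", {
  set.seed(12)
  sig <- sqrt(log(1 + 0.1^2))
  rej <- replicate(2000, {
    pen <- 2 * rlnorm(23, -sig^2 / 2, sig)
    fus <- 2 * rlnorm(20, -sig^2 / 2, sig)
    compareSV(pen, fus)@pValue <= 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("group comparisons print a readable report", {
  out <- capture.output(show(compareSV(c(3.1, 3.3, 3.2), c(1.2, 1.4, 1.5))))
  expect_true(any(grepl("student_t_two_tailed", out)))
  expect_true(any(grepl("SEM", out)))
})
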