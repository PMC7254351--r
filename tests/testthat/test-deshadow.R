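test_that("mean subtraction matches hand arithmetic", {
  expect_equal(meanSubtractAline(c(8, 4, 0, 0), w = 1), c(5, 1, 0, 0))
  expect_equal(meanSubtractAline(c(8, 4, 0, 0), w = 1,
                                 clipNegative = FALSE),
               c(5, 1, -3, -3))
  # w = 0 is the identity; a constant line is annihilated at w = 1
  a <- c(0.3, 1.2, 0.05, 2)
  expect_identical(meanSubtractAline(a, w = 0), a)
  expect_equal(meanSubtractAline(rep(3.7, 10), w = 1), rep(0, 10))
})

test_that("mean subtraction validates its input", {
  expect_error(meanSubtractAline(numeric(0), w = 1), "length >= 1")
  expect_error(meanSubtractAline(c(1, NaN), w = 1), "NaN")
  expect_error(meanSubtractAline(c(1, 2), w = -1), "non-negative")
})

test_that("subtracted offset grows with the tail (aggressiveness)", {
  base <- c(5, 1, 0.2, 0, 0, 0)
  longTail <- c(5, 1, 0.2, 0.4, 0.3, 0.2)   # same line, longer tail
  w <- 2
  offShort <- base - meanSubtractAline(base, w, clipNegative = FALSE)
  offLong <- longTail - meanSubtractAline(longTail, w,
                                          clipNegative = FALSE)
  expect_true(unique(offLong)[1] > unique(offShort)[1])
})

test_that("mean subtraction is not idempotent", {
  a <- c(8, 4, 0, 0)
  once <- meanSubtractAline(a, w = 1)
  twice <- meanSubtractAline(once, w = 1)
  expect_false(isTRUE(all.equal(once, twice)))
})

test_that("step-down recursion matches its analytic values", {
  out <- stepDownAline(c(1, 1, 1), gamma = 1)
  expect_equal(out, c(1, exp(-1), exp(-(1 + exp(-1)))),
               tolerance = 1e-9)
  expect_identical(stepDownAline(rep(0, 5), gamma = 2), rep(0, 5))
  # attenuation vanishes for very large gamma
  a <- c(2, 1, 3, 0.5)
  expect_equal(stepDownAline(a, gamma = 1e12 * sum(a)), a,
               tolerance = 1e-9)
  expect_error(stepDownAline(c(1, 2), gamma = 0), "positive")
  expect_error(stepDownAline(c(1, 2), gamma = -3), "positive")
})

test_that("step-down equals the scalar brute-force recursion", {
  for (seed in 0:19) {
    set.seed(seed)
    n <- sample(1:64, 1)
    a <- runif(n, 0, 5)
    g <- runif(1, 0.1, 50)
    got <- stepDownAline(a, g)
    want <- stepDownOracle(a, g)
    expect_lt(max(abs(got - want) / pmax(abs(want), 1e-300)), 1e-12)
  }
})

test_that("step-down output is dominated by its input", {
  set.seed(3)
  a <- runif(64, 0, 4)
  out <- stepDownAline(a, gamma = 2)
  expect_true(all(out >= 0))
  expect_true(all(out <= a + 1e-15))
})

test_that("deshadowVolume equals stacking the per-A-line operators", {
  vol <- randomVolume(c(8L, 3L, 4L), seed = 11)
  for (params in list(
    deshadowParams("mean_subtraction", w = 1.7, normalizeOutput = FALSE),
    deshadowParams("mean_subtraction", w = 1.7, clipNegative = FALSE,
                   normalizeOutput = FALSE),
    deshadowParams("step_down", gamma = 1.3, normalizeOutput = FALSE))) {
    got <- volData(deshadowVolume(vol, params))
    want <- array(0, dim(vol))
    for (i in seq_len(dim(vol)[2])) {
      for (j in seq_len(dim(vol)[3])) {
        a <- volData(vol)[, i, j]
        want[, i, j] <- if (params@method == "mean_subtraction")
          meanSubtractAline(a, params@w, params@clipNegative)
        else stepDownAline(a, params@gamma)
      }
    }
    expect_equal(got, want, tolerance = 1e-14)
  }
})

test_that("de-shadowing is per-A-line: column permutations commute", {
  vol <- randomVolume(c(10L, 4L, 5L), seed = 12)
  params <- deshadowParams("mean_subtraction", w = 2,
                           normalizeOutput = FALSE)
  set.seed(1)
  px <- sample(4); py <- sample(5)
  permuted <- OctaVolume(volData(vol)[, px, py], 4, 16, 16)
  expect_equal(volData(deshadowVolume(permuted, params)),
               volData(deshadowVolume(vol, params))[, px, py])
  params2 <- deshadowParams("step_down", gamma = 0.8,
                            normalizeOutput = FALSE)
  expect_equal(volData(deshadowVolume(permuted, params2)),
               volData(deshadowVolume(vol, params2))[, px, py])
})

test_that("only columns with signal are changed (locality)", {
  a <- array(0, c(6L, 3L, 3L))
  a[, 2, 3] <- c(4, 2, 1, 0.5, 0.2, 0)
  vol <- OctaVolume(a, 4, 16, 16)
  out <- volData(deshadowVolume(
    vol, deshadowParams("mean_subtraction", w = 2,
                        normalizeOutput = FALSE)))
  changed <- apply(out != a, c(2, 3), any)
  expect_identical(which(changed), which(apply(a > 0, c(2, 3), any)))
  expect_identical(sum(changed), 1L)
})

test_that("w = 0 reproduces the input up to global normalization", {
  vol <- randomVolume(c(8L, 4L, 4L), seed = 9)
  out <- deshadowVolume(vol, deshadowParams("mean_subtraction", w = 0))
  expect_equal(volData(out), volData(vol) / max(volData(vol)),
               tolerance = 1e-14)
})

test_that("pixels above the surface index pass through untouched", {
  set.seed(21)
  a <- array(runif(12 * 2 * 2, 0.5, 1), c(12L, 2L, 2L))
  vol <- OctaVolume(a, 4, 16, 16, surfaceIndex = 3L)
  ms <- volData(deshadowVolume(
    vol, deshadowParams("mean_subtraction", w = 2,
                        normalizeOutput = FALSE)))
  sdv <- volData(deshadowVolume(
    vol, deshadowParams("step_down", gamma = 0.5,
                        normalizeOutput = FALSE)))
  expect_identical(ms[1:3, , ], a[1:3, , ])
  expect_identical(sdv[1:3, , ], a[1:3, , ])
  # first tissue pixel of the step-down result is unattenuated: the
  # above-surface pixels are excluded from the accumulation
  expect_identical(sdv[4, , ], a[4, , ])
  # the mean-subtraction offset still uses all N pixels of the column
  expect_equal(ms[4, , ], pmax(a[4, , ] - 2 * apply(a, c(2, 3), mean), 0))
})

test_that("all-zero volume skips normalization with a warning", {
  vol <- OctaVolume(array(0, c(4L, 2L, 2L)), 4, 16, 16)
  expect_warning(out <- deshadowVolume(vol, deshadowParams()),
                 "normalization skipped")
  expect_true(all(volData(out) == 0))
})

test_that("histogram equalization follows the empirical CDF", {
  # two levels with equal mass map to CDF values 0.5 and 1
  a <- array(rep(c(1, 3), each = 8), c(4L, 2L, 2L))
  out <- volData(equalizeVolume(OctaVolume(a, 4, 16, 16), nBins = 16))
  expect_equal(sort(unique(as.vector(out))), c(0.5, 1.0))
  expect_equal(out[a == 1][1], 0.5)
  # monotone: input ordering is never inverted
  vol <- randomVolume(c(6L, 4L, 4L), seed = 5)
  eq <- volData(equalizeVolume(vol, nBins = 32))
  o <- order(as.vector(volData(vol)))
  expect_true(all(diff(as.vector(eq)[o]) >= 0))
  expect_true(all(eq >= 0 & eq <= 1))
})

test_that("equalizing a constant volume is a warned no-op", {
  vol <- OctaVolume(array(2, c(3L, 2L, 2L)), 4, 16, 16)
  expect_warning(out <- equalizeVolume(vol), "no-op")
  expect_identical(volData(out), volData(vol))
})

test_that("matchGamma reproduces the target tail residual", {
  p <- generatePhantom(smallPhantomSpec(seed = 2))
  vol <- p$volume; roi <- p$truth@tailMask
  # w chosen so the clipped mean-subtraction residual stays positive:
  # at large w the whole tail clips to zero, which is the boundary case
  # tested separately below
  w <- 0.75
  eMs <- mean(volData(deshadowVolume(
    vol, deshadowParams("mean_subtraction", w = w,
                        normalizeOutput = FALSE)))[roi])
  g <- matchGamma(vol, w, roi)
  eSd <- mean(volData(deshadowVolume(
    vol, deshadowParams("step_down", gamma = g,
                        normalizeOutput = FALSE)))[roi])
  expect_lte(abs(eSd - eMs), 0.05 * eMs)
  # at least as close as an independent 200-point grid search
  grid <- 10^seq(-2, 3, length.out = 200)
  resid <- vapply(grid, function(gg) mean(volData(deshadowVolume(
    vol, deshadowParams("step_down", gamma = gg,
                        normalizeOutput = FALSE)))[roi]), numeric(1))
  expect_lte(abs(eSd - eMs), min(abs(resid - eMs)) + 1e-9)
})

test_that("matched gamma is monotone non-increasing in w", {
  p <- generatePhantom(smallPhantomSpec(seed = 3))
  gs <- vapply(c(0.25, 0.5, 0.75, 1), function(w)
    matchGamma(p$volume, w, p$truth@tailMask), numeric(1))
  expect_true(all(diff(gs) <= 1e-8))
})

test_that("matchGamma returns the boundary when w = 0", {
  p <- generatePhantom(smallPhantomSpec(seed = 4))
  expect_warning(
    g <- matchGamma(p$volume, 0, p$truth@tailMask,
                    searchRange = c(0.1, 100)),
    "upper bound")
  expect_identical(g, 100)
})
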