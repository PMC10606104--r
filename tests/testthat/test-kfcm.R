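test_that("membership update matches the closed form and normalizes rows", {
  # zero-distance limit: crisp assignment
  M <- updateMembership(c(0.4), c(0.4, 0.9), n = 2)
  expect_equal(as.vector(M), c(1, 0))
  # symmetry at the midpoint
  M <- updateMembership(0.5, c(0.4, 0.6), n = 2)
  expect_equal(as.vector(M), c(0.5, 0.5))
  # oracle: direct evaluation, memberships proportional to inverse squared
  # distances for n = 2
  M <- updateMembership(0.2, c(0, 1), n = 2)
  expect_equal(as.vector(M), c(0.64 / 0.68, 0.04 / 0.68), tolerance = 1e-12)
  # row normalization across random problems
  withr::with_seed(2, {
    for (i in 1:10) {
      M <- updateMembership(runif(50), sort(runif(3)), n = runif(1, 1.5, 3))
      expect_true(all(abs(rowSums(M) - 1) < 1e-12))
      expect_true(all(M >= 0 & M <= 1))
    }
  })
})

test_that("centre update matches the weighted-mean closed form", {
  # crisp memberships reduce to per-cluster arithmetic means
  M <- rbind(c(1, 0), c(1, 0), c(0, 1))
  expect_equal(updateCenters(c(0.1, 0.3, 0.9), M, n = 2), c(0.2, 0.9))
  # single pixel
  expect_equal(updateCenters(0.7, matrix(1, 1, 1), n = 2), 0.7)
  # oracle: direct evaluation of the update formula
  M <- rbind(c(0.8, 0.2), c(0.2, 0.8))
  y <- updateCenters(c(0, 1), M, n = 2)
  expect_equal(y[1], 0.04 / 0.68, tolerance = 1e-12)
  # empty column keeps the previous centre
  M0 <- rbind(c(1, 0), c(1, 0))
  expect_warning(y <- updateCenters(c(0.2, 0.4), M0, n = 2, previous = c(0, 0.9)),
                 "empty")
  expect_equal(y[2], 0.9)
})

test_that("correlation distance follows the Pearson contract", {
  a <- c(1, 2, 3)
  expect_equal(correlationDistance(a, a), 0)
  expect_equal(correlationDistance(a, -a + 10), 2)
  expect_equal(correlationDistance(a, c(1, 3, 2)), 0.5)
  expect_equal(correlationDistance(c(2, 2, 2), a), 1)  # constant patch
  expect_error(correlationDistance(a, c(1, 2)), "mismatch")
})

test_that("fuzzy factor sums weighted neighbour disagreement", {
  dims <- c(3L, 3L)
  Mall1 <- matrix(1, 9, 2)
  expect_equal(fuzzyFactor(Mall1, 5L, 1L, dims), 0)
  # oracle: 8 neighbours at Chebyshev distance 1, weight 1/2 each
  Mall0 <- matrix(0, 9, 2)
  expect_equal(fuzzyFactor(Mall0, 5L, 1L, dims), 4)
  # monotone nonincreasing in each neighbour's membership
  M <- matrix(0.5, 9, 2)
  base <- fuzzyFactor(M, 5L, 1L, dims)
  M[1, 1] <- 0.9
  expect_lt(fuzzyFactor(M, 5L, 1L, dims), base)
  expect_error(fuzzyFactor(M, 10L, 1L, dims), "out of grid")
})

test_that("modified KFCM recovers the two plateaus of a two-valued image", {
  img <- matrix(c(rep(0.2, 32), rep(0.8, 32)), 8, 8)
  # oracle: plain FCM on perfectly separable data lands on the plateaus
  fitPlain <- runModifiedKFCM(img, kfcmControl(window = 1L, tol = 1e-10))
  expect_equal(sort(centers(fitPlain)), c(0.2, 0.8), tolerance = 1e-6)
  # the spatial factor shifts boundary memberships but not the plateaus' order
  fit <- runModifiedKFCM(img, kfcmControl())
  expect_equal(sort(centers(fit)), c(0.2, 0.8), tolerance = 0.05)
  expect_true(all(abs(rowSums(membership(fit)) - 1) < 1e-12))
})

test_that("factor-disabled KFCM equals textbook FCM (independent oracle)", {
  withr::with_seed(3, {
    for (trial in 1:5) {
      img <- clipMat(matrix(c(rnorm(32, 0.25, 0.05), rnorm(32, 0.75, 0.05)), 8, 8))
      fit <- runModifiedKFCM(img, kfcmControl(window = 1L, tol = 1e-10,
                                              maxIter = 500L))
      cm <- e1071::cmeans(matrix(as.vector(img)),
                          centers = matrix(sort(centers(fit))),
                          iter.max = 500, m = 2, method = "cmeans")
      expect_equal(sort(centers(fit)), sort(as.vector(cm$centers)),
                   tolerance = 1e-6)
    }
  })
})

test_that("plain-FCM objective trace is nonincreasing", {
  withr::with_seed(4, {
    img <- clipMat(matrix(c(rnorm(128, 0.3, 0.08), rnorm(128, 0.7, 0.08)), 16, 16))
  })
  fit <- runModifiedKFCM(img, kfcmControl(window = 1L, tol = 0, maxIter = 30L))
  tr <- objectiveTrace(fit)
  expect_gte(length(tr), 5L)
  expect_true(all(diff(tr[-1]) <= 1e-9))
})

test_that("ROI extraction pads, truncates and ignores cluster labelling", {
  withr::with_seed(9, {
    blob <- outer(1:64, 1:64, function(i, j) (i - 32)^2 + (j - 32)^2 < 26^2)
    img <- matrix(0.7, 64, 64); img[blob] <- 0.25
    img <- clipMat(img + matrix(rnorm(64^2, 0, 0.02), 64, 64))
  })
  fit <- runModifiedKFCM(img, kfcmControl())
  nFg <- sum(max.col(membership(fit)) ==
               which.max(tabulate(max.col(membership(fit)), 2)))

  # exact pass-through when the target equals the foreground size
  roiExact <- extractROI(img, fit, length = nFg)
  expect_length(roiValues(roiExact), nFg)
  # truncation keeps the highest-membership pixels
  roiTrunc <- extractROI(img, fit, length = nFg - 100L)
  expect_length(roiValues(roiTrunc), nFg - 100L)
  # padding fills with the foreground median
  roiPad <- extractROI(img, fit, length = nFg + 50L)
  expect_length(roiValues(roiPad), nFg + 50L)
  expect_equal(roiValues(roiPad)[nFg + 1L], median(roiValues(roiExact)))

  # the dark majority blob is the foreground
  expect_gte(sum(roiMask(roiExact) & blob) / sum(blob), 0.95)

  # label-permutation invariance
  fitSwap <- new("KFCMFit", membership = membership(fit)[, 2:1],
                 centers = centers(fit)[2:1],
                 objective = objectiveTrace(fit), dims = fit@dims,
                 iterations = fit@iterations, converged = fit@converged)
  expect_identical(roiValues(roiExact), roiValues(extractROI(img, fitSwap,
                                                             length = nFg)))
})
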