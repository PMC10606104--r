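test_that("KL divergence honours its limit cases and closed form", {
  expect_equal(klDivergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_identical(klDivergence(c(1, 0), c(0, 1)), Inf)
  expect_equal(klDivergence(c(0.5, 0.5), c(0.9, 0.1)),
               0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1))
  expect_gte(klDivergence(c(0.2, 0.8), c(0.6, 0.4)), 0)
  expect_error(klDivergence(c(0.5, 0.5), c(1, 0, 0)), "mismatch")
  expect_error(klDivergence(c(-0.5, 1.5), c(0.5, 0.5)), "negative")
  expect_error(klDivergence(c(0.5, 0.6), c(0.5, 0.5)), "sum to 1")
})

test_that("KLD ranking scores discriminative positions highest", {
  withr::with_seed(6, {
    n <- 20
    sep <- c(rnorm(n, 0.2, 0.05), rnorm(n, 0.8, 0.05))
    flat <- runif(2 * n, 0.45, 0.55)
    same <- rep(c(0.3, 0.6), n)
  })
  x <- clipMat(cbind(same, sep, flat))
  y <- rep(c("N", "ACA"), each = 20)
  sc <- rankFeaturesKLD(x, y)
  expect_true(all(is.finite(sc)) && all(sc >= 0))
  expect_identical(which.max(sc), 2L)
  # symmetry under class-label swap
  ySwap <- rep(c("ACA", "N"), each = 20)
  expect_equal(sc, rankFeaturesKLD(x, ySwap))
  # a position with identical class distributions scores ~0
  xSame <- cbind(same, same)
  expect_equal(rankFeaturesKLD(xSame, y)[1], rankFeaturesKLD(xSame, y)[2])
  expect_error(rankFeaturesKLD(x[y == "N", ], y[y == "N"]), "both")
})

test_that("top-k selection sorts, tie-breaks and reshapes as specified", {
  m <- matrix(runif(12), 2, 6)
  selAll <- selectTopK(m, scores = 6:1, k = 6L, shape = c(2L, 3L))
  expect_identical(selectedPositions(selAll), 1:6)     # identity selection
  selTies <- selectTopK(m, scores = rep(1, 6), k = 3L, shape = c(1L, 3L))
  expect_identical(selectedPositions(selTies), 1:3)    # tie rule: lower index
  sel <- selectTopK(m, scores = c(3, 1, 2, 0, 0, 0), k = 2L, shape = c(1L, 2L))
  expect_identical(selectedPositions(sel), c(1L, 3L))
  expect_identical(featureValues(sel), m[, c(1, 3)])
  expect_identical(dim(imageMatrix(sel, 1L)), c(1L, 2L))
  expect_error(selectTopK(m, scores = 6:1, k = 7L), "exceeds")
})

test_that("IWO schedules interpolate their endpoints", {
  expect_identical(iwoSeedCount(0, 0, 1, 0L, 4L), 4L)
  expect_identical(iwoSeedCount(1, 0, 1, 0L, 4L), 0L)
  expect_identical(iwoSeedCount(0.5, 0, 1, 0L, 4L), 2L)
  expect_identical(iwoSeedCount(0.3, 0.3, 0.3, 1L, 4L), 2L)  # degenerate colony
  expect_error(iwoSeedCount(2, 0, 1, 0L, 4L), "outside")

  ctl <- iwoControl(sigmaInitial = 0.5, sigmaFinal = 0.01, m = 1, nIter = 10L)
  expect_equal(iwoSigma(0, ctl), 0.5)
  expect_equal(iwoSigma(10, ctl), 0.01)
  expect_equal(iwoSigma(5, ctl), (0.5 + 0.01) / 2)
  ctl3 <- iwoControl(m = 3, nIter = 10L)
  sig <- vapply(0:10, iwoSigma, numeric(1), control = ctl3)
  expect_true(all(diff(sig) < 0))
  expect_error(iwoSigma(11, ctl), "nIter")
})

test_that("IWO selection is deterministic and respects degenerate configs", {
  toy <- toySelectable()
  # a single weed with no reproduction returns its own decoded subset
  ctl0 <- iwoControl(popInit = 1L, sMax = 1L, yMin = 0L, yMax = 0L, nIter = 1L,
                     seed = 2)
  sel0 <- selectIWO(toy$x, toy$labels, k = 2L, control = ctl0, shape = c(1L, 2L))
  expect_length(selectedPositions(sel0), 2L)
  # determinism
  s1 <- selectIWO(toy$x, toy$labels, k = 2L, control = iwoControl(seed = 7),
                  shape = c(1L, 2L))
  s2 <- selectIWO(toy$x, toy$labels, k = 2L, control = iwoControl(seed = 7),
                  shape = c(1L, 2L))
  expect_identical(selectedPositions(s1), selectedPositions(s2))
  expect_false(is.unsorted(selectedPositions(s1), strictly = TRUE))
  expect_error(selectIWO(toy$x, toy$labels, k = 100L), "exceeds")
})

test_that("IWO and top-k agree where Fisher and KLD rankings coincide", {
  toy <- toySelectable()
  klScores <- rankFeaturesKLD(toy$x, toy$labels)
  topk <- selectTopK(toy$x, klScores, k = 2L, shape = c(1L, 2L))
  iwoSel <- selectIWO(toy$x, toy$labels, k = 2L,
                      control = iwoControl(seed = 1), shape = c(1L, 2L))
  expect_identical(selectedPositions(topk), c(1L, 6L))
  expect_identical(selectedPositions(iwoSel), selectedPositions(topk))
})
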