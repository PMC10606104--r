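test_that("PSO inertia decays linearly between its bounds", {
  ctl <- psoControl(wMax = 0.9, wMin = 0.45, kMax = 100L)
  expect_equal(psoInertia(0, ctl), 0.9)
  expect_equal(psoInertia(100, ctl), 0.45)
  expect_equal(psoInertia(50, ctl), 0.675)
  expect_error(psoInertia(101, ctl), "kMax")
  ws <- vapply(0:100, psoInertia, numeric(1), control = ctl)
  expect_true(all(diff(ws) < 0))
  expect_true(all(ws >= 0.45 & ws <= 0.9))
})

test_that("PSO velocity update matches the closed form", {
  ctl <- psoControl(c1 = 2, c2 = 2, r1 = 0.85, r2 = 0.85, kMax = 10L)
  # converged-swarm fixed point
  upd <- psoVelocityUpdate(x = 1, v = 0, pbest = 1, gbest = 1, k = 0, ctl)
  expect_equal(upd$v, 0); expect_equal(upd$x, 1)
  # inertia-only carry-over
  ctl1 <- psoControl(c1 = 1, c2 = 1, kMax = 10L)
  upd <- psoVelocityUpdate(x = 0, v = 0.3, pbest = 0, gbest = 0, k = 0, ctl1)
  expect_equal(upd$v, 0.9 * 0.3)
  # oracle: direct evaluation of the update
  upd <- psoVelocityUpdate(x = 0, v = 0, pbest = 1, gbest = 2, k = 0, ctl)
  expect_equal(upd$v, 2 * 0.85 * 1 + 2 * 0.85 * 2)
  expect_equal(upd$x, 5.1)
  expect_error(psoVelocityUpdate(c(0, 0), 0, 1, 1, 0, ctl), "mismatch")
})

test_that("GWO control parameter decays linearly from 2 to 0", {
  expect_equal(gwoControlParameter(0, 100), 2)
  expect_equal(gwoControlParameter(100, 100), 0)
  expect_equal(gwoControlParameter(25, 100), 1.5)
  expect_error(gwoControlParameter(1, 0), "positive")
  is <- vapply(0:50, gwoControlParameter, numeric(1), maxIter = 50)
  expect_true(all(diff(is) < 0) && all(is >= 0 & is <= 2))
})

test_that("GWO position update matches the hand-evaluated hunting equations", {
  ctl <- gwoControl(r1 = 0.8, r2 = 0.5)
  # converged pack with A = 0 stays put
  expect_equal(gwoPositionUpdate(1, 1, 1, 1, i = 0, ctl, r2 = 0.5), 1)
  # oracle: scalar case, each leader contributes X_k = 1
  expect_equal(gwoPositionUpdate(0, 1, 1, 1, i = 0, ctl, r2 = 0.5), 1)
  # permutation symmetry when the leaders coincide
  a <- c(0.2, 0.6); x <- c(0, 0)
  expect_equal(gwoPositionUpdate(x, a, a, a, i = 1, ctl),
               gwoPositionUpdate(x, a, a, a, i = 1, ctl))
  expect_error(gwoPositionUpdate(c(0, 0), 1, 1, 1, 1, ctl), "mismatch")
})

test_that("subset fitness is a distribution-preservation score", {
  cst <- rep(0.4, 12)
  expect_equal(subsetFitness(1:6, cst), 0)
  roi <- runif(10)
  expect_equal(subsetFitness(seq_along(roi), roi), 0)  # identity subset
  expect_error(subsetFitness(c(1, 1, 2), roi), "duplicate")
  expect_error(subsetFitness(c(0, 2), roi), "range")
  # oracle: exhaustive enumeration over all choose(6, 3) subsets
  withr::with_seed(5, toy <- runif(6))
  cmb <- combn(6, 3)
  fits <- apply(cmb, 2, function(ix) subsetFitness(ix, toy))
  bestIdx <- sort(cmb[, which.max(fits)])
  expect_true(max(fits) >= fits[1])
  expect_equal(subsetFitness(bestIdx, toy), max(fits))
})

test_that("swarm reducers are deterministic and structurally valid", {
  roi <- toyROI20()
  for (fn in list(
    function(s) reduceIntensitiesPSO(roi, psoControl(nParticles = 8L, kMax = 10L,
                                                     seed = s), shape = c(2L, 4L)),
    function(s) reduceIntensitiesGWO(roi, gwoControl(nWolves = 8L, maxIter = 10L,
                                                     seed = s), shape = c(2L, 4L)))) {
    r1 <- fn(3); r2 <- fn(3); r3 <- fn(4)
    expect_identical(featureValues(r1), featureValues(r2))
    expect_identical(sourceIndices(r1), sourceIndices(r2))
    expect_false(identical(sourceIndices(r1), sourceIndices(r3)) &&
                   identical(featureValues(r1), featureValues(r3)))
    expect_false(is.unsorted(sourceIndices(r1), strictly = TRUE))
    expect_identical(dim(featureValues(r1)), c(2L, 4L))
  }
  # constant ROI: any subset is optimal, fitness exactly 0
  cst <- rep(0.25, 20)
  expect_equal(reduceIntensitiesPSO(cst, psoControl(nParticles = 4L, kMax = 3L),
                                    shape = c(2L, 4L))@fitness, 0)
  expect_equal(reduceIntensitiesGWO(cst, gwoControl(nWolves = 4L, maxIter = 3L),
                                    shape = c(2L, 4L))@fitness, 0)
  expect_error(reduceIntensitiesPSO(roi, shape = c(512L, 10L)), "exceeds")
})

test_that("PSO beats a 50-subset random-search baseline on the toy ROI", {
  roi <- toyROI20()
  wins <- 0L
  for (s in 1:100) {
    pso <- reduceIntensitiesPSO(roi, psoControl(nParticles = 10L, kMax = 30L,
                                                seed = s), shape = c(2L, 4L))
    randBest <- withr::with_seed(s + 1000L, {
      max(vapply(1:50, function(i) {
        subsetFitness(sample.int(20, 8), roi)
      }, numeric(1)))
    })
    if (pso@fitness >= randBest - 1e-12) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})

test_that("class statistics match direct moment computations", {
  dup <- matrix(rep(c(0.2, 0.4, 0.6), 3), 3, 3, byrow = TRUE)
  s <- classStatistics(list(N = dup, ACA = dup + 0.1))
  expect_equal(s$N$pearsonCC, 1)
  expect_equal(s$ACA$pearsonCC, 1)

  expect_warning(
    s0 <- classStatistics(list(N = matrix(0.5, 2, 4), ACA = dup)),
    "constant")
  expect_equal(s0$N$variance, 0)
  expect_equal(s0$N$skewness, 0)

  # oracle: direct moment formula with the bias-correction factor
  v <- c(1, 2, 3, 4, 100)
  n <- length(v)
  m2 <- mean((v - mean(v))^2); m3 <- mean((v - mean(v))^3)
  g1 <- m3 / m2^1.5
  expected <- g1 * sqrt(n * (n - 1)) / (n - 2)
  vs <- matrix(rep(v, 2), 2, 5, byrow = TRUE)
  s1 <- classStatistics(list(N = vs / 100, ACA = vs / 100))
  expect_equal(s1$N$skewness, e1071::skewness(rep(v / 100, 2), type = 2))
  expect_equal(e1071::skewness(v, type = 2), expected, tolerance = 1e-12)
  expect_true(s1$cca >= 0 && s1$cca <= 1)
  expect_error(classStatistics(list(N = dup[1, , drop = FALSE], ACA = dup)),
               ">= 2")
})
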