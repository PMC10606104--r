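test_that("target encoding and decoding follow the gap contract", {
  enc <- targetEncoding()
  expect_equal(unname(enc["benign"]), 0.1)
  expect_equal(unname(enc["aca"]), 0.85)
  expect_gte(enc[["aca"]] - enc[["benign"]], 0.5)
  expect_error(targetEncoding(0.3, 0.6), "gap")

  t <- encodeTargets(c("N", "ACA"))
  expect_equal(t, c(0.1, 0.85))
  expect_identical(as.character(decideClass(t)), c("N", "ACA"))  # round trip
  expect_identical(as.character(decideClass(c(0.85, 0.1, 0.475))),
                   c("ACA", "N", "N"))
  expect_error(decideClass(NaN), "non-finite")
  expect_error(encodeTargets("maybe"), "unknown")
})

test_that("all seven classifiers separate a linearly separable toy", {
  toy <- toySeparable2D()
  for (kind in c("svm", "knn", "rf", "dt", "sdc", "mlp", "bldc")) {
    m <- trainClassifier(toy$x, toy$labels, kind, seed = 1)
    pred <- predict(m, toy$x)
    expect_equal(mean(pred$label == toy$labels), 1,
                 info = paste("classifier", kind))
    expect_true(all(is.finite(pred$score)))
    # repeated prediction is identical
    expect_identical(pred, predict(m, toy$x))
  }
})

test_that("training rejects degenerate inputs", {
  toy <- toySeparable2D()
  expect_error(trainClassifier(toy$x, rep("N", nrow(toy$x)), "knn"), "both")
  bad <- toy$x; bad[1, 1] <- NaN
  expect_error(trainClassifier(bad, toy$labels, "knn"), "non-finite")
  m <- trainClassifier(toy$x, toy$labels, "knn")
  expect_error(predict(m, toy$x[, 1, drop = FALSE]), "dimensionality")
})

test_that("KNN scores are neighbour-target means", {
  x <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1)
  y <- c("N", "N", "N", "ACA", "ACA", "ACA")
  # k = 1 recovers a training point's own target
  m1 <- trainClassifier(x, y, "knn", params = list(k = 1L))
  expect_equal(predict(m1, x)$score, encodeTargets(y))
  # k = 5 on a point surrounded by ACA neighbours votes ACA
  m5 <- trainClassifier(rbind(x, 10.5), c(y, "ACA"), "knn")
  pred <- predict(m5, matrix(11))
  expect_identical(as.character(pred$label), "ACA")
  # oracle: mean of the 5 nearest targets (11, 10.5, 10, 12 are ACA; the
  # fifth neighbour is the N point at 2)
  expect_equal(pred$score, (4 * 0.85 + 0.1) / 5)
})

test_that("SDC follows its limiting and scaling identities", {
  toy <- toySeparable2D(n = 10)
  # large lambda forces the class of an exactly matching training sample
  m <- trainClassifier(toy$x, toy$labels, "sdc", params = list(lambda = 50))
  pred <- predict(m, toy$x[c(1, 15), , drop = FALSE])
  expect_identical(as.character(pred$label), c("N", "ACA"))
  # scale consistency: lambda * c on x equals lambda on sqrt(c) * x
  cScale <- 4
  mA <- trainClassifier(toy$x, toy$labels, "sdc",
                        params = list(lambda = 0.5 * cScale))
  mB <- trainClassifier(toy$x * sqrt(cScale), toy$labels, "sdc",
                        params = list(lambda = 0.5))
  expect_equal(predict(mA, toy$x)$score,
               predict(mB, toy$x * sqrt(cScale))$score, tolerance = 1e-10)
})

test_that("MLP outputs stay inside the sigmoid range", {
  toy <- toySeparable2D(n = 10)
  m <- trainClassifier(toy$x, toy$labels, "mlp", params = list(hidden = 4L),
                       seed = 2)
  probe <- matrix(runif(40, 90, 210), 20, 2)
  s <- predict(m, probe)$score
  expect_true(all(s > 0 & s < 1))
})

test_that("BLDC reduces to least squares in the precision limit", {
  withr::with_seed(11, {
    x <- matrix(rnorm(20), 10, 2)
    y <- rep(c("N", "ACA"), 5)
  })
  m <- trainClassifier(x, y, "bldc",
                       params = list(alphaInit = 1e-12, betaInit = 1e9,
                                     evidenceIter = 0L))
  # oracle: normal-equations solve on the standardized design
  xs <- scale(x)
  Z <- cbind(1, xs)
  qLS <- solve(crossprod(Z), crossprod(Z, encodeTargets(y)))
  expect_equal(m@fit$coef, as.vector(qLS), tolerance = 1e-6)
})

test_that("label symmetry holds for the geometric classifiers", {
  toy <- toySeparable2D(n = 12, seed = 3)
  flip <- ifelse(toy$labels == "N", "ACA", "N")
  symParams <- list(knn = list(), dt = list(classWeight = 0.5),
                    rf = list(classWeight = 0.5), sdc = list())
  for (kind in names(symParams)) {
    mA <- trainClassifier(toy$x, toy$labels, kind,
                          params = symParams[[kind]], seed = 5)
    mB <- trainClassifier(toy$x, flip, kind, params = symParams[[kind]],
                          seed = 5)
    predA <- as.character(predict(mA, toy$x)$label)
    predB <- as.character(predict(mB, toy$x)$label)
    expect_identical(predA, ifelse(predB == "N", "ACA", "N"),
                     info = paste("classifier", kind))
  }
})

test_that("a single unbootstrapped ranger tree matches the CART tree", {
  toy <- toySeparable2D(n = 15, seed = 6)
  rf1 <- trainClassifier(toy$x, toy$labels, "rf",
                         params = list(nTrees = 1L, bootstrapFraction = 1,
                                       replace = FALSE, classWeight = 0.5),
                         seed = 4)
  dt <- trainClassifier(toy$x, toy$labels, "dt",
                        params = list(classWeight = 0.5), seed = 4)
  expect_identical(predict(rf1, toy$x)$label, predict(dt, toy$x)$label)
})
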