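test_that("confusion counting matches a manual tally", {
  cm <- confusion(c("ACA", "ACA", "ACA", "N", "N"),
                  c("ACA", "ACA", "ACA", "N", "N"))
  expect_identical(confusionCounts(cm), c(TP = 3L, TN = 2L, FP = 0L, FN = 0L))
  cmAll <- confusion(rep("ACA", 5), c("ACA", "ACA", "ACA", "N", "N"))
  expect_identical(confusionCounts(cmAll), c(TP = 3L, TN = 0L, FP = 2L, FN = 0L))
  # oracle: manual tally on a random 20-label toy
  withr::with_seed(13, {
    truth <- sample(c("N", "ACA"), 20, replace = TRUE)
    pred <- sample(c("N", "ACA"), 20, replace = TRUE)
  })
  cm <- confusion(pred, truth)
  expect_identical(unname(confusionCounts(cm)),
                   c(sum(pred == "ACA" & truth == "ACA"),
                     sum(pred == "N" & truth == "N"),
                     sum(pred == "ACA" & truth == "N"),
                     sum(pred == "N" & truth == "ACA")))
  expect_error(confusion(c("yes"), c("N")), "unknown")
  expect_error(confusionFromCounts(0, 0, 0, 0), "positive")
})

test_that("metric identities hold on random confusion matrices", {
  withr::with_seed(17, {
    for (i in 1:200) {
      counts <- rpois(4, lambda = sample(c(5, 50, 500), 1))
      if (sum(counts) == 0) counts[1] <- 1
      cm <- confusionFromCounts(counts[1], counts[2], counts[3], counts[4])
      m <- metricsFromConfusion(cm)
      expect_equal(m$accuracy + m$errorRate, 100, tolerance = 1e-9)
      expect_true(m$mcc >= -1 && m$mcc <= 1)
      expect_true(m$kappa >= -1 && m$kappa <= 1)
      expect_true(all(unlist(m[c("accuracy", "f1", "jaccard", "gMean")]) >= 0))
      expect_true(all(unlist(m[c("accuracy", "f1", "jaccard", "gMean")]) <= 100))
      # F1 is the harmonic mean of precision and recall
      TP <- counts[1]; FP <- counts[3]; FN <- counts[4]
      if (TP + FP > 0 && TP + FN > 0 && TP > 0) {
        prec <- TP / (TP + FP); rec <- TP / (TP + FN)
        expect_equal(m$f1, 100 * 2 * prec * rec / (prec + rec),
                     tolerance = 1e-9)
      }
      # MCC sign equals the sign of TP*TN - FP*FN
      det <- counts[1] * counts[2] - counts[3] * counts[4]
      if (!("mcc" %in% m$degenerate) && det != 0) {
        expect_identical(sign(m$mcc), sign(det))
      }
    }
  })
  # perfect and chance-level classifiers
  perfect <- metricsFromConfusion(confusionFromCounts(10, 10, 0, 0))
  expect_equal(perfect$accuracy, 100); expect_equal(perfect$mcc, 1)
  expect_equal(perfect$kappa, 1); expect_equal(perfect$f1, 100)
  chance <- metricsFromConfusion(confusionFromCounts(5, 5, 5, 5))
  expect_equal(chance$mcc, 0); expect_equal(chance$kappa, 0)
})

test_that("mse follows its arithmetic and homogeneity contracts", {
  expect_equal(mse(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(mse(c(0, 1), c(1, 1)), 0.5)
  obs <- c(0.2, 0.5, 0.9); tgt <- c(0.1, 0.85, 0.85)
  expect_equal(mse(tgt + 3 * (obs - tgt), tgt), 9 * mse(obs, tgt))
  expect_error(mse(numeric(0), numeric(0)), "empty")
  expect_error(mse(1, c(1, 2)), "mismatch")
})

test_that("stratified CV partitions the data and pools confusions", {
  withr::with_seed(19, {
    x <- rbind(matrix(rnorm(20, 0.2, 0.01), 10), matrix(rnorm(20, 0.8, 0.01), 10))
  })
  y <- rep(c("N", "ACA"), each = 10)
  # k = 2 on 4 samples: every sample tested exactly once
  res2 <- kfoldCV(x[c(1, 2, 11, 12), ], y[c(1, 2, 11, 12)], kind = "knn",
                  params = list(k = 1L), k = 2L, seed = 1)
  expect_identical(sum(confusionCounts(res2$pooled)), 4L)
  expect_identical(sort(unname(res2$foldAssignment)), c(1L, 1L, 2L, 2L))
  # pooled total equals the dataset size
  res <- kfoldCV(x, y, kind = "knn", k = 5L, seed = 2)
  expect_identical(sum(confusionCounts(res$pooled)), nrow(x))
  # oracle: nearest-neighbour geometry on well-separated classes
  expect_equal(res$metrics$accuracy, 100)
  # per-fold matrices sum to the pooled matrix
  foldSum <- Reduce(`+`, lapply(res$folds, confusionCounts))
  expect_identical(foldSum, confusionCounts(res$pooled))
  expect_error(kfoldCV(x[1:4, ], y[1:4], k = 10L), "smaller")
})

test_that("cross-validation is reproducible under a fixed seed", {
  withr::with_seed(23, {
    x <- rbind(matrix(runif(60, 0, 0.6), 15), matrix(runif(60, 0.4, 1), 15))
  })
  y <- rep(c("N", "ACA"), each = 15)
  a <- kfoldCV(x, y, kind = "dt", selector = "kld", nSelect = 2L,
               selectShape = c(1L, 2L), k = 3L, seed = 7)
  b <- kfoldCV(x, y, kind = "dt", selector = "kld", nSelect = 2L,
               selectShape = c(1L, 2L), k = 3L, seed = 7)
  expect_identical(a$predictions, b$predictions)
  expect_identical(a$foldAssignment, b$foldAssignment)
  expect_identical(confusionCounts(a$pooled), confusionCounts(b$pooled))
})

test_that("deviation analysis centres and regresses as specified", {
  mcc <- c(0.2, 0.5, 0.8); kappa <- c(0.2, 0.5, 0.8)
  d <- deviationAnalysis(mcc, kappa)
  expect_equal(d$slope, 1); expect_equal(d$r2, 1)
  expect_equal(sum(d$mccDeviation), 0); expect_equal(sum(d$kappaDeviation), 0)
  # oracle: closed-form least squares on a 3-point toy
  mcc <- c(0.1, 0.4, 0.7); kap <- c(0.2, 0.3, 0.7)
  d <- deviationAnalysis(mcc, kap)
  dm <- mcc - mean(mcc); dk <- kap - mean(kap)
  slopeLS <- sum(dm * dk) / sum(dm^2)
  expect_equal(d$slope, slopeLS)
  expect_equal(d$r2, cor(dm, dk)^2)
  # constant input flagged, not NaN
  d0 <- deviationAnalysis(c(0.5, 0.5), c(0.1, 0.9))
  expect_true(d0$degenerate); expect_equal(d0$r2, 0)
  expect_error(deviationAnalysis(1, c(1, 2)), "equal-length")
})
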