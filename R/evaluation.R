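#' Build a confusion matrix (positive class = ACA)
#'
#' @param pred predicted labels in `{N, ACA}`.
#' @param truth true labels, same length.
#' @return a [ConfusionMatrix-class].
#' @examples
#' confusion(c("ACA", "N", "ACA"), c("ACA", "N", "N"))
#' @export
confusion <- function(pred, truth) {
  pred <- .checkLabels(pred)
  truth <- .checkLabels(truth)
  if (length(pred) != length(truth) || length(pred) < 1L) {
    stop("pred and truth must have equal positive length", call. = FALSE)
  }
  new("ConfusionMatrix",
      TP = sum(pred == "ACA" & truth == "ACA"),
      TN = sum(pred == "N" & truth == "N"),
      FP = sum(pred == "ACA" & truth == "N"),
      FN = sum(pred == "N" & truth == "ACA"))
}

#' Construct a confusion matrix from raw counts
#'
#' @param TP,TN,FP,FN nonnegative integer counts.
#' @return a [ConfusionMatrix-class].
#' @export
confusionFromCounts <- function(TP, TN, FP, FN) {
  new("ConfusionMatrix", TP = as.integer(TP), TN = as.integer(TN),
      FP = as.integer(FP), FN = as.integer(FN))
}

#' Benchmark metrics from a confusion matrix
#'
#' Computes the standard binary benchmark set: accuracy
#' `(TP+TN)/total`, error rate `1 - accuracy`, F1 `2TP/(2TP+FP+FN)`, Matthews
#' correlation coefficient, Jaccard index `TP/(TP+FP+FN)`, g-mean
#' `sqrt(sensitivity * specificity)` and Cohen's kappa
#' `(Pa - Pe)/(1 - Pe)` with `Pe` the chance agreement. Proportion metrics are
#' reported as percentages in \[0, 100\]; MCC and kappa stay on \[-1, 1\]. Any
#' metric with a zero denominator is reported as 0 and flagged in
#' `degenerate`.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return named list: `accuracy`, `errorRate`, `f1`, `mcc`, `jaccard`,
#'   `gMean`, `kappa`, `degenerate` (character vector of zero-denominator
#'   metrics).
#' @examples
#' metricsFromConfusion(confusionFromCounts(4517, 3984, 1016, 483))$accuracy
#' @export
metricsFromConfusion <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  TP <- as.numeric(cm@TP); TN <- as.numeric(cm@TN)
  FP <- as.numeric(cm@FP); FN <- as.numeric(cm@FN)
  total <- TP + TN + FP + FN
  degenerate <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { degenerate <<- c(degenerate, name); return(0) }
    num / den
  }
  acc <- (TP + TN) / total
  f1 <- safe(2 * TP, 2 * TP + FP + FN, "f1")
  mccDen <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  mcc <- safe(TN * TP - FN * FP, mccDen, "mcc")
  jac <- safe(TP, TP + FP + FN, "jaccard")
  sens <- safe(TP, TP + FN, "gMean")
  spec <- safe(TN, TN + FP, "gMean")
  gm <- sqrt(sens * spec)
  pe <- ((TP + FP) * (TP + FN) + (FN + TN) * (FP + TN)) / total^2
  kappa <- if (pe == 1) { degenerate <- c(degenerate, "kappa"); 0 } else {
    (acc - pe) / (1 - pe)
  }
  list(accuracy = 100 * acc, errorRate = 100 * (1 - acc), f1 = 100 * f1,
       mcc = mcc, jaccard = 100 * jac, gMean = 100 * gm, kappa = kappa,
       degenerate = unique(degenerate))
}

#' Mean squared error between observed scores and targets
#'
#' @param observed,targets numeric vectors of equal positive length.
#' @return nonnegative scalar.
#' @export
mse <- function(observed, targets) {
  if (length(observed) != length(targets)) stop("length mismatch", call. = FALSE)
  if (length(observed) == 0L) stop("empty input", call. = FALSE)
  mean((observed - targets)^2)
}

#' Stratified k-fold cross-validation of the classification stage
#'
#' Splits the images into `k` stratified folds; per fold, feature selection
#' (`kld` or `iwo`) and optional hyperparameter tuning (`adam` or `radam`,
#' with a 90/10 inner validation split of the training fold) are fit on the
#' training images only, the classifier is trained and the held-out fold
#' predicted. Fold confusion matrices are summed and the pooled matrix drives
#' the headline metrics; per-fold metrics are also returned.
#'
#' @param features images x features numeric matrix (extracted intensities).
#' @param labels class labels, one per image.
#' @param kind classifier kind, see [classifierParams()].
#' @param selector `"none"`, `"kld"` or `"iwo"`.
#' @param nSelect positions kept by the selector.
#' @param selectShape per-image grid of the selected matrix.
#' @param tuner `"none"`, `"adam"` or `"radam"`.
#' @param tunerIters Adam iterations inside the tuner.
#' @param k folds (default 10).
#' @param params classifier parameter overrides.
#' @param iwo an [iwoControl()] for the IWO selector.
#' @param encoding a [targetEncoding()].
#' @param seed integer seed (fold assignment, tuning, classifier fits).
#' @return list with `pooled` ([ConfusionMatrix-class]), `metrics` (pooled
#'   metrics list), `folds` (per-fold confusion matrices), `foldMetrics`
#'   (data.frame), `scores` and `predictions` aligned to the input rows.
#' @export
kfoldCV <- function(features, labels, kind = "dt",
                    selector = c("none", "kld", "iwo"), nSelect = 1200L,
                    selectShape = c(100L, 12L),
                    tuner = c("none", "adam", "radam"), tunerIters = 40L,
                    k = 10L, params = NULL, iwo = iwoControl(),
                    encoding = targetEncoding(), seed = 1L) {
  selector <- match.arg(selector)
  tuner <- match.arg(tuner)
  labels <- .checkLabels(labels)
  n <- nrow(features)
  if (n < k) stop("dataset smaller than fold count", call. = FALSE)
  folds <- .stratifiedFolds(labels, k, seed)
  if (any(vapply(seq_len(k), function(f) {
    length(unique(labels[folds != f])) < 2L
  }, logical(1)))) {
    stop("a training split lost one class; reduce k", call. = FALSE)
  }
  cms <- vector("list", k)
  scores <- numeric(n)
  preds <- factor(rep("N", n), levels = .classLevels)
  for (f in seq_len(k)) {
    trIdx <- which(folds != f)
    teIdx <- which(folds == f)
    xTr <- features[trIdx, , drop = FALSE]
    xTe <- features[teIdx, , drop = FALSE]
    yTr <- labels[trIdx]
    if (selector == "kld") {
      sc <- rankFeaturesKLD(xTr, yTr)
      sel <- selectTopK(xTr, sc, k = nSelect, shape = selectShape)
      pos <- selectedPositions(sel)
    } else if (selector == "iwo") {
      iwoF <- iwo; iwoF$seed <- deriveSeed(seed, f, 11L)
      sel <- selectIWO(xTr, yTr, k = nSelect, control = iwoF,
                       shape = selectShape)
      pos <- selectedPositions(sel)
    } else {
      pos <- seq_len(ncol(features))
    }
    xTrS <- xTr[, pos, drop = FALSE]
    xTeS <- xTe[, pos, drop = FALSE]
    fitParams <- params
    if (tuner != "none") {
      inner <- .stratifiedFolds(yTr, 10L, deriveSeed(seed, f, 13L))
      vIdx <- which(inner == 1L)
      if (length(unique(yTr[-vIdx])) == 2L && length(vIdx) > 0L) {
        tdata <- list(xTrain = xTrS[-vIdx, , drop = FALSE],
                      yTrain = yTr[-vIdx],
                      xVal = xTrS[vIdx, , drop = FALSE],
                      yVal = yTr[vIdx])
        tuned <- if (tuner == "adam") {
          tuneAdam(kind, tdata, maxIter = tunerIters, encoding = encoding,
                   seed = deriveSeed(seed, f, 17L))
        } else {
          tuneRAdam(kind, tdata, maxIter = tunerIters, encoding = encoding,
                    seed = deriveSeed(seed, f, 17L))
        }
        space <- hyperparamSpace(kind)
        tunedParams <- .materializeHyperparams(bestHyperparams(tuned)[space$name],
                                               space)
        fitParams <- utils::modifyList(params %||% list(), tunedParams)
      }
    }
    model <- trainClassifier(xTrS, yTr, kind, params = fitParams,
                             encoding = encoding,
                             seed = deriveSeed(seed, f, 19L))
    pred <- predict(model, xTeS)
    scores[teIdx] <- pred$score
    preds[teIdx] <- pred$label
    cms[[f]] <- confusion(pred$label, labels[teIdx])
  }
  counts <- vapply(cms, confusionCounts, numeric(4))
  pooled <- confusionFromCounts(sum(counts["TP", ]), sum(counts["TN", ]),
                                sum(counts["FP", ]), sum(counts["FN", ]))
  foldMetrics <- do.call(rbind, lapply(seq_len(k), function(f) {
    m <- metricsFromConfusion(cms[[f]])
    data.frame(fold = f, accuracy = m$accuracy, errorRate = m$errorRate,
               f1 = m$f1, mcc = m$mcc, jaccard = m$jaccard, gMean = m$gMean,
               kappa = m$kappa)
  }))
  list(pooled = pooled, metrics = metricsFromConfusion(pooled), folds = cms,
       foldMetrics = foldMetrics, scores = scores, predictions = preds,
       foldAssignment = folds)
}

# Stratified fold assignment: within each class, seeded shuffle then round-robin.
.stratifiedFolds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  withr::with_seed(as.integer(seed) %% 2147483629, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Deviation analysis of MCC and kappa across classifiers
#'
#' Centers each list on its mean and regresses the kappa deviations on the
#' MCC deviations by least squares, mirroring the agreement analysis between
#' the two chance-corrected metrics.
#'
#' @param mccList,kappaList numeric vectors of equal length >= 2.
#' @return list with `mccDeviation`, `kappaDeviation`, `slope`, `intercept`,
#'   `r2` (0 with a flag when a list is constant).
#' @export
deviationAnalysis <- function(mccList, kappaList) {
  if (length(mccList) != length(kappaList) || length(mccList) < 2L) {
    stop("need two equal-length vectors of length >= 2", call. = FALSE)
  }
  dm <- mccList - mean(mccList)
  dk <- kappaList - mean(kappaList)
  if (stats::var(dm) == 0 || stats::var(dk) == 0) {
    return(list(mccDeviation = dm, kappaDeviation = dk, slope = 0,
                intercept = 0, r2 = 0, degenerate = TRUE))
  }
  fit <- stats::lm(dk ~ dm)
  # a perfect fit (identical deviation lists) is legitimate here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(mccDeviation = dm, kappaDeviation = dk,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = r2, degenerate = FALSE)
}
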