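#' Numeric target encoding for the two tissue classes
#'
#' Benign images are regressed toward 0.1 and adenocarcinoma images toward
#' 0.85; the decision boundary is the midpoint. The gap must be at least 0.5
#' so that scores can separate the classes despite sigmoid-style shrinkage in
#' the continuous classifiers.
#'
#' @param benign target for class `N`, default 0.1.
#' @param aca target for class `ACA`, default 0.85.
#' @return named numeric vector `c(benign, aca, boundary)`.
#' @examples
#' targetEncoding()
#' @export
targetEncoding <- function(benign = 0.1, aca = 0.85) {
  if (aca - benign < 0.5) {
    stop("target gap aca - benign must be >= 0.5", call. = FALSE)
  }
  c(benign = benign, aca = aca, boundary = (benign + aca) / 2)
}

#' Encode class labels as numeric regression targets
#'
#' @param labels labels in `{N, ACA}`.
#' @param encoding a [targetEncoding()].
#' @return numeric vector of targets.
#' @examples
#' encodeTargets(c("N", "ACA"))
#' @export
encodeTargets <- function(labels, encoding = targetEncoding()) {
  labels <- .checkLabels(labels)
  ifelse(labels == "ACA", encoding[["aca"]], encoding[["benign"]])
}

#' Decode a continuous score to a class label
#'
#' Nearest-target rule: `ACA` iff the score is strictly closer to the ACA
#' target than to the benign target; ties (the exact midpoint) go to `N`.
#'
#' @param score finite numeric score(s) in target space.
#' @param encoding a [targetEncoding()].
#' @return factor with levels `N`, `ACA`.
#' @examples
#' decideClass(c(0.1, 0.85, 0.475))
#' @export
decideClass <- function(score, encoding = targetEncoding()) {
  if (any(!is.finite(score))) stop("non-finite score", call. = FALSE)
  aca <- abs(score - encoding[["aca"]]) < abs(score - encoding[["benign"]])
  factor(ifelse(aca, "ACA", "N"), levels = .classLevels)
}

#' Default classifier parameters
#'
#' Per-classifier parameter bundles: RBF-SVM (kernel width `sigma = 100`,
#' cost `alpha = 1`, with `w = 0.85`, `b = 0.01` recorded as initialization
#' metadata only -- the solver determines the separating function), KNN
#' (`k = 5`, Euclidean, vote weight 0.5), random forest (200 trees, depth 10,
#' 20% bootstrap sample, class weight 0.45 on the positive class), decision
#' tree (depth 20, class weight 0.4), softmax discriminant (`lambda = 0.5`),
#' multilayer perceptron (learning rate 0.3, hidden units swept up to 32),
#' Bayesian linear discriminant (prior 0.5, noise precision initialized at 1
#' and re-estimated by evidence iteration).
#'
#' @param kind one of `"svm"`, `"knn"`, `"rf"`, `"dt"`, `"sdc"`, `"mlp"`,
#'   `"bldc"`.
#' @return named list of parameters.
#' @export
classifierParams <- function(kind) {
  switch(match.arg(kind, .classifierKinds),
    svm = list(sigma = 100, cost = 1, w = 0.85, b = 0.01),
    knn = list(k = 5L, weight = 0.5),
    rf = list(nTrees = 200L, maxDepth = 10L, bootstrapFraction = 0.2,
              classWeight = 0.45, replace = TRUE),
    dt = list(maxDepth = 20L, classWeight = 0.4),
    sdc = list(lambda = 0.5),
    mlp = list(learningRate = 0.3, hidden = NA_integer_, maxHidden = 32L,
               maxIter = 1000L, tolMSE = 1e-5),
    bldc = list(prior = 0.5, betaInit = 1, alphaInit = 1e-3,
                evidenceIter = 50L))
}

.classifierKinds <- c("svm", "knn", "rf", "dt", "sdc", "mlp", "bldc")

#' Train one of the seven binary classifiers
#'
#' Uniform training facade. All classifiers regress or classify toward the
#' numeric target encoding ([targetEncoding()]); [predict()] on the returned
#' model yields continuous scores in target space plus decoded labels.
#'
#' Kinds: `svm` (epsilon-regression with RBF kernel of width `sigma`,
#' `gamma = 1/(2 sigma^2)`), `knn` (k nearest Euclidean neighbours, score =
#' mean neighbour target), `rf` (Gini probability forest), `dt` (CART with
#' Gini impurity and class case-weights), `sdc` (softmax discriminant: class
#' score `log sum_k exp(-lambda ||w - w_k^j||^2)`), `mlp` (one sigmoid hidden
#' layer trained by backpropagation gradient descent on squared error, inputs
#' standardized internally), `bldc` (Bayesian linear discriminant: regularized
#' least squares on the targets with noise precision and weight-prior scale
#' re-estimated by evidence iteration).
#'
#' @param x numeric feature matrix (rows = samples).
#' @param labels class labels in `{N, ACA}`, both classes present.
#' @param kind classifier kind, see [classifierParams()].
#' @param params parameter list (defaults from [classifierParams()]).
#' @param encoding a [targetEncoding()].
#' @param seed integer seed for any stochastic component.
#' @return a [TrainedModel-class].
#' @examples
#' x <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 4), 10))
#' y <- rep(c("N", "ACA"), each = 10)
#' m <- trainClassifier(x, y, "knn")
#' predict(m, x)$label
#' @export
trainClassifier <- function(x, labels, kind, params = NULL,
                            encoding = targetEncoding(), seed = 1L) {
  kind <- match.arg(kind, .classifierKinds)
  params <- utils::modifyList(classifierParams(kind), params %||% list())
  x <- as.matrix(x)
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite features", call. = FALSE)
  labels <- .checkLabels(labels)
  if (length(unique(labels)) < 2L) {
    stop("training requires both classes", call. = FALSE)
  }
  if (nrow(x) != length(labels)) stop("feature/label length mismatch", call. = FALSE)
  targets <- encodeTargets(labels, encoding)
  fit <- switch(kind,
    svm = .fitSVM(x, targets, params),
    knn = list(x = x, targets = targets, k = as.integer(params$k)),
    rf = .fitRF(x, labels, params, seed),
    dt = .fitDT(x, labels, params),
    sdc = list(classSamples = split.data.frame(x, labels),
               lambda = params$lambda),
    mlp = .fitMLP(x, targets, params, seed),
    bldc = .fitBLDC(x, targets, params))
  new("TrainedModel", kind = kind, fit = fit, encoding = encoding,
      featureDim = ncol(x), seed = as.integer(seed))
}

.fitSVM <- function(x, targets, params) {
  gamma <- 1 / (2 * params$sigma^2)
  list(model = e1071::svm(x, targets, type = "eps-regression",
                          kernel = "radial", gamma = gamma,
                          cost = params$cost, scale = FALSE),
       meta = params[c("w", "b")])
}

.fitRF <- function(x, labels, params, seed) {
  w <- params$classWeight
  caseWeights <- ifelse(labels == "ACA", w, 1 - w)
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  model <- ranger::ranger(x = df, y = labels,
                          num.trees = params$nTrees,
                          max.depth = params$maxDepth,
                          sample.fraction = params$bootstrapFraction,
                          replace = params$replace,
                          case.weights = caseWeights,
                          min.node.size = 1L,
                          probability = TRUE, seed = seed,
                          num.threads = 1L)
  list(model = model, featureNames = names(df))
}

.fitDT <- function(x, labels, params) {
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  df$.y <- labels
  w <- params$classWeight
  caseWeights <- ifelse(labels == "ACA", w, 1 - w)
  model <- rpart::rpart(.y ~ ., data = df, weights = caseWeights,
                        method = "class", parms = list(split = "gini"),
                        control = rpart::rpart.control(
                          maxdepth = min(30L, params$maxDepth),
                          cp = 0, minsplit = 2L, minbucket = 1L, xval = 0L))
  list(model = model, featureNames = setdiff(names(df), ".y"))
}

.standardize <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  list(x = sweep(sweep(x, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# Backpropagation gradient descent for a 1-hidden-layer sigmoid network,
# stopping at MSE <= tol or maxIter epochs (full-batch).
.trainMLPWeights <- function(xs, targets, hidden, lr, maxIter, tol, seed) {
  n <- nrow(xs); p <- ncol(xs)
  withr::with_seed(seed, {
    W1 <- matrix(stats::runif(p * hidden, -0.5, 0.5), p, hidden)
    b1 <- stats::runif(hidden, -0.5, 0.5)
    w2 <- stats::runif(hidden, -0.5, 0.5)
    b2 <- stats::runif(1, -0.5, 0.5)
  })
  for (it in seq_len(maxIter)) {
    H <- .sigmoid(sweep(xs %*% W1, 2, b1, "+"))
    o <- as.vector(.sigmoid(H %*% w2 + b2))
    err <- o - targets
    if (mean(err^2) <= tol) break
    dO <- (2 / n) * err * o * (1 - o)
    gw2 <- as.vector(crossprod(H, dO))
    gb2 <- sum(dO)
    dH <- outer(dO, w2) * H * (1 - H)
    gW1 <- crossprod(xs, dH)
    gb1 <- colSums(dH)
    W1 <- W1 - lr * gW1; b1 <- b1 - lr * gb1
    w2 <- w2 - lr * gw2; b2 <- b2 - lr * gb2
  }
  list(W1 = W1, b1 = b1, w2 = w2, b2 = b2,
       mse = mean(( .sigmoid(sweep(xs %*% W1, 2, b1, "+") %*% w2 + b2) - targets)^2))
}

.fitMLP <- function(x, targets, params, seed) {
  std <- .standardize(x)
  hidden <- params$hidden
  if (is.na(hidden)) {
    # sweep hidden-unit counts; keep the first count past which validation
    # MSE stops improving, capped at maxHidden
    candidates <- c(2L, 4L, 8L, 16L, 32L)
    candidates <- candidates[candidates <= params$maxHidden]
    n <- nrow(std$x)
    val <- withr::with_seed(seed, sample.int(n, max(2L, floor(n / 4))))
    tr <- setdiff(seq_len(n), val)
    if (length(tr) < 2L) { tr <- seq_len(n); val <- seq_len(n) }
    best <- candidates[1]; bestMSE <- Inf
    for (h in candidates) {
      wts <- .trainMLPWeights(std$x[tr, , drop = FALSE], targets[tr], h,
                              params$learningRate, 200L, params$tolMSE,
                              deriveSeed(seed, h))
      o <- .sigmoid(sweep(std$x[val, , drop = FALSE] %*% wts$W1, 2, wts$b1, "+")
                    %*% wts$w2 + wts$b2)
      mseVal <- mean((as.vector(o) - targets[val])^2)
      if (mseVal < bestMSE - 1e-9) { bestMSE <- mseVal; best <- h } else break
    }
    hidden <- best
  }
  wts <- .trainMLPWeights(std$x, targets, hidden, params$learningRate,
                          params$maxIter, params$tolMSE, seed)
  c(wts, list(center = std$center, scale = std$scale, hidden = hidden))
}

.fitBLDC <- function(x, targets, params) {
  std <- .standardize(x)
  Z <- cbind(1, std$x)
  n <- nrow(Z); d <- ncol(Z)
  ZtZ <- crossprod(Z)
  Zty <- as.vector(crossprod(Z, targets))
  ev <- eigen(ZtZ, symmetric = TRUE, only.values = TRUE)$values
  ev[ev < 0] <- 0
  alpha <- params$alphaInit
  beta <- params$betaInit
  q <- rep(0, d)
  for (it in seq_len(params$evidenceIter + 1L)) {
    q <- solve(alpha * diag(d) + beta * ZtZ, beta * Zty)
    if (it > params$evidenceIter) break
    gamma <- sum(beta * ev / (alpha + beta * ev))
    alpha <- max(gamma, 1e-10) / max(sum(q^2), 1e-12)
    resid <- sum((targets - as.vector(Z %*% q))^2)
    beta <- min(1e10, max(n - gamma, 1e-10) / max(resid, 1e-12))
  }
  list(coef = q, alpha = alpha, beta = beta, prior = params$prior,
       center = std$center, scale = std$scale)
}

#' Predict from a trained classifier
#'
#' Returns the continuous score in target space and the decoded class label
#' for every row of `newdata`. Deterministic given the model.
#'
#' @param object a [TrainedModel-class].
#' @param newdata numeric matrix with the training dimensionality.
#' @param ... ignored.
#' @return list with numeric `score` and factor `label`.
#' @export
setMethod("predict", "TrainedModel", function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != object@featureDim) {
    stop("feature dimensionality mismatch", call. = FALSE)
  }
  enc <- object@encoding
  score <- switch(object@kind,
    svm = as.vector(stats::predict(object@fit$model, x)),
    knn = .predictKNN(object@fit, x),
    rf = {
      df <- as.data.frame(x); names(df) <- object@fit$featureNames
      p <- stats::predict(object@fit$model, data = df)$predictions[, "ACA"]
      enc[["benign"]] + p * (enc[["aca"]] - enc[["benign"]])
    },
    dt = {
      df <- as.data.frame(x); names(df) <- object@fit$featureNames
      p <- stats::predict(object@fit$model, newdata = df, type = "prob")[, "ACA"]
      enc[["benign"]] + p * (enc[["aca"]] - enc[["benign"]])
    },
    sdc = .predictSDC(object@fit, x, enc),
    mlp = {
      xs <- sweep(sweep(x, 2, object@fit$center), 2, object@fit$scale, "/")
      as.vector(.sigmoid(sweep(xs %*% object@fit$W1, 2, object@fit$b1, "+")
                         %*% object@fit$w2 + object@fit$b2))
    },
    bldc = {
      xs <- sweep(sweep(x, 2, object@fit$center), 2, object@fit$scale, "/")
      as.vector(cbind(1, xs) %*% object@fit$coef)
    })
  list(score = unname(score), label = decideClass(unname(score), enc))
})

.predictKNN <- function(fit, x) {
  # squared Euclidean cross-distances, vectorized
  d2 <- outer(rowSums(x^2), rowSums(fit$x^2), "+") - 2 * tcrossprod(x, fit$x)
  k <- min(fit$k, ncol(d2))
  apply(d2, 1, function(row) mean(fit$targets[order(row)[seq_len(k)]]))
}

.logSumExp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

.predictSDC <- function(fit, x, enc) {
  zByClass <- vapply(.classLevels, function(cl) {
    ref <- as.matrix(fit$classSamples[[cl]])
    d2 <- outer(rowSums(x^2), rowSums(ref^2), "+") - 2 * tcrossprod(x, ref)
    d2[d2 < 0] <- 0
    apply(-fit$lambda * d2, 1, .logSumExp)
  }, numeric(nrow(x)))
  zByClass <- matrix(zByClass, nrow = nrow(x))
  # softmax posterior for the positive class, mapped to target space
  p <- 1 / (1 + exp(zByClass[, 1] - zByClass[, 2]))
  enc[["benign"]] + p * (enc[["aca"]] - enc[["benign"]])
}
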