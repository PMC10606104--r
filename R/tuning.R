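#' Adam optimizer state for hyperparameter search
#'
#' Creates the initial state of the finite-difference Adam loop: the continuous
#' relaxation `x` of the tuned hyperparameters plus zeroed first/second moment
#' vectors. Constants follow the hyperparameter-tuning configuration: learning
#' rate 0.001, moment decays `Z1 = 0.89`, `Z2 = 0.9`, `eps = 1e-9`, 40
#' iterations.
#'
#' @param x named numeric vector of initial hyperparameter values.
#' @param Lr learning rate.
#' @param Z1,Z2 first/second moment decay constants.
#' @param eps numerical stabilizer.
#' @param maxIter Adam iterations.
#' @return list of class `AdamState`.
#' @export
adamState <- function(x, Lr = 0.001, Z1 = 0.89, Z2 = 0.9, eps = 1e-9,
                      maxIter = 40L) {
  structure(list(x = x, m = numeric(length(x)), p = numeric(length(x)),
                 t = 0L, Lr = Lr, Z1 = Z1, Z2 = Z2, eps = eps,
                 maxIter = as.integer(maxIter)),
            class = "AdamState")
}

#' One Adam update step
#'
#' Standard Adam with bias correction:
#' `m <- Z1 m + (1-Z1) g`, `p <- Z2 p + (1-Z2) g^2`,
#' `Mhat = m / (1 - Z1^t)`, `Phat = p / (1 - Z2^t)`,
#' `x <- x - Lr / (eps + sqrt(Phat)) * Mhat`.
#'
#' @param state an [adamState()].
#' @param grad finite gradient vector of the same length as `state$x`.
#' @return updated state.
#' @examples
#' s <- adamState(c(d = 10))
#' adamUpdate(s, c(d = 1))$x # decreases by ~0.001
#' @export
adamUpdate <- function(state, grad) {
  if (any(!is.finite(grad))) stop("non-finite gradient", call. = FALSE)
  if (length(grad) != length(state$x)) stop("gradient length mismatch", call. = FALSE)
  state$t <- state$t + 1L
  state$m <- state$Z1 * state$m + (1 - state$Z1) * grad
  state$p <- state$Z2 * state$p + (1 - state$Z2) * grad^2
  mHat <- state$m / (1 - state$Z1^state$t)
  pHat <- state$p / (1 - state$Z2^state$t)
  state$x <- state$x - state$Lr / (state$eps + sqrt(pHat)) * mHat
  state
}

#' Finite-difference loss gradient from consecutive error rates
#'
#' First iteration: `ER / x` componentwise; later iterations: the secant
#' `(ER_t - ER_{t-1}) / (x_t - x_{t-1})` componentwise. A zero denominator
#' carries no information and yields a zero gradient component (with a
#' warning).
#'
#' @param erCurr,erPrev current and previous validation error rates.
#' @param xCurr,xPrev current and previous hyperparameter vectors.
#' @param tr current iteration (>= 1).
#' @return gradient vector.
#' @export
lossGradient <- function(erCurr, erPrev, xCurr, xPrev, tr) {
  if (tr < 1) stop("tr must be >= 1", call. = FALSE)
  if (tr == 1) {
    denom <- xCurr
  } else {
    denom <- xCurr - xPrev
  }
  zero <- denom == 0
  if (any(zero)) warning("zero denominator in gradient; component set to 0")
  num <- if (tr == 1) rep(erCurr, length(xCurr)) else rep(erCurr - erPrev, length(xCurr))
  g <- ifelse(zero, 0, num / denom)
  unname(g)
}

#' Tunable hyperparameter space per classifier
#'
#' Names, bounds, integer flags and initial values of the hyperparameters the
#' Adam/RAdam loops adjust for each classifier kind (the continuous knobs of
#' the default parameter bundles).
#'
#' @param kind classifier kind, see [classifierParams()].
#' @return data.frame with columns `name`, `lower`, `upper`, `integer`, `init`.
#' @export
hyperparamSpace <- function(kind) {
  kind <- match.arg(kind, .classifierKinds)
  spec <- switch(kind,
    dt = list(c("maxDepth", 1, 30, TRUE, 20)),
    rf = list(c("nTrees", 10, 300, TRUE, 200), c("maxDepth", 1, 30, TRUE, 10)),
    knn = list(c("k", 1, 15, TRUE, 5)),
    svm = list(c("sigma", 1, 300, FALSE, 100), c("cost", 0.1, 10, FALSE, 1)),
    sdc = list(c("lambda", 0.01, 5, FALSE, 0.5)),
    mlp = list(c("learningRate", 0.01, 1, FALSE, 0.3),
               c("hidden", 2, 32, TRUE, 8)),
    bldc = list(c("betaInit", 0.1, 100, FALSE, 1)))
  out <- do.call(rbind, lapply(spec, function(s) {
    data.frame(name = s[1], lower = as.numeric(s[2]), upper = as.numeric(s[3]),
               integer = as.logical(s[4]), init = as.numeric(s[5]))
  }))
  rownames(out) <- NULL
  out
}

# Clip to bounds and round integer-tagged dimensions.
.materializeHyperparams <- function(x, space) {
  x <- pmin(space$upper, pmax(space$lower, x))
  vals <- ifelse(space$integer, round(x), x)
  stats::setNames(as.list(vals), space$name)
}

# Fit at hyperparameters x and return the validation error rate; an
# unfittable configuration counts as ER = 1 so the loop continues.
.evalHyperparams <- function(x, space, kind, data, encoding, seed) {
  params <- .materializeHyperparams(x, space)
  if (kind == "mlp") params$hidden <- as.integer(params$hidden)
  er <- tryCatch({
    model <- trainClassifier(data$xTrain, data$yTrain, kind, params = params,
                             encoding = encoding, seed = seed)
    pred <- predict(model, data$xVal)
    mean(pred$label != .checkLabels(data$yVal))
  }, error = function(e) 1)
  er
}

#' Tune classifier hyperparameters with finite-difference Adam
#'
#' Runs a fixed-length Adam loop on the continuous relaxation of the
#' classifier's hyperparameters: each iteration fits the classifier at the
#' current (clipped, integer-rounded) values, computes the validation error
#' rate from the held-out confusion, forms the secant gradient
#' ([lossGradient()]) and applies [adamUpdate()]. The best-ever configuration
#' is returned; the best error rate is monotone nonincreasing over the trace.
#'
#' @param kind classifier kind.
#' @param data list with `xTrain`, `yTrain`, `xVal`, `yVal`.
#' @param init named numeric initial values (defaults from
#'   [hyperparamSpace()]).
#' @param maxIter Adam iterations (default 40).
#' @param encoding a [targetEncoding()].
#' @param seed integer seed passed to classifier fits.
#' @return a [TuningResult-class].
#' @export
tuneAdam <- function(kind, data, init = NULL, maxIter = 40L,
                     encoding = targetEncoding(), seed = 1L) {
  kind <- match.arg(kind, .classifierKinds)
  space <- hyperparamSpace(kind)
  x <- if (is.null(init)) space$init else unname(init[space$name])
  state <- adamState(stats::setNames(x, space$name), maxIter = maxIter)
  bestX <- x; bestER <- Inf
  xPrev <- x; erPrev <- NA_real_
  rows <- vector("list", maxIter)
  for (tr in seq_len(maxIter)) {
    xc <- pmin(space$upper, pmax(space$lower, state$x))
    er <- .evalHyperparams(xc, space, kind, data, encoding, seed)
    if (er < bestER) { bestER <- er; bestX <- xc }
    rows[[tr]] <- data.frame(iteration = tr, phase = "adam",
                             t(stats::setNames(xc, space$name)),
                             errorRate = er)
    grad <- suppressWarnings(
      lossGradient(er, erPrev, xc, xPrev, tr))
    xPrev <- xc; erPrev <- er
    state$x <- xc
    state <- adamUpdate(state, grad)
  }
  trace <- do.call(rbind, rows)
  new("TuningResult", best = stats::setNames(as.numeric(bestX), space$name),
      bestER = bestER, trace = trace)
}

#' Tune hyperparameters with Adam plus controlled randomization
#'
#' Runs [tuneAdam()], then `randIters` controlled-randomization rounds around
#' the incumbent: with probability `solutionConsideringRate` the candidate
#' stays at the incumbent values, nested-perturbed by
#' `bandwidth * U(0, 0.1)` with probability `solutionAdjustingRate`; otherwise
#' the candidate is resampled at `lower + bandwidth * U(0, 1)`. All candidates
#' are clipped to bounds and evaluated by refitting; since the evaluated set is
#' a superset of the Adam candidates, the returned error rate never exceeds
#' [tuneAdam()]'s on the same data and seed.
#'
#' @inheritParams tuneAdam
#' @param bandwidth perturbation scale (default 0.0098).
#' @param randIters randomization rounds (default 15).
#' @param solutionConsideringRate probability of refining the incumbent
#'   rather than resampling (default 0.6).
#' @param solutionAdjustingRate probability of the nested perturbation
#'   (default 0.92).
#' @return a [TuningResult-class].
#' @export
tuneRAdam <- function(kind, data, init = NULL, maxIter = 40L,
                      bandwidth = 0.0098, randIters = 15L,
                      solutionConsideringRate = 0.6,
                      solutionAdjustingRate = 0.92,
                      encoding = targetEncoding(), seed = 1L) {
  .assertScalarNumeric(bandwidth, "bandwidth", 1e-12)
  .assertScalarNumeric(solutionConsideringRate, "solutionConsideringRate", 0, 1)
  .assertScalarNumeric(solutionAdjustingRate, "solutionAdjustingRate", 0, 1)
  adam <- tuneAdam(kind, data, init = init, maxIter = maxIter,
                   encoding = encoding, seed = seed)
  space <- hyperparamSpace(kind)
  bestX <- unname(bestHyperparams(adam)[space$name])
  bestER <- bestErrorRate(adam)
  rows <- list(tuningTrace(adam))
  # dedicated randomization stream, independent of the classifier seeds
  withr::with_seed(deriveSeed(seed, 7919L), {
    for (it in seq_len(randIters)) {
      cand <- bestX
      if (stats::runif(1) < solutionConsideringRate) {
        if (stats::runif(1) < solutionAdjustingRate) {
          cand <- cand + bandwidth * stats::runif(length(cand), 0, 0.1)
        }
      } else {
        cand <- space$lower + bandwidth * stats::runif(length(cand))
      }
      cand <- pmin(space$upper, pmax(space$lower, cand))
      er <- .evalHyperparams(cand, space, kind, data,
                             encoding, seed)
      if (er < bestER) { bestER <- er; bestX <- cand }
      rows[[length(rows) + 1L]] <-
        data.frame(iteration = maxIter + it, phase = "radam",
                   t(stats::setNames(cand, space$name)), errorRate = er)
    }
  })
  trace <- do.call(rbind, rows)
  new("TuningResult", best = stats::setNames(as.numeric(bestX), space$name),
      bestER = bestER, trace = trace)
}
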