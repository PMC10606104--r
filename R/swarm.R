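#' Control parameters for PSO intensity reduction
#'
#' Inertia decays linearly from `wMax` to `wMin` over `kMax` iterations; the
#' control draws `r1`, `r2` are fixed constants (0.85) rather than uniform
#' random values, so a run is deterministic given the seed used for particle
#' initialization. Set `stochastic = TRUE` to restore U(0,1) draws.
#'
#' @param nParticles particles in the swarm.
#' @param wMax,wMin inertia bounds (defaults 0.9 and 0.45).
#' @param c1,c2 cognitive/social acceleration coefficients in \[1, 2\].
#' @param r1,r2 fixed control values in \[0, 1\], default 0.85.
#' @param kMax iterations.
#' @param stochastic if TRUE, draw `r1`, `r2` uniformly each update.
#' @param seed integer seed.
#' @return validated list of class `PSOControl`.
#' @export
psoControl <- function(nParticles = 20L, wMax = 0.9, wMin = 0.45,
                       c1 = 1.5, c2 = 1.5, r1 = 0.85, r2 = 0.85,
                       kMax = 100L, stochastic = FALSE, seed = 1L) {
  .assertScalarNumeric(wMax, "wMax"); .assertScalarNumeric(wMin, "wMin")
  if (wMin >= wMax) stop("wMin must be < wMax", call. = FALSE)
  .assertScalarNumeric(c1, "c1", 1, 2); .assertScalarNumeric(c2, "c2", 1, 2)
  .assertScalarNumeric(r1, "r1", 0, 1); .assertScalarNumeric(r2, "r2", 0, 1)
  kMax <- as.integer(kMax)
  if (is.na(kMax) || kMax < 1L) stop("kMax must be >= 1", call. = FALSE)
  structure(list(nParticles = as.integer(nParticles), wMax = wMax, wMin = wMin,
                 c1 = c1, c2 = c2, r1 = r1, r2 = r2, kMax = kMax,
                 stochastic = isTRUE(stochastic), seed = as.integer(seed)),
            class = "PSOControl")
}

#' Control parameters for GWO intensity reduction
#'
#' The exploration coefficient decays linearly from 2 to 0
#' ([gwoControlParameter()]); `r1`, `r2` are fixed at 0.8 (controlled
#' randomization) unless `stochastic = TRUE`.
#'
#' @param nWolves pack size.
#' @param r1,r2 fixed control values in \[0, 1\], default 0.8.
#' @param maxIter iterations.
#' @param stochastic if TRUE, draw `r1`, `r2` uniformly each update.
#' @param seed integer seed.
#' @return validated list of class `GWOControl`.
#' @export
gwoControl <- function(nWolves = 20L, r1 = 0.8, r2 = 0.8, maxIter = 100L,
                       stochastic = FALSE, seed = 1L) {
  .assertScalarNumeric(r1, "r1", 0, 1); .assertScalarNumeric(r2, "r2", 0, 1)
  maxIter <- as.integer(maxIter)
  if (is.na(maxIter) || maxIter < 1L) stop("maxIter must be >= 1", call. = FALSE)
  structure(list(nWolves = as.integer(nWolves), r1 = r1, r2 = r2,
                 maxIter = maxIter, stochastic = isTRUE(stochastic),
                 seed = as.integer(seed)),
            class = "GWOControl")
}

#' Linearly decaying PSO inertia weight
#'
#' `w(k) = wMax - (wMax - wMin) * k / kMax`: `wMax` at `k = 0`, `wMin` at
#' `k = kMax`.
#'
#' @param k iteration in `[0, kMax]`.
#' @param control a [psoControl()] bundle.
#' @return scalar inertia weight.
#' @export
psoInertia <- function(k, control = psoControl()) {
  if (k < 0 || k > control$kMax) stop("k must be in [0, kMax]", call. = FALSE)
  control$wMax - (control$wMax - control$wMin) * k / control$kMax
}

#' PSO velocity and position update
#'
#' `v' = w(k) v + c1 r1 (pbest - x) + c2 r2 (gbest - x)` followed by
#' `x' = x + v'`.
#'
#' @param x,v current position and velocity vectors.
#' @param pbest,gbest personal and global best positions.
#' @param k current iteration (for the inertia schedule).
#' @param control a [psoControl()] bundle.
#' @param r1,r2 override draws (used internally for the stochastic variant).
#' @return list with updated `x` and `v`.
#' @export
psoVelocityUpdate <- function(x, v, pbest, gbest, k, control = psoControl(),
                              r1 = control$r1, r2 = control$r2) {
  lens <- lengths(list(x, v, pbest, gbest))
  if (length(unique(lens)) != 1L) stop("vector length mismatch", call. = FALSE)
  w <- psoInertia(k, control)
  vNew <- w * v + control$c1 * r1 * (pbest - x) + control$c2 * r2 * (gbest - x)
  list(x = x + vNew, v = vNew)
}

#' GWO exploration control parameter
#'
#' Linearly decreased from 2 at the first iteration to 0 at the last:
#' `i = 2 - 2 * iter / maxIter`.
#'
#' @param iter iteration in `[0, maxIter]`.
#' @param maxIter total iterations (> 0).
#' @return scalar in \[0, 2\].
#' @export
gwoControlParameter <- function(iter, maxIter) {
  if (maxIter <= 0) stop("maxIter must be positive", call. = FALSE)
  if (iter < 0 || iter > maxIter) stop("iter must be in [0, maxIter]", call. = FALSE)
  2 - iter * 2 / maxIter
}

#' GWO position update toward the three leading wolves
#'
#' For each leader `L` in (alpha, beta, gamma):
#' `D_L = |B * X_L - X|`, `X_L' = X_L - A * D_L` with `A = 2 i r1 - i` and
#' `B = 2 r2`; the new position is the average `(X_1' + X_2' + X_3') / 3`.
#'
#' @param x current wolf position vector.
#' @param alpha,beta,gamma positions of the three best wolves.
#' @param i exploration parameter from [gwoControlParameter()].
#' @param control a [gwoControl()] bundle.
#' @param r1,r2 override draws (used internally for the stochastic variant).
#' @return updated position vector.
#' @export
gwoPositionUpdate <- function(x, alpha, beta, gamma, i, control = gwoControl(),
                              r1 = control$r1, r2 = control$r2) {
  lens <- lengths(list(x, alpha, beta, gamma))
  if (length(unique(lens)) != 1L) stop("vector length mismatch", call. = FALSE)
  A <- 2 * i * r1 - i
  B <- 2 * r2
  x1 <- alpha - A * abs(B * alpha - x)
  x2 <- beta - A * abs(B * beta - x)
  x3 <- gamma - A * abs(B * gamma - x)
  (x1 + x2 + x3) / 3
}

#' Distribution-preservation fitness of an index subset
#'
#' Scores how faithfully the subset of ROI intensities preserves the full
#' vector's distribution:
#' `f = -|mean(sub) - mean(full)| - |var(sub) - var(full)| - JSD(hist_sub, hist_full)`
#' with 32-bin histograms over \[0, 1\]. The maximum is 0, attained when the
#' subset's distribution matches the full vector's.
#'
#' @param indices unique 1-based positions into `roi`.
#' @param roi full ROI intensity vector.
#' @param bins histogram bins (default 32).
#' @return scalar fitness (<= 0), higher is better.
#' @export
subsetFitness <- function(indices, roi, bins = 32L) {
  if (anyDuplicated(indices)) stop("duplicate indices in candidate", call. = FALSE)
  if (any(indices < 1L) || any(indices > length(roi))) {
    stop("indices out of range", call. = FALSE)
  }
  sub <- roi[indices]
  fullVar <- stats::var(roi)
  subVar <- if (length(sub) > 1L) stats::var(sub) else 0
  -abs(mean(sub) - mean(roi)) - abs(subVar - fullVar) -
    .jsd(.histProbs(sub, bins), .histProbs(roi, bins))
}

# Decode continuous random keys to a subset: the k smallest keys win.
.decodeKeys <- function(keys, k) sort(order(keys)[seq_len(k)])

# Shared post-processing: wrap the winning subset as a ReducedFeatures matrix.
.wrapReduced <- function(roi, indices, fitness, shape) {
  vals <- matrix(roi[indices], nrow = shape[1], ncol = shape[2], byrow = TRUE)
  new("ReducedFeatures", values = vals, sourceIndices = as.integer(indices),
      fitness = fitness)
}

.checkReductionArgs <- function(roi, shape) {
  if (is(roi, "SegmentedROI")) roi <- roi@values
  k <- prod(shape)
  if (k > length(roi)) stop("subset size exceeds ROI length", call. = FALSE)
  roi
}

#' Reduce ROI intensities with particle swarm optimization
#'
#' Particles are continuous random-key vectors over the ROI positions; the
#' `k = prod(shape)` smallest keys of a particle select its subset, which is
#' scored by [subsetFitness()]. The first particle's keys are initialized from
#' the ROI intensities themselves; the rest start uniform. The global-best
#' subset after `kMax` iterations is returned, reshaped row-major.
#'
#' @param roi a [SegmentedROI-class] or numeric vector.
#' @param control a [psoControl()] bundle.
#' @param shape per-image output shape; `c(512, 10)` at full scale.
#' @param bins histogram bins for the fitness.
#' @return a [ReducedFeatures-class].
#' @export
reduceIntensitiesPSO <- function(roi, control = psoControl(),
                                 shape = c(512L, 10L), bins = 32L) {
  roi <- .checkReductionArgs(roi, shape)
  k <- prod(shape)
  d <- length(roi)
  P <- control$nParticles
  withr::with_seed(control$seed, {
    X <- matrix(stats::runif(P * d), P, d)
    X[1, ] <- roi  # spec'd initialization from the intensities themselves
    V <- matrix(0, P, d)
    fit <- apply(X, 1, function(keys) subsetFitness(.decodeKeys(keys, k), roi, bins))
    pbest <- X; pbestFit <- fit
    gIdx <- which.max(fit)
    gbest <- X[gIdx, ]; gbestFit <- fit[gIdx]
    for (it in seq_len(control$kMax)) {
      r1 <- if (control$stochastic) stats::runif(1) else control$r1
      r2 <- if (control$stochastic) stats::runif(1) else control$r2
      for (p in seq_len(P)) {
        upd <- psoVelocityUpdate(X[p, ], V[p, ], pbest[p, ], gbest, it - 1L,
                                 control, r1 = r1, r2 = r2)
        X[p, ] <- upd$x; V[p, ] <- upd$v
        f <- subsetFitness(.decodeKeys(X[p, ], k), roi, bins)
        if (f > pbestFit[p]) { pbest[p, ] <- X[p, ]; pbestFit[p] <- f }
        if (f > gbestFit) { gbest <- X[p, ]; gbestFit <- f }
      }
    }
    .wrapReduced(roi, .decodeKeys(gbest, k), gbestFit, shape)
  })
}

#' Reduce ROI intensities with grey wolf optimization
#'
#' Same subset encoding and fitness as [reduceIntensitiesPSO()], with the
#' wolves' positions driven by [gwoPositionUpdate()] toward the three
#' best-scoring key vectors under the linearly decaying exploration parameter.
#' The best-ever subset is returned (the alpha archive never regresses).
#'
#' @inheritParams reduceIntensitiesPSO
#' @param control a [gwoControl()] bundle.
#' @return a [ReducedFeatures-class].
#' @export
reduceIntensitiesGWO <- function(roi, control = gwoControl(),
                                 shape = c(512L, 10L), bins = 32L) {
  roi <- .checkReductionArgs(roi, shape)
  k <- prod(shape)
  d <- length(roi)
  W <- control$nWolves
  withr::with_seed(control$seed, {
    X <- matrix(stats::runif(W * d), W, d)
    X[1, ] <- roi
    fit <- apply(X, 1, function(keys) subsetFitness(.decodeKeys(keys, k), roi, bins))
    bestKeys <- X[which.max(fit), ]; bestFit <- max(fit)
    for (it in seq_len(control$maxIter)) {
      ord <- order(fit, decreasing = TRUE)
      alpha <- X[ord[1], ]
      beta <- X[ord[min(2L, W)], ]
      gamma <- X[ord[min(3L, W)], ]
      i <- gwoControlParameter(it - 1L, control$maxIter)
      r1 <- if (control$stochastic) stats::runif(1) else control$r1
      r2 <- if (control$stochastic) stats::runif(1) else control$r2
      for (p in seq_len(W)) {
        X[p, ] <- gwoPositionUpdate(X[p, ], alpha, beta, gamma, i, control,
                                    r1 = r1, r2 = r2)
        fit[p] <- subsetFitness(.decodeKeys(X[p, ], k), roi, bins)
        if (fit[p] > bestFit) { bestKeys <- X[p, ]; bestFit <- fit[p] }
      }
    }
    .wrapReduced(roi, .decodeKeys(bestKeys, k), bestFit, shape)
  })
}

#' Per-class statistical summary of extracted features
#'
#' Computes, per class, the mean, variance, bias-corrected Fisher skewness and
#' non-excess kurtosis of all feature values; the mean pairwise Pearson
#' correlation between images within the class; and the first canonical
#' correlation between the two classes' feature matrices (computed on a
#' principal-component projection since the feature count far exceeds the
#' image count).
#'
#' @param featuresByClass named list with elements `N` and `ACA`, each an
#'   images x features numeric matrix (>= 2 rows each).
#' @return list with per-class `mean`, `variance`, `skewness`, `kurtosis`,
#'   `pearsonCC`, plus a between-class scalar `cca` in \[0, 1\].
#' @export
classStatistics <- function(featuresByClass) {
  stopifnot(all(c("N", "ACA") %in% names(featuresByClass)))
  perClass <- lapply(featuresByClass[c("N", "ACA")], function(m) {
    if (!is.matrix(m) || nrow(m) < 2L) {
      stop("need >= 2 images per class", call. = FALSE)
    }
    v <- as.vector(m)
    if (stats::var(v) == 0) {
      warning("constant features: skewness/kurtosis undefined, reported as 0")
      sk <- 0; ku <- 0
    } else {
      sk <- e1071::skewness(v, type = 2)
      ku <- e1071::kurtosis(v, type = 1) + 3  # non-excess
    }
    cc <- suppressWarnings(stats::cor(t(m)))
    ccVals <- cc[upper.tri(cc)]
    list(mean = mean(v), variance = stats::var(v), skewness = sk,
         kurtosis = ku,
         pearsonCC = if (all(is.na(ccVals))) 0 else mean(ccVals, na.rm = TRUE))
  })
  list(N = perClass$N, ACA = perClass$ACA,
       cca = .firstCanonicalCorrelation(featuresByClass$N, featuresByClass$ACA))
}

# First canonical correlation between two feature matrices with p >> n: both
# matrices are truncated to common rows and projected onto their leading
# principal components before stats::cancor.
.firstCanonicalCorrelation <- function(a, b) {
  n <- min(nrow(a), nrow(b))
  a <- a[seq_len(n), , drop = FALSE]
  b <- b[seq_len(n), , drop = FALSE]
  d <- max(1L, min(n - 2L, 5L))
  proj <- function(m) {
    if (ncol(m) <= d) return(m)
    p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
    p$x[, seq_len(min(d, ncol(p$x))), drop = FALSE]
  }
  res <- tryCatch(stats::cancor(proj(a), proj(b)),
                  error = function(e) NULL)
  if (is.null(res) || length(res$cor) == 0L) return(0)
  min(1, max(0, res$cor[1]))
}
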