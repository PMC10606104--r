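# Shared fixtures and independent oracles, built in code at test time.

# Clip helper that keeps matrix dims (base pmin/pmax take attrs from arg 1).
clipMat <- function(x) {
  d <- dim(x)
  out <- pmin(1, pmax(0, x))
  dim(out) <- d
  out
}

# A 20-value ROI with three intensity levels; the distribution-preservation
# optimum over 8-subsets is degenerate (any proportional allocation), which
# brute force below confirms.
toyROI20 <- function() rep(c(0.15, 0.5, 0.85), times = c(7, 6, 7))

# Independent oracle: exhaustive enumeration of all size-k subsets.
bruteForceBestFitness <- function(roi, k) {
  cmb <- utils::combn(length(roi), k)
  max(apply(cmb, 2, function(ix) subsetFitness(ix, roi)))
}

# 10-feature two-class toy where positions 1 and 6 separate the classes and
# the rest are uniform noise; Fisher and KLD rankings agree by construction.
toySelectable <- function(n = 30, seed = 42) {
  withr::with_seed(seed, {
    xN <- cbind(matrix(runif(n * 8), n, 8),
                rnorm(n, 0.2, 0.03), rnorm(n, 0.8, 0.03))
    xA <- cbind(matrix(runif(n * 8), n, 8),
                rnorm(n, 0.8, 0.03), rnorm(n, 0.2, 0.03))
  })
  x <- clipMat(rbind(xN, xA))
  x <- x[, c(9, 1:4, 10, 5:8)]
  list(x = x, labels = rep(c("N", "ACA"), each = n))
}

# Linearly separable 2-D toy at a coordinate scale matched to the default RBF
# kernel width (sigma = 100), so every classifier can reach 100% on it.
toySeparable2D <- function(n = 20, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(2 * n, 100, 5), n, 2),
               matrix(rnorm(2 * n, 200, 5), n, 2))
  })
  list(x = x, labels = rep(c("N", "ACA"), each = n))
}

# Small noisy classification problem with a train/validation split, for the
# tuning loops.
toyTuningData <- function(seed = 5) {
  withr::with_seed(seed, {
    n <- 40
    x <- rbind(matrix(rnorm(n * 5, 0.35, 0.12), n, 5),
               matrix(rnorm(n * 5, 0.6, 0.12), n, 5))
  })
  y <- rep(c("N", "ACA"), each = 40)
  tr <- c(1:30, 41:70); va <- c(31:40, 71:80)
  list(xTrain = x[tr, ], yTrain = y[tr], xVal = x[va, ], yVal = y[va])
}

# Tiny fast pipeline configuration for orchestration tests.
miniPipelineConfig <- function(seed = 1L, ...) {
  pipelineConfig(
    nPerClass = 6L, side = 32L,
    synth = syntheticParams(textureNoiseSD = 0.03),
    kfcm = kfcmControl(maxIter = 25L),
    roiLength = 512L,
    pso = psoControl(nParticles = 8L, kMax = 10L),
    gwo = gwoControl(nWolves = 8L, maxIter = 10L),
    reducedShape = c(10L, 10L),
    nSelect = 24L, selectShape = c(2L, 12L),
    iwo = iwoControl(nIter = 10L),
    folds = 3L, seed = seed, ...)
}
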