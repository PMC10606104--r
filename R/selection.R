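#' Kullback-Leibler divergence between two discrete distributions
#'
#' `D(q || p) = sum_j q_j log(q_j / p_j)` with natural logarithm and the
#' conventions `0 log(0/x) = 0` and `q_j > 0, p_j = 0 => +Inf` (non-overlapping
#' support). Equal distributions give exactly 0.
#'
#' @param q,p nonnegative probability vectors of equal length, each summing to
#'   1 within 1e-9.
#' @return nonnegative scalar, possibly `Inf`.
#' @examples
#' klDivergence(c(0.5, 0.5), c(0.9, 0.1)) # ~0.5108
#' @export
klDivergence <- function(q, p) {
  if (length(q) != length(p)) stop("length mismatch", call. = FALSE)
  if (any(q < 0) || any(p < 0)) stop("negative entries", call. = FALSE)
  if (abs(sum(q) - 1) > 1e-9 || abs(sum(p) - 1) > 1e-9) {
    stop("distributions must sum to 1", call. = FALSE)
  }
  pos <- q > 0
  if (any(pos & p == 0)) return(Inf)
  sum(q[pos] * log(q[pos] / p[pos]))
}

#' Rank feature positions by symmetrized KL divergence
#'
#' For every feature position, class-conditional histograms of the training
#' values are built over shared \[0, 1\] bin edges with add-one (Laplace)
#' smoothing, and the position's score is the symmetrized divergence
#' `D(N || ACA) + D(ACA || N)`. Higher scores mark positions whose intensity
#' distribution separates the classes; identical class distributions score 0,
#' and the score is invariant to swapping the class labels.
#'
#' @param trainMatrix images x features numeric matrix.
#' @param labels class labels (`N` / `ACA`), both classes present with >= 2
#'   images each.
#' @param bins histogram bins, default 32.
#' @return numeric vector of per-position scores (all finite and >= 0).
#' @export
rankFeaturesKLD <- function(trainMatrix, labels, bins = 32L) {
  labels <- .checkLabels(labels)
  if (nlevels(droplevels(labels)) < 2L || min(table(labels)) < 2L) {
    stop("need >= 2 images in each of both classes", call. = FALSE)
  }
  xn <- trainMatrix[labels == "N", , drop = FALSE]
  xa <- trainMatrix[labels == "ACA", , drop = FALSE]
  vapply(seq_len(ncol(trainMatrix)), function(j) {
    pn <- .histProbs(xn[, j], bins, smooth = 1)
    pa <- .histProbs(xa[, j], bins, smooth = 1)
    klDivergence(pn, pa) + klDivergence(pa, pn)
  }, numeric(1))
}

#' Select the top-k scoring positions across a dataset
#'
#' One shared index set for all images: the `k` highest-scoring positions,
#' ties broken toward the lower index, sorted ascending, applied to every
#' image row and reshaped row-major to the per-image grid.
#'
#' @param matrixSet images x features numeric matrix (one flattened extracted
#'   vector per row).
#' @param scores per-position scores, `length(scores) == ncol(matrixSet)`.
#' @param k positions to keep (default 1200 = 100 x 12).
#' @param shape per-image grid, `prod(shape) == k`.
#' @return a [SelectedFeatures-class].
#' @examples
#' m <- matrix(runif(12), 2, 6)
#' selectTopK(m, c(3, 1, 2, 6, 5, 4), k = 2, shape = c(1, 2))
#' @export
selectTopK <- function(matrixSet, scores, k = 1200L, shape = c(100L, 12L)) {
  k <- as.integer(k)
  if (k > length(scores)) stop("k exceeds the feature count", call. = FALSE)
  if (length(scores) != ncol(matrixSet)) stop("score/feature mismatch", call. = FALSE)
  if (prod(shape) != k) shape <- c(1L, k)
  pos <- sort(order(-scores, seq_along(scores))[seq_len(k)])
  new("SelectedFeatures",
      values = matrixSet[, pos, drop = FALSE],
      positions = as.integer(pos), shape = as.integer(shape))
}

#' Control parameters for invasive weed optimization
#'
#' @param popInit initial colony size.
#' @param sMax maximum colony size after competition (>= `popInit`).
#' @param yMin,yMax seed-count bounds: the fittest weed disperses `yMax`
#'   seeds, the least fit `yMin` ([iwoSeedCount()]).
#' @param m nonlinear modulation exponent of the dispersal schedule.
#' @param sigmaInitial,sigmaFinal dispersal standard deviations at the first
#'   and last iteration (`sigmaFinal <= sigmaInitial`).
#' @param nIter iterations.
#' @param seed integer seed.
#' @return validated list of class `IWOControl`.
#' @export
iwoControl <- function(popInit = 5L, sMax = 15L, yMin = 0L, yMax = 3L,
                       m = 3, sigmaInitial = 0.5, sigmaFinal = 0.01,
                       nIter = 30L, seed = 1L) {
  if (yMin > yMax) stop("yMin must be <= yMax", call. = FALSE)
  if (sigmaFinal > sigmaInitial) stop("sigmaFinal must be <= sigmaInitial", call. = FALSE)
  if (sMax < popInit) stop("sMax must be >= popInit", call. = FALSE)
  structure(list(popInit = as.integer(popInit), sMax = as.integer(sMax),
                 yMin = as.integer(yMin), yMax = as.integer(yMax), m = m,
                 sigmaInitial = sigmaInitial, sigmaFinal = sigmaFinal,
                 nIter = as.integer(nIter), seed = as.integer(seed)),
            class = "IWOControl")
}

#' Seed count of a weed under linear fitness interpolation
#'
#' Fitness is minimized: the fittest weed (`fit = minFit`) disperses `yMax`
#' seeds and the least fit (`fit = maxFit`) disperses `yMin`, interpolating
#' linearly (rounded). Degenerate colonies (`minFit == maxFit`) all get
#' `floor((yMin + yMax) / 2)`.
#'
#' @param fit this weed's fitness.
#' @param minFit,maxFit colony fitness range.
#' @param yMin,yMax seed-count bounds.
#' @return integer seed count.
#' @export
iwoSeedCount <- function(fit, minFit, maxFit, yMin, yMax) {
  if (minFit == maxFit) return(as.integer(floor((yMin + yMax) / 2)))
  if (fit < minFit || fit > maxFit) stop("fit outside [minFit, maxFit]", call. = FALSE)
  as.integer(round((yMax * (maxFit - fit) + yMin * (fit - minFit)) /
                     (maxFit - minFit)))
}

#' Dispersal standard deviation schedule
#'
#' `sigma_t = ((nIter - t) / nIter)^m (sigmaInitial - sigmaFinal) + sigmaFinal`:
#' starts at `sigmaInitial`, ends at `sigmaFinal`, with nonlinearity `m`.
#'
#' @param t iteration in `[0, nIter]`.
#' @param control an [iwoControl()] bundle.
#' @return nonnegative scalar.
#' @export
iwoSigma <- function(t, control = iwoControl()) {
  if (control$nIter <= 0) stop("nIter must be positive", call. = FALSE)
  if (t < 0 || t > control$nIter) stop("t must be in [0, nIter]", call. = FALSE)
  ((control$nIter - t) / control$nIter)^control$m *
    (control$sigmaInitial - control$sigmaFinal) + control$sigmaFinal
}

#' Feature selection by invasive weed optimization
#'
#' Weeds are continuous score vectors over the feature positions, decoded to
#' the `k` largest-key subset. The (minimized) fitness is the negative sum of
#' Fisher separation scores `(mu_N - mu_ACA)^2 / (var_N + var_ACA + eps)` over
#' the selected positions. Each iteration the colony reproduces
#' ([iwoSeedCount()]) with Gaussian dispersal of shrinking spread
#' ([iwoSigma()]) and is truncated to `sMax` by fitness; the best-ever subset
#' is returned and applied to every image.
#'
#' @param matrixSet images x features numeric matrix.
#' @param labels class labels, both classes present.
#' @param k positions to keep (default 1200).
#' @param control an [iwoControl()] bundle.
#' @param shape per-image grid, `prod(shape) == k`.
#' @return a [SelectedFeatures-class].
#' @export
selectIWO <- function(matrixSet, labels, k = 1200L, control = iwoControl(),
                      shape = c(100L, 12L)) {
  labels <- .checkLabels(labels)
  k <- as.integer(k)
  p <- ncol(matrixSet)
  if (k > p) stop("k exceeds the feature count", call. = FALSE)
  if (prod(shape) != k) shape <- c(1L, k)
  fisher <- .fisherScores(matrixSet, labels)
  decode <- function(keys) sort(order(-keys, seq_along(keys))[seq_len(k)])
  fitOf <- function(keys) -sum(fisher[decode(keys)])
  withr::with_seed(control$seed, {
    pop <- matrix(stats::runif(control$popInit * p), control$popInit, p)
    fits <- apply(pop, 1, fitOf)
    bestKeys <- pop[which.min(fits), ]; bestFit <- min(fits)
    for (t in seq_len(control$nIter)) {
      sigma <- iwoSigma(t, control)
      lo <- min(fits); hi <- max(fits)
      offspring <- list()
      for (wdx in seq_len(nrow(pop))) {
        ns <- iwoSeedCount(fits[wdx], lo, hi, control$yMin, control$yMax)
        if (ns > 0) {
          kids <- matrix(rep(pop[wdx, ], ns), ns, p, byrow = TRUE) +
            matrix(stats::rnorm(ns * p, 0, sigma), ns, p)
          offspring[[length(offspring) + 1L]] <- kids
        }
      }
      if (length(offspring) > 0) {
        kids <- do.call(rbind, offspring)
        pop <- rbind(pop, kids)
        fits <- c(fits, apply(kids, 1, fitOf))
      }
      if (nrow(pop) > control$sMax) {
        keep <- order(fits)[seq_len(control$sMax)]
        pop <- pop[keep, , drop = FALSE]
        fits <- fits[keep]
      }
      if (min(fits) < bestFit) {
        bestFit <- min(fits)
        bestKeys <- pop[which.min(fits), ]
      }
    }
    pos <- decode(bestKeys)
    new("SelectedFeatures",
        values = matrixSet[, pos, drop = FALSE],
        positions = as.integer(pos), shape = as.integer(shape))
  })
}
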