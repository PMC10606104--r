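#' @import methods
NULL

#' Labeled set of synthetic grayscale tissue images
#'
#' Container for a balanced two-class image set produced by
#' [generateDataset()]. Images are square numeric matrices with intensities in
#' \[0, 1\]; labels are `"N"` (benign) or `"ACA"` (adenocarcinoma); `seeds`
#' records the per-image seed derived from the master seed so any single image
#' can be regenerated in isolation.
#'
#' @slot images list of numeric matrices, all square with identical side.
#' @slot labels factor with levels `N`, `ACA`.
#' @slot seeds integer vector of per-image seeds.
#'
#' @seealso [generateDataset()], [images()], [labels,LabeledImageSet-method]
#' @export
setClass("LabeledImageSet",
  representation(images = "list", labels = "factor", seeds = "integer"))

setValidity("LabeledImageSet", function(object) {
  n <- length(object@images)
  if (length(object@labels) != n || length(object@seeds) != n) {
    return("images, labels and seeds must have equal length")
  }
  if (n > 0L) {
    sides <- vapply(object@images, function(im) {
      if (!is.matrix(im) || nrow(im) != ncol(im)) return(-1L)
      nrow(im)
    }, integer(1))
    if (any(sides < 0L)) return("all images must be square matrices")
    if (length(unique(sides)) != 1L) return("all images must share one side length")
    rng <- range(vapply(object@images, range, numeric(2)))
    if (rng[1] < 0 || rng[2] > 1) return("intensities must lie in [0, 1]")
  }
  TRUE
})

#' Converged modified-KFCM clustering of one image
#'
#' Result object of [runModifiedKFCM()]: the row-normalized fuzzy membership
#' matrix (one row per pixel, one column per cluster), the scalar cluster
#' centres, and the per-iteration objective trace.
#'
#' @slot membership numeric matrix, `n_pixels x c`, rows summing to 1.
#' @slot centers numeric vector of `c` cluster centres in \[0, 1\].
#' @slot objective numeric vector, objective value per iteration.
#' @slot dims integer, `c(nrow, ncol)` of the clustered image.
#' @slot iterations integer, iterations actually run.
#' @slot converged logical, whether the centre-shift tolerance was met.
#'
#' @seealso [runModifiedKFCM()], [membership()], [centers()], [objectiveTrace()]
#' @export
setClass("KFCMFit",
  representation(membership = "matrix", centers = "numeric",
                 objective = "numeric", dims = "integer",
                 iterations = "integer", converged = "logical"))

setValidity("KFCMFit", function(object) {
  if (nrow(object@membership) != prod(object@dims)) {
    return("membership rows must equal the pixel count")
  }
  if (ncol(object@membership) != length(object@centers)) {
    return("membership columns must equal the number of centers")
  }
  rs <- rowSums(object@membership)
  if (any(abs(rs - 1) > 1e-8)) return("membership rows must sum to 1")
  TRUE
})

#' Segmented region-of-interest intensity vector
#'
#' Output of [extractROI()]: the foreground pixel intensities of one image,
#' padded or truncated to a fixed target length so downstream swarm reduction
#' sees a constant problem size, plus the boolean foreground mask.
#'
#' @slot values numeric vector of ROI intensities in \[0, 1\].
#' @slot mask logical matrix marking foreground pixels.
#'
#' @seealso [extractROI()], [roiValues()], [roiMask()]
#' @export
setClass("SegmentedROI",
  representation(values = "numeric", mask = "matrix"))

setValidity("SegmentedROI", function(object) {
  if (any(object@values < 0) || any(object@values > 1)) {
    return("ROI intensities must lie in [0, 1]")
  }
  if (!is.logical(object@mask)) return("mask must be logical")
  TRUE
})

#' Swarm-reduced intensity feature matrix for one image
#'
#' Result of [reduceIntensitiesPSO()] / [reduceIntensitiesGWO()]: the retained
#' ROI intensities arranged row-major into a fixed shape (512 x 10 at full
#' scale) together with the strictly increasing positions they came from.
#'
#' @slot values numeric matrix of retained intensities.
#' @slot sourceIndices integer vector of unique, sorted positions into the
#'   ROI vector (1-based).
#' @slot fitness numeric, the distribution-preservation fitness of the subset.
#'
#' @seealso [featureValues()], [sourceIndices()], [subsetFitness()]
#' @export
setClass("ReducedFeatures",
  representation(values = "matrix", sourceIndices = "integer",
                 fitness = "numeric"))

setValidity("ReducedFeatures", function(object) {
  k <- length(object@sourceIndices)
  if (length(object@values) != k) return("values must hold one entry per index")
  if (is.unsorted(object@sourceIndices, strictly = TRUE)) {
    return("sourceIndices must be strictly increasing")
  }
  TRUE
})

#' Dataset-level feature selection result
#'
#' Result of [selectTopK()] / [selectIWO()]: one shared index set applied to
#' every image of the dataset, with each image's selected values stored as one
#' row (reshape any row with [imageMatrix()] to the per-image grid, 100 x 12 at
#' full scale).
#'
#' @slot values numeric matrix, images x k selected values.
#' @slot positions integer vector of unique, sorted positions into the
#'   extracted feature vector (1-based), identical across images.
#' @slot shape integer, the per-image grid `c(rows, cols)`.
#'
#' @seealso [selectTopK()], [selectIWO()], [imageMatrix()]
#' @export
setClass("SelectedFeatures",
  representation(values = "matrix", positions = "integer", shape = "integer"))

setValidity("SelectedFeatures", function(object) {
  k <- length(object@positions)
  if (ncol(object@values) != k) return("one column per selected position required")
  if (is.unsorted(object@positions, strictly = TRUE)) {
    return("positions must be strictly increasing")
  }
  if (prod(object@shape) != k) return("shape must multiply to the position count")
  TRUE
})

#' Fitted binary classifier with target encoding
#'
#' Uniform facade over the seven supported classifiers. `fit` holds the
#' kind-specific state (support vectors, neighbour store, tree ensemble,
#' network weights, discriminant coefficients, ...); predictions are produced
#' with [predict()] and return continuous scores in target space plus decoded
#' class labels.
#'
#' @slot kind character, one of `svm`, `knn`, `rf`, `dt`, `sdc`, `mlp`, `bldc`.
#' @slot fit list of kind-specific fitted state.
#' @slot encoding numeric target encoding, see [targetEncoding()].
#' @slot featureDim integer, training feature dimensionality.
#' @slot seed integer training seed.
#'
#' @seealso [trainClassifier()], [predict,TrainedModel-method]
#' @export
setClass("TrainedModel",
  representation(kind = "character", fit = "list", encoding = "numeric",
                 featureDim = "integer", seed = "integer"))

#' Binary confusion matrix with adenocarcinoma as the positive class
#'
#' @slot TP,TN,FP,FN nonnegative integer counts.
#'
#' @seealso [confusion()], [metricsFromConfusion()]
#' @export
setClass("ConfusionMatrix",
  representation(TP = "integer", TN = "integer", FP = "integer", FN = "integer"))

setValidity("ConfusionMatrix", function(object) {
  counts <- c(object@TP, object@TN, object@FP, object@FN)
  if (any(counts < 0)) return("counts must be nonnegative")
  if (sum(counts) == 0) return("total count must be positive")
  TRUE
})

#' Hyperparameter tuning result
#'
#' @slot best named numeric vector of the best hyperparameters found.
#' @slot bestER numeric, the best (lowest) validation error rate in \[0, 1\].
#' @slot trace data.frame with one row per evaluated candidate
#'   (iteration, phase, hyperparameters, error rate).
#'
#' @seealso [tuneAdam()], [tuneRAdam()]
#' @export
setClass("TuningResult",
  representation(best = "numeric", bestER = "numeric", trace = "data.frame"))

setValidity("TuningResult", function(object) {
  if (nrow(object@trace) > 0 &&
      abs(object@bestER - min(object@trace$errorRate)) > 1e-12) {
    return("bestER must equal the minimum error rate in the trace")
  }
  TRUE
})

setMethod("show", "LabeledImageSet", function(object) {
  side <- if (length(object@images)) nrow(object@images[[1]]) else 0L
  cat(sprintf("LabeledImageSet: %d images (%dx%d), %d N / %d ACA\n",
              length(object@images), side, side,
              sum(object@labels == "N"), sum(object@labels == "ACA")))
})

setMethod("show", "KFCMFit", function(object) {
  cat(sprintf("KFCMFit: %d pixels, %d clusters, %d iterations (%s)\n",
              nrow(object@membership), length(object@centers),
              object@iterations,
              if (object@converged) "converged" else "max iterations"))
  cat("  centers:", paste(sprintf("%.4f", object@centers), collapse = ", "), "\n")
})

setMethod("show", "SegmentedROI", function(object) {
  cat(sprintf("SegmentedROI: %d intensities, %d foreground pixels\n",
              length(object@values), sum(object@mask)))
})

setMethod("show", "ReducedFeatures", function(object) {
  cat(sprintf("ReducedFeatures: %d x %d (fitness %.4g)\n",
              nrow(object@values), ncol(object@values), object@fitness))
})

setMethod("show", "SelectedFeatures", function(object) {
  cat(sprintf("SelectedFeatures: %d images x %d positions (per-image %d x %d)\n",
              nrow(object@values), length(object@positions),
              object@shape[1], object@shape[2]))
})

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("TrainedModel: %s, %d features, targets N=%.2f / ACA=%.2f\n",
              object@kind, object@featureDim,
              object@encoding[["benign"]], object@encoding[["aca"]]))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (positive = ACA)\n")
  cat(sprintf("  TP=%d  FN=%d\n  FP=%d  TN=%d\n",
              object@TP, object@FN, object@FP, object@TN))
})

setMethod("show", "TuningResult", function(object) {
  cat(sprintf("TuningResult: best ER %.4f after %d evaluations\n",
              object@bestER, nrow(object@trace)))
  cat("  best:", paste(sprintf("%s=%.4g", names(object@best), object@best),
                       collapse = ", "), "\n")
})
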