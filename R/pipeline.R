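#' Full pipeline configuration
#'
#' Bundles every stage's settings: synthetic data generation (or a
#' user-supplied [LabeledImageSet-class]), preprocessing, modified-KFCM
#' segmentation, swarm intensity reduction, feature selection, classification,
#' hyperparameter tuning and cross-validation.
#'
#' The defaults are the desk-scale profile: 40 images per class at 64 x 64
#' with 50-iteration, 20-agent swarms, an ROI of 2048 intensities reduced to a
#' 32 x 10 matrix and selected down to 7 x 12. The full-scale shapes
#' (256 x 256 images, 36100-value ROI, 512 x 10 reduction, 100 x 12 selection)
#' are available by passing `side = 256`, `roiLength = 36100`,
#' `reducedShape = c(512, 10)`, `nSelect = 1200`, `selectShape = c(100, 12)`.
#'
#' @param nPerClass synthetic images per class.
#' @param side image side in pixels.
#' @param synth a [syntheticParams()] bundle.
#' @param imageSet optional pre-built [LabeledImageSet-class]; when supplied,
#'   `nPerClass`/`synth` are ignored.
#' @param filter apply the adaptive median filter during preprocessing.
#' @param maxWindow adaptive median filter maximum window.
#' @param kfcm a [kfcmControl()].
#' @param roiLength target ROI length.
#' @param extractor `"pso"` or `"gwo"`.
#' @param pso,gwo swarm controls ([psoControl()], [gwoControl()]).
#' @param reducedShape per-image reduced matrix shape.
#' @param selector `"none"`, `"kld"` or `"iwo"`.
#' @param nSelect selected positions; must equal `prod(selectShape)`.
#' @param selectShape per-image selected matrix shape.
#' @param iwo an [iwoControl()].
#' @param classifier classifier kind, see [classifierParams()].
#' @param classifierParams parameter overrides for the classifier.
#' @param tuner `"none"`, `"adam"` or `"radam"`.
#' @param tunerIters Adam iterations inside the tuner.
#' @param folds cross-validation folds.
#' @param encoding a [targetEncoding()].
#' @param seed master seed for the whole run.
#' @return list of class `PipelineConfig`.
#' @seealso [runPipeline()], [runGrid()]
#' @export
pipelineConfig <- function(nPerClass = 40L, side = 64L,
                           synth = syntheticParams(), imageSet = NULL,
                           filter = TRUE, maxWindow = 7L,
                           kfcm = kfcmControl(),
                           roiLength = 2048L,
                           extractor = c("gwo", "pso"),
                           pso = psoControl(kMax = 50L),
                           gwo = gwoControl(maxIter = 50L),
                           reducedShape = c(32L, 10L),
                           selector = c("iwo", "kld", "none"),
                           nSelect = 84L, selectShape = c(7L, 12L),
                           iwo = iwoControl(),
                           classifier = "dt", classifierParams = NULL,
                           tuner = c("none", "adam", "radam"),
                           tunerIters = 10L, folds = 10L,
                           encoding = targetEncoding(), seed = 1L) {
  extractor <- match.arg(extractor)
  selector <- match.arg(selector)
  tuner <- match.arg(tuner)
  classifier <- match.arg(classifier, .classifierKinds)
  if (prod(selectShape) != nSelect) {
    stop("nSelect must equal prod(selectShape)", call. = FALSE)
  }
  if (prod(reducedShape) > roiLength) {
    stop("reducedShape larger than the ROI", call. = FALSE)
  }
  structure(list(nPerClass = as.integer(nPerClass), side = as.integer(side),
                 synth = synth, imageSet = imageSet, filter = isTRUE(filter),
                 maxWindow = as.integer(maxWindow), kfcm = kfcm,
                 roiLength = as.integer(roiLength), extractor = extractor,
                 pso = pso, gwo = gwo,
                 reducedShape = as.integer(reducedShape),
                 selector = selector, nSelect = as.integer(nSelect),
                 selectShape = as.integer(selectShape), iwo = iwo,
                 classifier = classifier, classifierParams = classifierParams,
                 tuner = tuner, tunerIters = as.integer(tunerIters),
                 folds = as.integer(folds), encoding = encoding,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

# Stages 1-4 (data -> preprocess -> segment -> reduce), shared by
# runPipeline() and reused across a grid. Returns per-image flattened feature
# rows plus labels and stage hashes/timings.
.computeFeatureStage <- function(config) {
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  imageSet <- config$imageSet %||%
    generateDataset(config$nPerClass, config$synth, seed = config$seed,
                    side = config$side)
  timings["synthesize"] <- tic() - t0

  t0 <- tic()
  imgs <- lapply(images(imageSet), function(im) {
    im <- toGrayscale(im)
    im <- resizeSquare(im, config$side)
    if (config$filter) im <- adaptiveMedianFilter(im, config$maxWindow)
    im
  })
  timings["preprocess"] <- tic() - t0

  t0 <- tic()
  rois <- lapply(imgs, function(im) {
    fit <- runModifiedKFCM(im, config$kfcm)
    extractROI(im, fit, length = config$roiLength)
  })
  timings["segment"] <- tic() - t0

  t0 <- tic()
  reduced <- lapply(seq_along(rois), function(i) {
    if (config$extractor == "pso") {
      ctl <- config$pso; ctl$seed <- deriveSeed(config$seed, i, 23L)
      reduceIntensitiesPSO(rois[[i]], ctl, shape = config$reducedShape)
    } else {
      ctl <- config$gwo; ctl$seed <- deriveSeed(config$seed, i, 23L)
      reduceIntensitiesGWO(rois[[i]], ctl, shape = config$reducedShape)
    }
  })
  timings["extract"] <- tic() - t0

  features <- do.call(rbind, lapply(reduced, function(r) {
    as.vector(t(featureValues(r)))  # row-major flatten
  }))
  list(features = features, labels = labels(imageSet),
       imageSet = imageSet, reduced = reduced, timings = timings,
       hashes = c(images = .objectHash(imgs), features = .objectHash(features)))
}

# Config fields that determine the feature stage (used as a grid cache key).
.featureStageKey <- function(config) {
  .objectHash(config[c("nPerClass", "side", "synth", "imageSet", "filter",
                       "maxWindow", "kfcm", "roiLength", "extractor",
                       "pso", "gwo", "reducedShape", "seed")])
}

#' Run the full classification pipeline
#'
#' Executes preprocess -> segment -> extract -> select -> (tune) -> classify
#' -> evaluate on synthetic (or supplied) images under one master seed, and
#' returns pooled cross-validation metrics together with a reproducibility
#' manifest (stage content hashes, per-stage wall-clock, config snapshot).
#' Identical configurations produce identical manifests.
#'
#' @param config a [pipelineConfig()].
#' @param featureStage optional precomputed result of the internal feature
#'   stage (used by [runGrid()] to share upstream work).
#' @return list with `metrics`, `cv` (full [kfoldCV()] result), `features`,
#'   `labels` and `manifest`.
#' @export
runPipeline <- function(config = pipelineConfig(), featureStage = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  stage <- featureStage %||% .computeFeatureStage(config)
  t0 <- proc.time()[["elapsed"]]
  cv <- kfoldCV(stage$features, stage$labels, kind = config$classifier,
                selector = config$selector, nSelect = config$nSelect,
                selectShape = config$selectShape, tuner = config$tuner,
                tunerIters = config$tunerIters, k = config$folds,
                params = config$classifierParams, iwo = config$iwo,
                encoding = config$encoding, seed = config$seed)
  timings <- c(stage$timings, classify = proc.time()[["elapsed"]] - t0)
  manifest <- list(
    config = config[setdiff(names(config), "imageSet")],
    hashes = c(stage$hashes,
               predictions = .objectHash(cv$predictions),
               pooled = .objectHash(confusionCounts(cv$pooled))),
    timings = timings,
    version = as.character(utils::packageVersion("histoclass")))
  list(metrics = cv$metrics, cv = cv, features = stage$features,
       labels = stage$labels, manifest = manifest)
}

#' Run a grid of pipeline configurations
#'
#' Evaluates each configuration with [runPipeline()], reusing the expensive
#' upstream stages (synthesis, filtering, segmentation, swarm reduction)
#' across configurations that share them, and returns one row per
#' configuration sorted by pooled accuracy (best first). A failed run keeps
#' its row, marked failed, and the grid continues.
#'
#' @param configs list of [pipelineConfig()] objects.
#' @return data.frame with extractor, selector, classifier, tuner, the pooled
#'   metrics, and a `failed` flag.
#' @export
runGrid <- function(configs) {
  if (length(configs) < 1L) stop("need at least one config", call. = FALSE)
  cache <- new.env(parent = emptyenv())
  rows <- lapply(configs, function(cfg) {
    res <- tryCatch({
      key <- .featureStageKey(cfg)
      if (!exists(key, envir = cache, inherits = FALSE)) {
        cache[[key]] <- .computeFeatureStage(cfg)
      }
      runPipeline(cfg, featureStage = cache[[key]])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(extractor = cfg$extractor, selector = cfg$selector,
                 classifier = cfg$classifier, tuner = cfg$tuner,
                 accuracy = NA_real_, errorRate = NA_real_, f1 = NA_real_,
                 mcc = NA_real_, jaccard = NA_real_, gMean = NA_real_,
                 kappa = NA_real_, failed = TRUE)
    } else {
      m <- res$metrics
      data.frame(extractor = cfg$extractor, selector = cfg$selector,
                 classifier = cfg$classifier, tuner = cfg$tuner,
                 accuracy = m$accuracy, errorRate = m$errorRate, f1 = m$f1,
                 mcc = m$mcc, jaccard = m$jaccard, gMean = m$gMean,
                 kappa = m$kappa, failed = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out[order(-ifelse(is.na(out$accuracy), -Inf, out$accuracy)), , drop = FALSE]
}
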