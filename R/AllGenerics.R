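# Accessor generics. Slot access from user code goes through these.

#' @describeIn LabeledImageSet-class list of image matrices.
#' @param x,object an object of the documented class.
#' @export
setGeneric("images", function(x) standardGeneric("images"))

#' @describeIn LabeledImageSet-class class labels (factor with levels N, ACA).
#' @export
setGeneric("labels")

#' @describeIn LabeledImageSet-class per-image seeds.
#' @export
setGeneric("imageSeeds", function(x) standardGeneric("imageSeeds"))

#' @describeIn KFCMFit-class fuzzy membership matrix (pixels x clusters).
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @describeIn KFCMFit-class cluster centres.
#' @export
setGeneric("centers", function(x) standardGeneric("centers"))

#' @describeIn KFCMFit-class per-iteration objective values.
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))

#' @describeIn SegmentedROI-class ROI intensity vector.
#' @export
setGeneric("roiValues", function(x) standardGeneric("roiValues"))

#' @describeIn SegmentedROI-class logical foreground mask.
#' @export
setGeneric("roiMask", function(x) standardGeneric("roiMask"))

#' @describeIn ReducedFeatures-class feature value matrix.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @describeIn ReducedFeatures-class positions of the retained values.
#' @export
setGeneric("sourceIndices", function(x) standardGeneric("sourceIndices"))

#' @describeIn SelectedFeatures-class shared selected positions.
#' @export
setGeneric("selectedPositions", function(x) standardGeneric("selectedPositions"))

#' @describeIn SelectedFeatures-class per-image grid for image `i`.
#' @param i image row index.
#' @export
setGeneric("imageMatrix", function(x, i) standardGeneric("imageMatrix"))

#' @describeIn ConfusionMatrix-class named counts `c(TP, TN, FP, FN)`.
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))

#' @describeIn TuningResult-class best hyperparameters found.
#' @export
setGeneric("bestHyperparams", function(x) standardGeneric("bestHyperparams"))

#' @describeIn TuningResult-class best validation error rate.
#' @export
setGeneric("bestErrorRate", function(x) standardGeneric("bestErrorRate"))

#' @describeIn TuningResult-class full evaluation trace.
#' @export
setGeneric("tuningTrace", function(x) standardGeneric("tuningTrace"))

#' @rdname images
#' @export
setMethod("images", "LabeledImageSet", function(x) x@images)

#' @describeIn LabeledImageSet-class labels accessor.
#' @export
setMethod("labels", "LabeledImageSet", function(object) object@labels)

#' @rdname imageSeeds
#' @export
setMethod("imageSeeds", "LabeledImageSet", function(x) x@seeds)

#' @rdname membership
#' @export
setMethod("membership", "KFCMFit", function(x) x@membership)

#' @rdname centers
#' @export
setMethod("centers", "KFCMFit", function(x) x@centers)

#' @rdname objectiveTrace
#' @export
setMethod("objectiveTrace", "KFCMFit", function(x) x@objective)

#' @rdname roiValues
#' @export
setMethod("roiValues", "SegmentedROI", function(x) x@values)

#' @rdname roiMask
#' @export
setMethod("roiMask", "SegmentedROI", function(x) x@mask)

#' @rdname featureValues
#' @export
setMethod("featureValues", "ReducedFeatures", function(x) x@values)

#' @rdname featureValues
#' @export
setMethod("featureValues", "SelectedFeatures", function(x) x@values)

#' @rdname sourceIndices
#' @export
setMethod("sourceIndices", "ReducedFeatures", function(x) x@sourceIndices)

#' @rdname selectedPositions
#' @export
setMethod("selectedPositions", "SelectedFeatures", function(x) x@positions)

#' @rdname imageMatrix
#' @export
setMethod("imageMatrix", "SelectedFeatures", function(x, i) {
  matrix(x@values[i, ], nrow = x@shape[1], ncol = x@shape[2], byrow = TRUE)
})

#' @rdname confusionCounts
#' @export
setMethod("confusionCounts", "ConfusionMatrix", function(x) {
  c(TP = x@TP, TN = x@TN, FP = x@FP, FN = x@FN)
})

#' @rdname bestHyperparams
#' @export
setMethod("bestHyperparams", "TuningResult", function(x) x@best)

#' @rdname bestErrorRate
#' @export
setMethod("bestErrorRate", "TuningResult", function(x) x@bestER)

#' @rdname tuningTrace
#' @export
setMethod("tuningTrace", "TuningResult", function(x) x@trace)
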