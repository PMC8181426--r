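# Generics and accessors for the S4 containers.

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))
#' @rdname accessors
#' @export
setGeneric("gestureLabels", function(x) standardGeneric("gestureLabels"))
#' @rdname accessors
#' @export
setGeneric("repetitionIds", function(x) standardGeneric("repetitionIds"))
#' @rdname accessors
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))
#' @rdname accessors
#' @export
setGeneric("channelCount", function(x) standardGeneric("channelCount"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("recordings", function(x) standardGeneric("recordings"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("featureSetName", function(x) standardGeneric("featureSetName"))
#' @rdname accessors
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))
#' @rdname accessors
#' @export
setGeneric("accuracies", function(x) standardGeneric("accuracies"))
#' @rdname accessors
#' @export
setGeneric("confusionMatrices", function(x) standardGeneric("confusionMatrices"))

#' Accessors for emgadapt containers
#'
#' Small read-only accessors; user code should use these rather than
#' reaching into slots.
#'
#' @param x an emgadapt S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("subjectIds", "EmgDataset", function(x)
  unique(vapply(x@recordings, function(r) r@subjectId, character(1))))
#' @rdname accessors
#' @export
setMethod("subjectIds", "WindowSet", function(x) x@subjectIds)
#' @rdname accessors
#' @export
setMethod("subjectIds", "FeatureMatrix", function(x) x@subjectIds)

#' @rdname accessors
#' @export
setMethod("gestureLabels", "WindowSet", function(x) x@gestureLabels)
#' @rdname accessors
#' @export
setMethod("gestureLabels", "FeatureMatrix", function(x) x@gestureLabels)
#' @rdname accessors
#' @export
setMethod("gestureLabels", "EmgDataset", function(x)
  vapply(x@recordings, function(r) r@gestureId, integer(1)))

#' @rdname accessors
#' @export
setMethod("repetitionIds", "WindowSet", function(x) x@repetitionIds)
#' @rdname accessors
#' @export
setMethod("repetitionIds", "FeatureMatrix", function(x) x@repetitionIds)
#' @rdname accessors
#' @export
setMethod("repetitionIds", "EmgDataset", function(x)
  vapply(x@recordings, function(r) r@repetitionId, integer(1)))

#' @rdname accessors
#' @export
setMethod("classNames", "EmgDataset", function(x) x@classNames)
#' @rdname accessors
#' @export
setMethod("channelCount", "EmgDataset", function(x) x@channelCount)
#' @rdname accessors
#' @export
setMethod("channelCount", "WindowSet", function(x) dim(x@windows)[2])
#' @rdname accessors
#' @export
setMethod("samplingRate", "EmgDataset", function(x) x@samplingRate)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EmgRecording", function(x) x@samplingRate)
#' @rdname accessors
#' @export
setMethod("samplingRate", "WindowSet", function(x) x@samplingRate)
#' @rdname accessors
#' @export
setMethod("recordings", "EmgDataset", function(x) x@recordings)
#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("featureSetName", "FeatureMatrix", function(x) x@featureSet)
#' @rdname accessors
#' @export
setMethod("nWindows", "WindowSet", function(x) dim(x@windows)[1])
#' @rdname accessors
#' @export
setMethod("nWindows", "FeatureMatrix", function(x) nrow(x@values))
#' @rdname accessors
#' @export
setMethod("accuracies", "EvaluationResult", function(x) x@accuracies)
#' @rdname accessors
#' @export
setMethod("confusionMatrices", "EvaluationResult", function(x) x@confusion)

# (subject, gesture, repetition) keys, used by validity and the splits
recordingKeys <- function(dataset) {
  vapply(dataset@recordings, function(r)
    paste(r@subjectId, r@gestureId, r@repetitionId, sep = "|"), character(1))
}

setMethod("show", "EmgRecording", function(object) {
  cat(sprintf(
    "EmgRecording: subject %s, gesture %d, repetition %d\n  %d channels x %d samples @ %g Hz\n",
    object@subjectId, object@gestureId, object@repetitionId,
    nrow(object@signal), ncol(object@signal), object@samplingRate))
})

setMethod("show", "EmgDataset", function(object) {
  sid <- subjectIds(object)
  cat(sprintf(
    "EmgDataset: %d recordings, %d subjects, %d gesture classes\n  %d channels @ %g Hz; classes: %s\n",
    length(object@recordings), length(sid), length(object@classNames),
    object@channelCount, object@samplingRate,
    paste(object@classNames, collapse = ", ")))
})

setMethod("show", "WindowSet", function(object) {
  d <- dim(object@windows)
  cat(sprintf(
    "WindowSet: %d windows of %d channels x %d samples (%d subjects, %d classes)\n",
    d[1], d[2], d[3], length(unique(object@subjectIds)),
    length(unique(object@gestureLabels))))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix (%s): %d windows x %d features\n",
              object@featureSet, nrow(object@values), ncol(object@values)))
})

setMethod("show", "CcaProjection", function(object) {
  cat(sprintf(
    "CcaProjection: target %s -> expert %s (%d x %d, lambda = %g)\n",
    object@targetId, object@expertId, nrow(object@W), ncol(object@W),
    object@lambda))
})

setMethod("show", "EvaluationResult", function(object) {
  cat(sprintf("EvaluationResult [%s / %s]\n", object@framework,
              object@pipeline))
  acc <- object@accuracies
  cat(sprintf("  %d subjects, mean accuracy %.3f (sd %.3f)\n",
              length(acc), mean(acc),
              if (length(acc) > 1) stats::sd(acc) else 0))
})
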