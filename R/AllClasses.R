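#' @import methods
#' @importFrom stats rnorm runif sd var predict aggregate setNames dist
#' @importFrom utils modifyList tail write.table
#' @useDynLib emgadapt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' EmgRecording: one repetition of one gesture by one subject
#'
#' Holds a channels x samples matrix of raw (or filtered) surface-EMG
#' amplitudes together with its identifying metadata. Amplitude units are
#' unconstrained; nothing downstream may assume a fixed scale.
#'
#' @slot signal numeric matrix, channels x samples.
#' @slot subjectId character scalar identifying the subject.
#' @slot gestureId integer gesture class label, zero-based (0 .. C-1).
#' @slot repetitionId integer repetition index, zero-based.
#' @slot samplingRate sampling rate in Hz (> 0).
#' @export
setClass("EmgRecording",
  representation(
    signal = "matrix",
    subjectId = "character",
    gestureId = "integer",
    repetitionId = "integer",
    samplingRate = "numeric"
  )
)

setValidity("EmgRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@signal) || nrow(object@signal) < 1L ||
      ncol(object@signal) < 1L)
    msg <- c(msg, "signal must be a numeric matrix with >= 1 channel and >= 1 sample")
  if (any(!is.finite(object@signal)))
    msg <- c(msg, "signal contains non-finite values")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a positive scalar")
  if (length(object@subjectId) != 1L)
    msg <- c(msg, "subjectId must be a single identifier")
  if (length(object@gestureId) != 1L || object@gestureId < 0L)
    msg <- c(msg, "gestureId must be a single non-negative integer")
  if (length(object@repetitionId) != 1L || object@repetitionId < 0L)
    msg <- c(msg, "repetitionId must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

#' Construct an EmgRecording
#'
#' @param signal channels x samples numeric matrix.
#' @param subjectId subject identifier (coerced to character).
#' @param gestureId zero-based gesture label.
#' @param repetitionId zero-based repetition index.
#' @param samplingRate sampling rate in Hz.
#' @return An \linkS4class{EmgRecording}.
#' @export
EmgRecording <- function(signal, subjectId, gestureId, repetitionId,
                         samplingRate) {
  new("EmgRecording",
      signal = signal,
      subjectId = as.character(subjectId),
      gestureId = as.integer(gestureId),
      repetitionId = as.integer(repetitionId),
      samplingRate = as.numeric(samplingRate))
}

#' EmgDataset: a multi-subject collection of EMG recordings
#'
#' All recordings share channel count and sampling rate;
#' (subject, gesture, repetition) triples are unique, and every subject
#' provides the same gesture set. Gesture labels are dense zero-based
#' integers indexing \code{classNames}; the names are metadata only.
#'
#' @slot recordings list of \linkS4class{EmgRecording}.
#' @slot classNames ordered character vector of gesture names.
#' @slot channelCount integer number of channels.
#' @slot samplingRate shared sampling rate in Hz.
#' @export
setClass("EmgDataset",
  representation(
    recordings = "list",
    classNames = "character",
    channelCount = "integer",
    samplingRate = "numeric"
  )
)

setValidity("EmgDataset", function(object) {
  msg <- character()
  recs <- object@recordings
  if (!length(recs))
    return("dataset contains no recordings")
  if (!all(vapply(recs, is, logical(1), "EmgRecording")))
    return("recordings must all be EmgRecording objects")
  fs <- vapply(recs, function(r) r@samplingRate, numeric(1))
  if (length(unique(fs)) != 1L || fs[1] != object@samplingRate)
    msg <- c(msg, "all recordings must share the dataset samplingRate")
  nch <- vapply(recs, function(r) nrow(r@signal), integer(1))
  if (any(nch != object@channelCount))
    msg <- c(msg, "all recordings must share the dataset channelCount")
  gid <- vapply(recs, function(r) r@gestureId, integer(1))
  if (any(gid >= length(object@classNames)))
    msg <- c(msg, "gestureId out of range of classNames")
  key <- recordingKeys(object)
  if (anyDuplicated(key))
    msg <- c(msg, "duplicated (subject, gesture, repetition) triple")
  sid <- vapply(recs, function(r) r@subjectId, character(1))
  gsets <- tapply(gid, sid, function(g) paste(sort(unique(g)), collapse = ","))
  if (length(unique(gsets)) != 1L)
    msg <- c(msg, "every subject must have the same gesture set")
  if (length(msg)) msg else TRUE
})

#' Construct an EmgDataset
#'
#' @param recordings list of \linkS4class{EmgRecording}.
#' @param classNames ordered gesture names; labels index this vector.
#' @return An \linkS4class{EmgDataset}.
#' @export
EmgDataset <- function(recordings, classNames) {
  stopifnot(length(recordings) > 0L)
  new("EmgDataset",
      recordings = recordings,
      classNames = as.character(classNames),
      channelCount = nrow(recordings[[1]]@signal),
      samplingRate = recordings[[1]]@samplingRate)
}

#' WindowSet: windowed signal frames with labels
#'
#' @slot windows n x channels x samplesPerWindow numeric array.
#' @slot gestureLabels length-n zero-based integer labels.
#' @slot subjectIds length-n subject identifiers.
#' @slot repetitionIds length-n zero-based repetition indices.
#' @slot samplingRate sampling rate in Hz.
#' @export
setClass("WindowSet",
  representation(
    windows = "array",
    gestureLabels = "integer",
    subjectIds = "character",
    repetitionIds = "integer",
    samplingRate = "numeric"
  )
)

setValidity("WindowSet", function(object) {
  d <- dim(object@windows)
  if (length(d) != 3L)
    return("windows must be an n x channels x samples array")
  n <- d[1]
  if (length(object@gestureLabels) != n ||
      length(object@subjectIds) != n ||
      length(object@repetitionIds) != n)
    return("label vectors must have length n")
  TRUE
})

#' Construct a WindowSet
#'
#' @param windows n x channels x samples array.
#' @param gestureLabels,subjectIds,repetitionIds length-n label vectors.
#' @param samplingRate sampling rate in Hz.
#' @return A \linkS4class{WindowSet}.
#' @export
WindowSet <- function(windows, gestureLabels, subjectIds, repetitionIds,
                      samplingRate) {
  new("WindowSet", windows = windows,
      gestureLabels = as.integer(gestureLabels),
      subjectIds = as.character(subjectIds),
      repetitionIds = as.integer(repetitionIds),
      samplingRate = as.numeric(samplingRate))
}

#' FeatureMatrix: per-window handcrafted feature vectors
#'
#' @slot values n x d numeric matrix; row i is window i's concatenated
#'   per-channel feature vector.
#' @slot featureSet one of "TD", "TDAR", "TDPSD", "LSF4", "LSF9".
#' @slot gestureLabels,subjectIds,repetitionIds length-n label vectors.
#' @export
setClass("FeatureMatrix",
  representation(
    values = "matrix",
    featureSet = "character",
    gestureLabels = "integer",
    subjectIds = "character",
    repetitionIds = "integer"
  )
)

setValidity("FeatureMatrix", function(object) {
  n <- nrow(object@values)
  msg <- character()
  if (any(!is.finite(object@values)))
    msg <- c(msg, "feature values contain non-finite entries")
  if (length(object@gestureLabels) != n ||
      length(object@subjectIds) != n ||
      length(object@repetitionIds) != n)
    msg <- c(msg, "label vectors must have length n")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureMatrix
#'
#' @param values n x d numeric matrix.
#' @param featureSet feature-set name.
#' @param gestureLabels,subjectIds,repetitionIds length-n label vectors.
#' @return A \linkS4class{FeatureMatrix}.
#' @export
FeatureMatrix <- function(values, featureSet, gestureLabels, subjectIds,
                          repetitionIds) {
  new("FeatureMatrix", values = values, featureSet = as.character(featureSet),
      gestureLabels = as.integer(gestureLabels),
      subjectIds = as.character(subjectIds),
      repetitionIds = as.integer(repetitionIds))
}

#' CcaProjection: linear map from a target subject's feature space to an
#' expert subject's feature space
#'
#' Learned by ridge-regularized least squares on class-paired,
#' standardized feature samples; \code{W} maps a standardized target row t
#' to the expert space as \eqn{W^T t}.
#'
#' @slot W k x d projection matrix (k = d here).
#' @slot lambda ridge penalty (default 0.04).
#' @slot expertId,targetId subject identifiers.
#' @slot expertCenter,expertScale,targetCenter,targetScale per-feature
#'   standardization parameters (population standard deviation).
#' @export
setClass("CcaProjection",
  representation(
    W = "matrix",
    lambda = "numeric",
    expertId = "character",
    targetId = "character",
    expertCenter = "numeric",
    expertScale = "numeric",
    targetCenter = "numeric",
    targetScale = "numeric"
  )
)

setValidity("CcaProjection", function(object) {
  msg <- character()
  if (any(!is.finite(object@W))) msg <- c(msg, "W must be finite")
  if (object@lambda <= 0) msg <- c(msg, "lambda must be > 0")
  if (length(msg)) msg else TRUE
})

#' EvaluationResult: per-subject accuracies under a named framework
#'
#' @slot framework one of "within_subject", "single_repetition",
#'   "cross_subject".
#' @slot pipeline pipeline name, e.g. "LSF9", "CCA_TD", "CNN", "ADANN".
#' @slot accuracies named numeric vector, one entry per subject.
#' @slot confusion named list of C x C count matrices (rows = truth).
#' @slot fingerprint character hash of the specs and seeds that produced
#'   the result.
#' @export
setClass("EvaluationResult",
  representation(
    framework = "character",
    pipeline = "character",
    accuracies = "numeric",
    confusion = "list",
    fingerprint = "character"
  )
)

setValidity("EvaluationResult", function(object) {
  msg <- character()
  if (any(object@accuracies < 0 | object@accuracies > 1))
    msg <- c(msg, "accuracies must lie in [0, 1]")
  for (s in names(object@confusion)) {
    cm <- object@confusion[[s]]
    if (!is.null(cm) && s %in% names(object@accuracies)) {
      acc <- sum(diag(cm)) / sum(cm)
      if (abs(acc - object@accuracies[[s]]) > 1e-8)
        msg <- c(msg, sprintf("accuracy for %s does not match confusion trace", s))
    }
  }
  if (length(msg)) msg else TRUE
})

EvaluationResult <- function(framework, pipeline, accuracies, confusion,
                             fingerprint = "") {
  new("EvaluationResult", framework = framework, pipeline = pipeline,
      accuracies = accuracies, confusion = confusion,
      fingerprint = fingerprint)
}
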