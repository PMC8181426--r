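# Cross-user adaptation by CCA-style regularized least squares: learn a
# linear projection from a target subject's (standardized) feature space
# into an expert subject's, train one pooled LDA in the expert space,
# and adapt a new user from a single repetition of each gesture.

#' PairedFeatureSet: class-aligned expert/target feature samples
#'
#' Rows are aligned so that \code{expertSamples[i, ]} and
#' \code{targetSamples[i, ]} carry the same gesture label
#' (\code{labels[i]}); classes are stacked in ascending label order.
#'
#' @slot expertSamples n x d standardized expert matrix.
#' @slot targetSamples n x k standardized target matrix.
#' @slot labels length-n gesture labels.
#' @export
setClass("PairedFeatureSet",
  representation(expertSamples = "matrix", targetSamples = "matrix",
                 labels = "integer"))

setValidity("PairedFeatureSet", function(object) {
  if (nrow(object@expertSamples) != nrow(object@targetSamples))
    return("expert and target must have equal row counts")
  if (length(object@labels) != nrow(object@expertSamples))
    return("labels must have length n")
  TRUE
})

#' Standardize a feature matrix to zero mean and unit variance
#'
#' Uses the population (1/n) standard deviation. Zero-variance columns
#' are mapped to zero with a unit divisor recorded in the returned
#' scale vector (a message notes how many).
#'
#' @param features a \linkS4class{FeatureMatrix} or plain matrix.
#' @param center,scale optionally reuse previously computed parameters
#'   (e.g. standardize test data with adaptation-set statistics).
#' @return A list with elements \code{features} (same type as input),
#'   \code{center} and \code{scale}.
#' @export
standardizeFeatures <- function(features, center = NULL, scale = NULL) {
  x <- if (is(features, "FeatureMatrix")) featureValues(features)
       else as.matrix(features)
  if (!nrow(x)) stop("empty input")
  if (is.null(center)) {
    if (nrow(x) < 2) stop("need at least 2 rows to standardize")
    center <- colMeans(x)
    scale <- sqrt(pmax(colMeans(x^2) - center^2, 0))
    zero <- scale < .Machine$double.eps^0.5 * (1 + abs(center))
    if (any(zero)) {
      message(sum(zero), " zero-variance column(s) mapped to 0")
      scale[zero] <- 1
    }
  }
  z <- sweep(sweep(x, 2, center), 2, scale, "/")
  out <- features
  if (is(features, "FeatureMatrix")) out@values <- z else out <- z
  list(features = out, center = center, scale = scale)
}

#' Pair two subjects' features class by class
#'
#' Per class, rows are taken in their stored (repetition, time) order
#' and truncated to the minimum of the two per-class counts; classes are
#' stacked in ascending label order.
#'
#' @param expert,target \linkS4class{FeatureMatrix} objects (already
#'   standardized) covering the same class set.
#' @return A \linkS4class{PairedFeatureSet}.
#' @export
pairByClass <- function(expert, target) {
  stopifnot(is(expert, "FeatureMatrix"), is(target, "FeatureMatrix"))
  cls <- sort(union(unique(gestureLabels(expert)),
                    unique(gestureLabels(target))))
  missE <- setdiff(cls, unique(gestureLabels(expert)))
  missT <- setdiff(cls, unique(gestureLabels(target)))
  if (length(missE) || length(missT))
    stop("class(es) absent: ",
         if (length(missE)) paste0("expert lacks ",
                                   paste(missE, collapse = ",")) else "",
         if (length(missT)) paste0(" target lacks ",
                                   paste(missT, collapse = ",")) else "")
  eRows <- list(); tRows <- list(); labs <- list()
  for (cl in cls) {
    ei <- which(gestureLabels(expert) == cl)
    ti <- which(gestureLabels(target) == cl)
    m <- min(length(ei), length(ti))
    eRows[[length(eRows) + 1L]] <- featureValues(expert)[ei[seq_len(m)], ,
                                                         drop = FALSE]
    tRows[[length(tRows) + 1L]] <- featureValues(target)[ti[seq_len(m)], ,
                                                         drop = FALSE]
    labs[[length(labs) + 1L]] <- rep(cl, m)
  }
  new("PairedFeatureSet",
      expertSamples = do.call(rbind, eRows),
      targetSamples = do.call(rbind, tRows),
      labels = as.integer(unlist(labs)))
}

#' Fit the ridge-regularized least-squares projection
#'
#' Solves \eqn{\min_W \sum_i \|W^T t_i - x_i\|_2^2 + \lambda \|W\|^2} in
#' closed form: \eqn{W = (T^T T + \lambda I)^{-1} T^T X} with T the
#' n x k target matrix and X the n x d expert matrix.
#'
#' @param paired a \linkS4class{PairedFeatureSet}.
#' @param lambda ridge penalty (default 0.04).
#' @param expertId,targetId identifiers stored on the projection.
#' @param expertStd,targetStd lists with \code{center}/\code{scale}
#'   standardization parameters to carry along.
#' @return A \linkS4class{CcaProjection}.
#' @export
fitProjection <- function(paired, lambda = 0.04, expertId = "expert",
                          targetId = "target", expertStd = NULL,
                          targetStd = NULL) {
  stopifnot(is(paired, "PairedFeatureSet"), lambda > 0)
  Tm <- paired@targetSamples
  X <- paired@expertSamples
  n <- nrow(Tm); k <- ncol(Tm); d <- ncol(X)
  if (n < d)
    stop("only ", n, " paired samples for ", d, " features; supply more ",
         "adaptation data or increase lambda")
  G <- crossprod(Tm) + diag(lambda, k)
  W <- tryCatch(solve(G, crossprod(Tm, X)), error = function(e)
    stop("projection system singular even with lambda = ", lambda, ": ",
         conditionMessage(e)))
  if (any(!is.finite(W))) stop("non-finite projection")
  emptyStd <- function(p) list(center = numeric(p), scale = rep(1, p))
  if (is.null(expertStd)) expertStd <- emptyStd(d)
  if (is.null(targetStd)) targetStd <- emptyStd(k)
  new("CcaProjection", W = W, lambda = lambda,
      expertId = as.character(expertId), targetId = as.character(targetId),
      expertCenter = expertStd$center, expertScale = expertStd$scale,
      targetCenter = targetStd$center, targetScale = targetStd$scale)
}

#' Project target-subject features into the expert space
#'
#' Rows are mapped as \eqn{W^T t_i}. With \code{standardize = TRUE} the
#' stored target standardization is applied first (the convention for
#' raw test-set features; adaptation-set statistics are reused, never
#' recomputed from test data).
#'
#' @param projection a \linkS4class{CcaProjection}.
#' @param features a \linkS4class{FeatureMatrix} or matrix.
#' @param standardize apply the stored target center/scale first.
#' @return Same type as \code{features}, mapped into the expert space.
#' @export
projectFeatures <- function(projection, features, standardize = FALSE) {
  stopifnot(is(projection, "CcaProjection"))
  x <- if (is(features, "FeatureMatrix")) featureValues(features)
       else as.matrix(features)
  if (ncol(x) != nrow(projection@W))
    stop("feature dimension (", ncol(x), ") does not match projection (",
         nrow(projection@W), ")")
  if (standardize)
    x <- sweep(sweep(x, 2, projection@targetCenter), 2,
               projection@targetScale, "/")
  z <- x %*% projection@W
  out <- features
  if (is(features, "FeatureMatrix")) out@values <- z else out <- z
  out
}

#' Run the full CCA cross-user pipeline for one target subject
#'
#' For each expert among the training subjects: every other training
#' subject's training repetitions are standardized (own statistics),
#' paired with the expert's standardized training data, and projected
#' into the expert space; one pooled LDA is fit on all projected
#' training data plus the expert's own (unprojected) data; the target
#' learns its projection from the single adaptation repetition, and the
#' test repetitions (standardized with the adaptation-set statistics)
#' are projected and classified. With \code{expertId = "all"} the
#' reported accuracy is the mean over expert choices.
#'
#' @param dataset an \linkS4class{EmgDataset}.
#' @param targetId the held-out target subject.
#' @param expertId a training-subject id, or "all" (default).
#' @param feature a \code{\link{featureSpec}}.
#' @param filter a \code{\link{filterSpec}} (NULL to skip filtering).
#' @param window a \code{\link{windowSpec}}.
#' @param lambda ridge penalty (default 0.04).
#' @param trainReps,adaptRep,testReps repetition splits (defaults 0-7,
#'   8, 9-15).
#' @return An \linkS4class{EvaluationResult} with one accuracy entry for
#'   the target subject.
#' @export
runCcaPipeline <- function(dataset, targetId, expertId = "all",
                           feature = featureSpec("TD"),
                           filter = filterSpec(), window = windowSpec(),
                           lambda = 0.04, trainReps = 0:7, adaptRep = 8L,
                           testReps = 9:15) {
  stopifnot(is(dataset, "EmgDataset"))
  subjects <- subjectIds(dataset)
  if (!targetId %in% subjects) stop("unknown target subject: ", targetId)
  trainers <- setdiff(subjects, targetId)
  experts <- if (identical(expertId, "all")) trainers else expertId
  if (!all(experts %in% trainers))
    stop("expert must be a training subject distinct from the target")
  featsOf <- function(subj, reps)
    extractFeatures(windowsForSubset(dataset, subj, reps, filter, window),
                    feature)
  trainFeats <- lapply(trainers, featsOf, reps = trainReps)
  names(trainFeats) <- trainers
  adaptF <- featsOf(targetId, adaptRep)
  testF <- featsOf(targetId, testReps)
  adaptStd <- standardizeFeatures(adaptF)
  C <- length(dataset@classNames)
  classIds <- seq_len(C) - 1L
  confusion <- matrix(0L, C, C, dimnames = list(truth = classIds,
                                                predicted = classIds))
  accs <- numeric(0)
  for (ex in experts) {
    exStd <- standardizeFeatures(trainFeats[[ex]])
    pooledX <- list(featureValues(exStd$features))
    pooledY <- list(gestureLabels(exStd$features))
    for (tr in setdiff(trainers, ex)) {
      trStd <- standardizeFeatures(trainFeats[[tr]])
      proj <- fitProjection(pairByClass(exStd$features, trStd$features),
                            lambda, ex, tr, exStd, trStd)
      pooledX[[length(pooledX) + 1L]] <-
        featureValues(projectFeatures(proj, trStd$features))
      pooledY[[length(pooledY) + 1L]] <- gestureLabels(trStd$features)
    }
    model <- fitLda(do.call(rbind, pooledX), unlist(pooledY))
    projT <- fitProjection(pairByClass(exStd$features, adaptStd$features),
                           lambda, ex, targetId, exStd, adaptStd)
    testStd <- standardizeFeatures(testF, adaptStd$center, adaptStd$scale)
    pred <- predictLda(model, projectFeatures(projT, testStd$features))
    accs <- c(accs, accuracy(pred, gestureLabels(testF)))
    confusion <- confusion +
      confusionCounts(pred, gestureLabels(testF), classIds)
  }
  acc <- stats::setNames(mean(accs), targetId)
  conf <- stats::setNames(list(confusion), targetId)
  EvaluationResult("cross_subject", paste0("CCA_", feature$setName),
                   acc, conf,
                   fingerprint = fingerprintOf(list("cca", targetId,
                                                    expertId, feature,
                                                    lambda)))
}

# Cheap deterministic fingerprint of a spec list (no external digest
# dependency): hash of the deparsed structure.
fingerprintOf <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (v in utf8ToInt(s)) h <- (h * 33 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}
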