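# The three evaluation frameworks: within-subject (8/8 repetitions),
# single-repetition (1 training repetition), and leave-one-subject-out
# cross-subject (8 trainer-train / 8 trainer-validation; target:
# 8 unused / 1 adaptation / 7 test).

HANDCRAFTED_SETS <- c("TD", "TDAR", "TDPSD", "LSF4", "LSF9")

#' Repetition splits of the evaluation frameworks
#'
#' Repetition-to-split assignment is by index order (deterministic), for
#' a 16-repetition protocol by default.
#'
#' @param framework "within_subject", "single_repetition" or
#'   "cross_subject".
#' @param nRepetitions total repetitions per gesture (default 16).
#' @return Named list of zero-based repetition index vectors.
#' @export
frameworkSplits <- function(framework = c("within_subject",
                                          "single_repetition",
                                          "cross_subject"),
                            nRepetitions = 16L) {
  framework <- match.arg(framework)
  if (nRepetitions < 16L && framework != "within_subject")
    stop("frameworks are defined for >= 16 repetitions")
  half <- nRepetitions %/% 2L
  switch(framework,
    within_subject = list(train = 0:(half - 1L),
                          test = half:(nRepetitions - 1L)),
    single_repetition = list(train = 0L,
                             test = half:(nRepetitions - 1L)),
    cross_subject = list(trainerTrain = 0:(half - 1L),
                         trainerVal = half:(nRepetitions - 1L),
                         targetUnused = 0:(half - 1L),
                         targetAdapt = half,
                         targetTest = (half + 1L):(nRepetitions - 1L)))
}

pipelineFeatureSpec <- function(pipeline, feature = NULL) {
  setName <- sub("^CCA_", "", pipeline)
  if (!setName %in% HANDCRAFTED_SETS)
    stop("no handcrafted feature set for pipeline ", pipeline)
  if (is.null(feature)) featureSpec(setName)
  else modifyList(feature, list(setName = setName))
}

resultFor <- function(framework, pipeline, perSubject, fingerprint) {
  EvaluationResult(framework, pipeline,
                   vapply(perSubject, `[[`, numeric(1), "accuracy"),
                   lapply(perSubject, `[[`, "confusion"),
                   fingerprint)
}

#' Within-subject evaluation (full training protocol)
#'
#' Per subject independently: repetitions 0-7 train, 8-15 test.
#' Handcrafted pipelines fit an LDA on the named feature set; the CNN
#' pipeline trains the network with the last two training repetitions
#' held out as validation.
#'
#' @param dataset an \linkS4class{EmgDataset} (>= 16 repetitions).
#' @param pipeline one of "TD", "TDAR", "TDPSD", "LSF4", "LSF9", "CNN".
#' @param filter,window preprocessing specs.
#' @param feature optional \code{\link{featureSpec}} overriding
#'   thresholds (its set name is replaced by \code{pipeline}).
#' @param net,training configs for the CNN pipeline.
#' @param seed seed for network training.
#' @return An \linkS4class{EvaluationResult} with one accuracy per
#'   subject.
#' @export
runWithinSubject <- function(dataset, pipeline = "TD",
                             filter = filterSpec(), window = windowSpec(),
                             feature = NULL, net = NULL, training = NULL,
                             seed = 1) {
  stopifnot(is(dataset, "EmgDataset"))
  reps <- sort(unique(repetitionIds(dataset)))
  splits <- frameworkSplits("within_subject", length(reps))
  subjects <- subjectIds(dataset)
  C <- length(dataset@classNames)
  classIds <- seq_len(C) - 1L
  perSubject <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    trainWs <- windowsForSubset(dataset, s, splits$train, filter, window)
    testWs <- windowsForSubset(dataset, s, splits$test, filter, window)
    if (pipeline %in% HANDCRAFTED_SETS) {
      fspec <- pipelineFeatureSpec(pipeline, feature)
      model <- fitLda(extractFeatures(trainWs, fspec))
      pred <- predictLda(model, extractFeatures(testWs, fspec))
    } else if (pipeline == "CNN") {
      valReps <- utils::tail(splits$train, 2L)       # last 2 of 8
      coreReps <- setdiff(splits$train, valReps)
      coreWs <- windowsForSubset(dataset, s, coreReps, filter, window)
      valWs <- windowsForSubset(dataset, s, valReps, filter, window)
      net0 <- if (is.null(net))
        networkConfig(nChannels = channelCount(dataset), nClasses = C)
      else net
      tr0 <- if (is.null(training)) trainingConfig() else training
      tr0$seed <- deriveSeed(seed, i, 41L)
      cnn <- buildCnn(net0, seed = tr0$seed)
      cnn <- trainCnn(cnn, coreWs, valWs, tr0)
      pred <- predictWindows(cnn, testWs, "shared")
    } else {
      stop("pipeline '", pipeline,
           "' is not available in the within-subject framework")
    }
    truth <- gestureLabels(testWs)
    perSubject[[s]] <- list(
      accuracy = accuracy(pred, truth),
      confusion = confusionCounts(pred, truth, classIds))
  }
  resultFor("within_subject", pipeline, perSubject,
            fingerprintOf(list("within", pipeline, seed)))
}

#' Single-repetition evaluation (minimal training protocol)
#'
#' Per subject: repetition 0 of each gesture trains an LDA; repetitions
#' 8-15 test (the same test half as the within-subject framework, for
#' comparability). Only handcrafted feature pipelines are defined here:
#' deep models are excluded because no repetitions remain to serve as a
#' validation set.
#'
#' @inheritParams runWithinSubject
#' @return An \linkS4class{EvaluationResult}.
#' @export
runSingleRepetition <- function(dataset, pipeline = "TD",
                                filter = filterSpec(),
                                window = windowSpec(), feature = NULL) {
  stopifnot(is(dataset, "EmgDataset"))
  if (!pipeline %in% HANDCRAFTED_SETS)
    stop("the single-repetition framework evaluates handcrafted feature ",
         "sets only (no validation data remains for deep pipelines); got '",
         pipeline, "'")
  reps <- sort(unique(repetitionIds(dataset)))
  splits <- frameworkSplits("single_repetition", length(reps))
  subjects <- subjectIds(dataset)
  C <- length(dataset@classNames)
  classIds <- seq_len(C) - 1L
  fspec <- pipelineFeatureSpec(pipeline, feature)
  perSubject <- list()
  for (s in subjects) {
    trainWs <- windowsForSubset(dataset, s, splits$train, filter, window)
    testWs <- windowsForSubset(dataset, s, splits$test, filter, window)
    model <- fitLda(extractFeatures(trainWs, fspec))
    pred <- predictLda(model, extractFeatures(testWs, fspec))
    truth <- gestureLabels(testWs)
    perSubject[[s]] <- list(
      accuracy = accuracy(pred, truth),
      confusion = confusionCounts(pred, truth, classIds))
  }
  resultFor("single_repetition", pipeline, perSubject,
            fingerprintOf(list("single_rep", pipeline)))
}

#' Leave-one-subject-out cross-subject evaluation
#'
#' For each fold one subject is the target: all other subjects train
#' (repetitions 0-7) and validate (8-15); the target's repetitions 0-7
#' are untouched, repetition 8 is the adaptation set and repetitions
#' 9-15 are the test set. Pipelines: "CCA_<set>" (projection per
#' expert, mean over experts), "CNN" (naive pooled model, no
#' adaptation) and "ADANN" (domain-adversarial training plus
#' single-repetition batch-normalization adaptation).
#'
#' @inheritParams runWithinSubject
#' @param pipeline "CCA_TD" ... "CCA_LSF9", "CNN" or "ADANN".
#' @param lambda CCA ridge penalty.
#' @param targets optional subset of subjects to use as folds (default:
#'   every subject in turn).
#' @return An \linkS4class{EvaluationResult} with one accuracy per
#'   target subject.
#' @export
runCrossSubject <- function(dataset, pipeline = "ADANN",
                            filter = filterSpec(), window = windowSpec(),
                            feature = NULL, net = NULL, training = NULL,
                            lambda = 0.04, seed = 1, targets = NULL) {
  stopifnot(is(dataset, "EmgDataset"))
  subjects <- subjectIds(dataset)
  if (length(subjects) < 3) stop("cross-subject evaluation needs >= 3 subjects")
  if (is.null(targets)) targets <- subjects
  stopifnot(all(targets %in% subjects))
  reps <- sort(unique(repetitionIds(dataset)))
  splits <- frameworkSplits("cross_subject", length(reps))
  C <- length(dataset@classNames)
  classIds <- seq_len(C) - 1L
  perSubject <- list()
  for (fold in seq_along(targets)) {
    target <- targets[fold]
    trainers <- setdiff(subjects, target)
    if (startsWith(pipeline, "CCA_")) {
      fspec <- pipelineFeatureSpec(pipeline, feature)
      res <- runCcaPipeline(dataset, target, "all", fspec, filter, window,
                            lambda, splits$trainerTrain,
                            splits$targetAdapt, splits$targetTest)
      perSubject[[target]] <- list(accuracy = accuracies(res)[[target]],
                                   confusion = confusionMatrices(res)[[target]])
      next
    }
    trainWs <- windowsForSubset(dataset, trainers, splits$trainerTrain,
                                filter, window)
    valWs <- windowsForSubset(dataset, trainers, splits$trainerVal,
                              filter, window)
    testWs <- windowsForSubset(dataset, target, splits$targetTest,
                               filter, window)
    stopifnot(!target %in% subjectIds(trainWs),
              !target %in% subjectIds(valWs))
    net0 <- if (is.null(net))
      networkConfig(nChannels = channelCount(dataset), nClasses = C)
    else net
    tr0 <- if (is.null(training)) trainingConfig() else training
    tr0$seed <- deriveSeed(seed, fold, 97L)
    if (pipeline == "CNN") {
      model <- buildCnn(net0, seed = tr0$seed)
      model <- trainCnn(model, trainWs, valWs, tr0)
      pred <- predictWindows(model, testWs, "shared")
    } else if (pipeline == "ADANN") {
      model <- buildCnn(net0, seed = tr0$seed)
      model <- trainAdann(model, trainWs, valWs, tr0)
      adaptWs <- windowsForSubset(dataset, target, splits$targetAdapt,
                                  filter, window)
      model <- adaptToSubject(model, adaptWs)
      pred <- predictWindows(model, testWs, target)
    } else {
      stop("unknown cross-subject pipeline: ", pipeline)
    }
    truth <- gestureLabels(testWs)
    perSubject[[target]] <- list(
      accuracy = accuracy(pred, truth),
      confusion = confusionCounts(pred, truth, classIds))
  }
  resultFor("cross_subject", pipeline, perSubject,
            fingerprintOf(list("cross", pipeline, lambda, seed, targets)))
}

#' Summarize evaluation results
#'
#' @param results a list of \linkS4class{EvaluationResult} objects (or a
#'   single one).
#' @return A list with \code{table}, a long-format data frame
#'   (framework, pipeline, subject, accuracy) in deterministic order,
#'   and \code{summary}, the per-pipeline mean and sample standard
#'   deviation.
#' @export
summarizeResults <- function(results) {
  if (is(results, "EvaluationResult")) results <- list(results)
  stopifnot(length(results) > 0)
  fps <- vapply(results, function(r) r@fingerprint, character(1))
  rows <- lapply(results, function(r)
    data.frame(framework = r@framework, pipeline = r@pipeline,
               subject = names(r@accuracies),
               accuracy = as.numeric(r@accuracies),
               row.names = NULL))
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$framework, tab$pipeline, tab$subject), ,
             drop = FALSE]
  rownames(tab) <- NULL
  agg <- aggregate(accuracy ~ framework + pipeline, tab, function(a)
    c(mean = mean(a), sd = if (length(a) > 1) stats::sd(a) else NA_real_,
      n = length(a)))
  summary <- data.frame(framework = agg$framework, pipeline = agg$pipeline,
                        mean = agg$accuracy[, "mean"],
                        sd = agg$accuracy[, "sd"], n = agg$accuracy[, "n"])
  summary <- summary[order(summary$framework, summary$pipeline), ,
                     drop = FALSE]
  rownames(summary) <- NULL
  list(table = tab, summary = summary)
}

#' Write a summary as tab-delimited text
#'
#' @param results as in \code{\link{summarizeResults}}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeResultsTsv <- function(results, path) {
  s <- summarizeResults(results)
  utils::write.table(s$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Box plot of per-subject accuracies by pipeline
#'
#' @param results as in \code{\link{summarizeResults}}.
#' @return A ggplot object.
#' @export
plotResults <- function(results) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotResults requires ggplot2")
  tab <- summarizeResults(results)$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$pipeline,
                                    y = .data$accuracy)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::facet_wrap(~framework, scales = "free_x") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "per-window accuracy")
}
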