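# Desk-scale cross-user benchmark on synthetic data: the qualitative
# reproduction of the study's orderings (within-subject > adapted
# cross-subject > naive cross-subject > chance) at reduced network and
# dataset scale.

#' Cross-user benchmark on synthetic EMG
#'
#' For each of \code{nSeeds} master seeds, generates a 7-subject
#' synthetic dataset (6 training subjects + 1 held-out target; 7
#' gestures, 16 repetitions, 10 channels, 1 s per repetition), trains a
#' reduced-scale naive pooled CNN and an ADANN on the training
#' subjects (repetitions 0-7 train, 8-15 validation), adapts the ADANN
#' to the target from the single adaptation repetition (repetition 8),
#' and evaluates both on the target's seven test repetitions (9-15).
#' Within-subject and single-repetition TD/LDA accuracies are computed
#' for every subject of the same datasets, and a CCA/TD cross-subject
#' fold is run for the first seed.
#'
#' The reduced problem sizes (2 convolutional blocks of 8 kernels,
#' 9 training epochs, 1 s repetitions windowed at 151/100 ms) keep the
#' benchmark desk-scale; the full-scale architecture runs through the
#' same code path. Both deep models also report their unadapted
#' (shared-statistics) target accuracy so the adaptation benefit is
#' visible separately.
#'
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param nSeeds number of independent replicates (default 3).
#' @param nEpochs training epochs for both deep models (default 9).
#' @param kernels,nBlocks reduced network size (defaults 8, 2).
#' @param durationS seconds per synthetic repetition (default 1).
#' @param incrementMs window increment (default 100).
#' @param withCca also run the CCA/TD fold on the first replicate.
#' @param verbose print progress lines.
#' @return A list with per-seed accuracies and their means:
#'   \code{adann}, \code{cnn}, \code{ldaWithin}, \code{ldaSingleRep},
#'   \code{ccaTd} (or NA), and \code{chance}.
#' @export
runSyntheticBenchmark <- function(seed = 1, nSeeds = 3, nEpochs = 9,
                                  kernels = 8, nBlocks = 2,
                                  durationS = 1, incrementMs = 100,
                                  withCca = TRUE, verbose = FALSE) {
  wspec <- windowSpec(151, incrementMs)
  fspec <- featureSpec("TD")
  splits <- frameworkSplits("cross_subject")
  wsplits <- frameworkSplits("within_subject")
  ssplits <- frameworkSplits("single_repetition")
  out <- list(adann = numeric(0), cnn = numeric(0),
              adannUnadapted = numeric(0),
              ldaWithin = numeric(0), ldaSingleRep = numeric(0),
              ccaTd = NA_real_)
  say <- function(...) if (verbose) message(sprintf(...))
  for (k in seq_len(nSeeds)) {
    sk <- deriveSeed(seed, k, 555L)
    cfg <- simConfig(nSubjects = 7, durationS = durationS, seed = sk)
    ds <- generateDataset(cfg)
    subjects <- subjectIds(ds)
    target <- subjects[length(subjects)]
    trainers <- setdiff(subjects, target)
    allWs <- windowsForSubset(ds, window = wspec)
    pick <- function(subj, reps)
      subsetWindows(allWs, which(subjectIds(allWs) %in% subj &
                                   repetitionIds(allWs) %in% reps))
    trainWs <- pick(trainers, splits$trainerTrain)
    valWs <- pick(trainers, splits$trainerVal)
    adaptWs <- pick(target, splits$targetAdapt)
    testWs <- pick(target, splits$targetTest)
    truth <- gestureLabels(testWs)
    net <- networkConfig(nBlocks = nBlocks, kernels = kernels,
                         nChannels = channelCount(ds),
                         nClasses = length(classNames(ds)))
    tc <- trainingConfig(maxEpochs = nEpochs, seed = sk)
    cnn <- trainCnn(buildCnn(net, sk), trainWs, valWs, tc)
    accCnn <- accuracy(predictWindows(cnn, testWs, "shared"), truth)
    adann <- trainAdann(buildCnn(net, sk), trainWs, valWs, tc)
    accUnadapted <- accuracy(predictWindows(adann, testWs, "shared"),
                             truth)
    adann <- adaptToSubject(adann, adaptWs)
    accAdann <- accuracy(predictWindows(adann, testWs, target), truth)
    say("seed %d: ADANN %.3f (unadapted %.3f), naive CNN %.3f", sk,
        accAdann, accUnadapted, accCnn)
    # window-level TD/LDA baselines, every subject of the same dataset
    feats <- extractFeatures(allWs, fspec)
    featPick <- function(subj, reps) {
      idx <- which(subjectIds(feats) %in% subj &
                     repetitionIds(feats) %in% reps)
      FeatureMatrix(featureValues(feats)[idx, , drop = FALSE],
                    featureSetName(feats), gestureLabels(feats)[idx],
                    subjectIds(feats)[idx], repetitionIds(feats)[idx])
    }
    for (s in subjects) {
      teF <- featPick(s, wsplits$test)
      mW <- fitLda(featPick(s, wsplits$train))
      out$ldaWithin <- c(out$ldaWithin,
                         accuracy(predictLda(mW, teF), gestureLabels(teF)))
      mS <- fitLda(featPick(s, ssplits$train))
      out$ldaSingleRep <- c(out$ldaSingleRep,
                            accuracy(predictLda(mS, teF),
                                     gestureLabels(teF)))
    }
    out$adann <- c(out$adann, accAdann)
    out$cnn <- c(out$cnn, accCnn)
    out$adannUnadapted <- c(out$adannUnadapted, accUnadapted)
    if (withCca && k == 1L) {
      cca <- runCcaPipeline(ds, target, "all", fspec, window = wspec)
      out$ccaTd <- as.numeric(accuracies(cca)[[target]])
      say("seed %d: CCA_TD %.3f", sk, out$ccaTd)
    }
  }
  out$meanAdann <- mean(out$adann)
  out$meanCnn <- mean(out$cnn)
  out$meanAdannUnadapted <- mean(out$adannUnadapted)
  out$meanLdaWithin <- mean(out$ldaWithin)
  out$meanLdaSingleRep <- mean(out$ldaSingleRep)
  out$chance <- 1 / 7
  out
}
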