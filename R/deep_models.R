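# The per-channel temporal CNN and the ADANN model (adaptive per-subject
# batch normalization + domain-adversarial training with a two-neuron
# domain head and single-repetition adaptation).

#' Network architecture configuration
#'
#' Defaults are the full-scale architecture: six convolutional blocks
#' (convolution with 64 kernels of size 1 x 21 and "same" temporal
#' padding, batch normalization without learned affine parameters,
#' leaky rectifier with slope 0.1, dropout 0.35), global average
#' pooling over time, and a linear layer mapping
#' kernels x channels features to the class scores. Reduced
#' configurations (fewer blocks/kernels) run the same code path.
#'
#' @param nBlocks number of convolutional blocks (default 6).
#' @param kernels feature maps per block (default 64).
#' @param kernelLength temporal kernel length (default 21).
#' @param bnMomentum batch-normalization momentum: the weight of the
#'   new batch statistics in the running-statistics blend
#'   \code{running <- (1 - m) * running + m * batch} (default 0.99).
#' @param leakySlope negative slope of the leaky rectifier (default 0.1).
#' @param dropoutP dropout probability (default 0.35).
#' @param nChannels input channels (default 10).
#' @param samplesPerFrame samples per window (default 151).
#' @param nClasses gesture classes (default 7).
#' @return A \code{"NetworkConfig"} list.
#' @export
networkConfig <- function(nBlocks = 6, kernels = 64, kernelLength = 21,
                          bnMomentum = 0.99, leakySlope = 0.1,
                          dropoutP = 0.35, nChannels = 10,
                          samplesPerFrame = 151, nClasses = 7) {
  stopifnot(nBlocks >= 1, kernels >= 1, kernelLength >= 1,
            kernelLength %% 2 == 1, bnMomentum > 0, bnMomentum < 1,
            leakySlope > 0, dropoutP >= 0, dropoutP < 1, nChannels >= 1,
            samplesPerFrame >= 1, nClasses >= 2)
  structure(list(nBlocks = as.integer(nBlocks),
                 kernels = as.integer(kernels),
                 kernelLength = as.integer(kernelLength),
                 bnMomentum = bnMomentum, leakySlope = leakySlope,
                 dropoutP = dropoutP, nChannels = as.integer(nChannels),
                 samplesPerFrame = as.integer(samplesPerFrame),
                 nClasses = as.integer(nClasses)),
            class = "NetworkConfig")
}

#' Training configuration
#'
#' Defaults follow the reference training heuristics: initial learning
#' rate 0.04047 with Adam, batch size 256, learning rate divided by 5
#' after 15 epochs without a new minimum of the monitored loss, and
#' training complete when the learning rate drops below 1e-8.
#'
#' @param learningRate initial learning rate (default 0.04047).
#' @param batchSize windows per mini-batch (default 256).
#' @param lrPatience plateau patience in epochs (default 15).
#' @param lrFactor learning-rate decrement factor (default 5).
#' @param lrFloor stopping threshold on the learning rate (default 1e-8).
#' @param adversarialLambda gradient-reversal scale for the domain loss
#'   (default 0.1; ADANN only).
#' @param maxEpochs optional hard cap on epochs (default Inf: the
#'   learning-rate floor is the only stopping rule).
#' @param beta1,beta2,adamEps Adam moment decays and epsilon.
#' @param seed RNG seed for shuffling, dropout and initial draws.
#' @return A \code{"TrainingConfig"} list.
#' @export
trainingConfig <- function(learningRate = 0.04047, batchSize = 256,
                           lrPatience = 15, lrFactor = 5, lrFloor = 1e-8,
                           adversarialLambda = 0.1, maxEpochs = Inf,
                           beta1 = 0.9, beta2 = 0.999, adamEps = 1e-8,
                           seed = 1) {
  stopifnot(lrFloor < learningRate, lrFactor > 1, batchSize >= 2,
            lrPatience >= 1)
  structure(list(learningRate = learningRate,
                 batchSize = as.integer(batchSize),
                 lrPatience = as.integer(lrPatience), lrFactor = lrFactor,
                 lrFloor = lrFloor, adversarialLambda = adversarialLambda,
                 maxEpochs = maxEpochs, beta1 = beta1, beta2 = beta2,
                 adamEps = adamEps, seed = as.integer(seed)),
            class = "TrainingConfig")
}

#' Build an (untrained) convolutional network
#'
#' Weight initialization is deterministic given \code{seed}. The model
#' carries a gesture head (\code{nClasses} outputs), a two-neuron
#' domain head, and a batch-normalization registry with a "shared"
#' entry; batch normalization carries no learned affine parameters, so
#' each block contributes exactly \code{2 * kernels} adaptable
#' statistics (128 for the 64-kernel configuration).
#'
#' @param net a \code{\link{networkConfig}}.
#' @param seed RNG seed for the weight draws.
#' @return An object of class \code{"EmgCnn"}.
#' @export
buildCnn <- function(net = networkConfig(), seed = 1) {
  stopifnot(inherits(net, "NetworkConfig"))
  withSeed(seed, {
    blocks <- vector("list", net$nBlocks)
    for (i in seq_len(net$nBlocks)) {
      fanIn <- (if (i == 1) 1L else net$kernels) * net$kernelLength
      sd <- sqrt(2 / ((1 + net$leakySlope^2) * fanIn))
      blocks[[i]] <- list(W = matrix(rnorm(net$kernels * fanIn, 0, sd),
                                     net$kernels, fanIn))
    }
    dIn <- net$kernels * net$nChannels
    model <- list(
      net = net,
      blocks = blocks,
      linW = matrix(rnorm(net$nClasses * dIn, 0, sqrt(1 / dIn)),
                    net$nClasses, dIn),
      linb = rep(0, net$nClasses),
      domW = matrix(rnorm(2 * dIn, 0, sqrt(1 / dIn)), 2, dIn),
      domb = rep(0, 2),
      bn = list(shared = replicate(net$nBlocks, newBnState(net$kernels),
                                   simplify = FALSE)),
      trainSubjects = character(0),
      history = NULL)
    class(model) <- "EmgCnn"
    model
  })
}

#' @export
print.EmgCnn <- function(x, ...) {
  cat(sprintf(
    "%s: %d blocks x %d kernels (1 x %d), %d channels x %d samples -> %d classes\n",
    if (inherits(x, "AdannModel")) "AdannModel" else "EmgCnn",
    x$net$nBlocks, x$net$kernels, x$net$kernelLength, x$net$nChannels,
    x$net$samplesPerFrame, x$net$nClasses))
  cat(sprintf("  BN registry: %s\n", paste(names(x$bn), collapse = ", ")))
  invisible(x)
}

#' Count of adaptive batch-normalization parameters per block
#'
#' @param model an \code{"EmgCnn"}.
#' @return \code{2 * kernels} (running mean + running variance per
#'   feature map).
#' @export
bnParametersPerBlock <- function(model) {
  st <- model$bn[[1]][[1]]
  length(st$mean) + length(st$var)
}

#' Batch normalization transform
#'
#' Normalizes a (feature maps x observations) activation matrix. In
#' train mode batch statistics are used and the running statistics are
#' blended as \code{running <- (1 - m) * running + m * batch} (the
#' momentum is the weight of the new batch, so a single adaptation
#' sweep moves the running statistics almost entirely to the new
#' subject's); in eval mode the running statistics are used. No learned
#' affine rescaling is applied.
#'
#' @param x maps x observations numeric matrix.
#' @param state list with \code{mean} and \code{var} running statistics
#'   (see \code{\link{buildCnn}}).
#' @param mode "train" or "eval".
#' @param momentum blend weight of the new batch statistics.
#' @return List with \code{activations} and the updated \code{state}.
#' @export
batchNormForward <- function(x, state, mode = c("train", "eval"),
                             momentum = 0.99) {
  mode <- match.arg(mode)
  res <- bnGroupForward(as.matrix(x), state, mode, momentum)
  list(activations = res$y, state = res$state)
}

# Gesture labels of a WindowSet, checked against the model's class count.
checkedLabels <- function(model, ws) {
  y <- gestureLabels(ws)
  if (any(y < 0 | y >= model$net$nClasses))
    stop("gesture labels out of range [0, ", model$net$nClasses, ")")
  y
}

evalGestureLoss <- function(model, X, labels, bnKeys, C, T, chunk = 512L) {
  n <- length(labels)
  total <- 0
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    sl <- list(X = X[, windowColumns(idx, C, T), drop = FALSE],
               n = length(idx), C = C, T = T)
    fwd <- netForward(model, sl, "eval",
                      bnKeys = if (length(bnKeys) == 1L) bnKeys
                               else bnKeys[idx])
    total <- total +
      softmaxCrossEntropy(fwd$gScores, labels[idx])$loss * length(idx)
  }
  total / n
}

#' Train the plain CNN
#'
#' Mini-batches of \code{batchSize} windows (final partial batch kept)
#' shuffled per epoch by a seeded generator; after every epoch the
#' monitored loss (validation gesture loss if \code{val} is provided,
#' else the mean training loss) drives the plateau learning-rate
#' schedule; training stops when the learning rate drops below the
#' floor (or \code{maxEpochs} is reached).
#'
#' @param model an \code{"EmgCnn"} from \code{\link{buildCnn}}.
#' @param train a \linkS4class{WindowSet} of training windows.
#' @param val optional \linkS4class{WindowSet} of validation windows.
#' @param config a \code{\link{trainingConfig}}.
#' @return The trained model; \code{model$history} holds per-epoch
#'   training loss, monitored loss and learning rate.
#' @export
trainCnn <- function(model, train, val = NULL, config = trainingConfig()) {
  stopifnot(inherits(model, "EmgCnn"), is(train, "WindowSet"))
  y <- checkedLabels(model, train)
  sl <- windowsToSlices(train)
  X <- sl$X; C <- sl$C; T <- sl$T; n <- sl$n
  if (!n) stop("empty training set")
  valY <- if (!is.null(val)) checkedLabels(model, val)
  valX <- if (!is.null(val)) windowsToSlices(val)$X
  withSeed(config$seed, {
    params <- flattenParams(model)
    opt <- adamInit(params)
    sched <- plateauScheduler(config$learningRate, config$lrPatience,
                              config$lrFactor, config$lrFloor)
    history <- list()
    epoch <- 0L
    while (!sched$finished() && epoch < config$maxEpochs) {
      epoch <- epoch + 1L
      lr <- sched$lr()
      perm <- sample.int(n)
      losses <- c()
      for (s in seq(1L, n, by = config$batchSize)) {
        widx <- perm[s:min(n, s + config$batchSize - 1L)]
        slb <- list(X = X[, windowColumns(widx, C, T), drop = FALSE],
                    n = length(widx), C = C, T = T)
        fwd <- netForward(model, slb, "train", bnKeys = "shared",
                          keepCache = TRUE)
        model$bn <- fwd$bn
        ce <- softmaxCrossEntropy(fwd$gScores, y[widx])
        if (!is.finite(ce$loss))
          stop("non-finite training loss at epoch ", epoch)
        losses <- c(losses, ce$loss)
        grads <- netBackward(model, fwd, ce$dScores)
        upd <- adamStep(params, flattenGrads(grads, model$net$nBlocks),
                        opt, lr, config$beta1, config$beta2,
                        config$adamEps)
        params <- upd$params
        opt <- upd$state
        model <- unflattenParams(model, params)
      }
      trainLoss <- mean(losses)
      monitored <- if (is.null(val)) trainLoss else
        evalGestureLoss(model, valX, valY, "shared", C, T)
      newLr <- sched$observe(monitored)
      history[[epoch]] <- data.frame(epoch = epoch, trainLoss = trainLoss,
                                     monitoredLoss = monitored, lr = lr,
                                     nextLr = newLr)
    }
    model$history <- do.call(rbind, history)
    model$trained <- TRUE
    model
  })
}

#' Train the ADANN model
#'
#' Each epoch one training subject becomes the "selected" subject,
#' drawn from a seeded shuffled rotation (so subjects are equally
#' represented over training); every mini-batch is composed half of the
#' selected subject's
#' windows (domain label 1) and half of the other subjects' (domain
#' label 0). Forward passes route each window through its own subject's
#' batch-normalization statistics. The total loss couples the gesture
#' cross-entropy with the domain cross-entropy, whose gradient reaches
#' the convolutional blocks multiplied by \code{-adversarialLambda}
#' (gradient reversal) while the domain head itself trains normally.
#' The learning-rate schedule and stopping rule match
#' \code{\link{trainCnn}}, with the validation gesture loss monitored.
#'
#' @param model an \code{"EmgCnn"} from \code{\link{buildCnn}}.
#' @param train multi-subject training \linkS4class{WindowSet}
#'   (>= 2 subjects).
#' @param val optional multi-subject validation \linkS4class{WindowSet}.
#' @param config a \code{\link{trainingConfig}}.
#' @param domainHead set \code{FALSE} to disable the domain loss
#'   entirely (diagnostic; batch composition and RNG stream unchanged).
#' @return An object of class \code{"AdannModel"} with one
#'   batch-normalization registry entry per training subject plus a
#'   "shared" entry holding their average.
#' @export
trainAdann <- function(model, train, val = NULL,
                       config = trainingConfig(), domainHead = TRUE) {
  stopifnot(inherits(model, "EmgCnn"), is(train, "WindowSet"))
  y <- checkedLabels(model, train)
  subj <- subjectIds(train)
  subjects <- unique(subj)
  if (length(subjects) < 2) stop("ADANN needs >= 2 training subjects")
  pools <- split(seq_along(subj), factor(subj, levels = subjects))
  if (any(vapply(pools, length, integer(1)) == 0))
    stop("a subject has no training windows")
  sl <- windowsToSlices(train)
  X <- sl$X; C <- sl$C; T <- sl$T; n <- sl$n
  valY <- if (!is.null(val)) checkedLabels(model, val)
  valX <- if (!is.null(val)) windowsToSlices(val)$X
  valSubj <- if (!is.null(val)) subjectIds(val)
  # one BN registry entry per training subject
  for (s in subjects)
    model$bn[[s]] <- replicate(model$net$nBlocks,
                               newBnState(model$net$kernels),
                               simplify = FALSE)
  half <- config$batchSize %/% 2L
  nBatches <- max(1L, n %/% config$batchSize)
  withSeed(config$seed, {
    params <- flattenParams(model)
    opt <- adamInit(params)
    sched <- plateauScheduler(config$learningRate, config$lrPatience,
                              config$lrFactor, config$lrFloor)
    history <- list()
    selectedLog <- character(0)
    rotation <- character(0)
    epoch <- 0L
    while (!sched$finished() && epoch < config$maxEpochs) {
      epoch <- epoch + 1L
      lr <- sched$lr()
      # seeded shuffled rotation: every subject is the selected subject
      # once per cycle, giving the approximately equal representation
      # the balanced-batch scheme is meant to ensure
      if (!length(rotation)) rotation <- sample(subjects)
      selected <- rotation[1L]
      rotation <- rotation[-1L]
      selectedLog <- c(selectedLog, selected)
      selPool <- sample(pools[[selected]])
      othPool <- sample(unlist(pools[setdiff(subjects, selected)],
                               use.names = FALSE))
      selAt <- 0L; othAt <- 0L
      takeFrom <- function(pool, at, k) {
        out <- integer(0)
        while (k > 0L) {
          if (at >= length(pool)) at <- 0L
          take <- min(k, length(pool) - at)
          out <- c(out, pool[(at + 1L):(at + take)])
          at <- at + take
          k <- k - take
        }
        list(idx = out, at = at)
      }
      losses <- c()
      for (b in seq_len(nBatches)) {
        sTake <- takeFrom(selPool, selAt, half)
        selAt <- sTake$at
        oTake <- takeFrom(othPool, othAt, config$batchSize - half)
        othAt <- oTake$at
        widx <- c(sTake$idx, oTake$idx)
        dLabels <- c(rep(1L, length(sTake$idx)),
                     rep(0L, length(oTake$idx)))
        slb <- list(X = X[, windowColumns(widx, C, T), drop = FALSE],
                    n = length(widx), C = C, T = T)
        fwd <- netForward(model, slb, "train", bnKeys = subj[widx],
                          keepCache = TRUE)
        model$bn <- fwd$bn
        ceG <- softmaxCrossEntropy(fwd$gScores, y[widx])
        if (!is.finite(ceG$loss))
          stop("non-finite training loss at epoch ", epoch)
        losses <- c(losses, ceG$loss)
        if (domainHead) {
          ceD <- softmaxCrossEntropy(fwd$dScores, dLabels)
          grads <- netBackward(model, fwd, ceG$dScores, ceD$dScores,
                               config$adversarialLambda)
        } else {
          grads <- netBackward(model, fwd, ceG$dScores)
        }
        upd <- adamStep(params, flattenGrads(grads, model$net$nBlocks),
                        opt, lr, config$beta1, config$beta2,
                        config$adamEps)
        params <- upd$params
        opt <- upd$state
        model <- unflattenParams(model, params)
      }
      trainLoss <- mean(losses)
      monitored <- if (is.null(val)) trainLoss else
        evalGestureLoss(model, valX, valY, valSubj, C, T)
      newLr <- sched$observe(monitored)
      history[[epoch]] <- data.frame(epoch = epoch, trainLoss = trainLoss,
                                     monitoredLoss = monitored, lr = lr,
                                     nextLr = newLr, selected = selected)
    }
    model$bn$shared <- averageBnStates(model$bn[subjects])
    model$trainSubjects <- subjects
    model$history <- do.call(rbind, history)
    model$selectedLog <- selectedLog
    model$trained <- TRUE
    class(model) <- c("AdannModel", "EmgCnn")
    model
  })
}

# Average running statistics across subjects' registries.
averageBnStates <- function(registries) {
  nBlocks <- length(registries[[1]])
  lapply(seq_len(nBlocks), function(i) {
    list(mean = Reduce(`+`, lapply(registries, function(r) r[[i]]$mean)) /
           length(registries),
         var = Reduce(`+`, lapply(registries, function(r) r[[i]]$var)) /
           length(registries))
  })
}

#' Adapt a trained model to a new subject from one repetition per gesture
#'
#' Creates a fresh batch-normalization registry entry for the new
#' subject, initialized to the average of the training subjects'
#' running statistics, and updates it by forward passes over the
#' adaptation windows in train mode with dropout inactive. All
#' convolutional, linear, gesture-head and domain-head weights are
#' bit-identical before and after (only running statistics change).
#'
#' @param model a trained \code{"AdannModel"} (or \code{"EmgCnn"}).
#' @param adaptation \linkS4class{WindowSet} covering every gesture
#'   exactly once (one repetition each).
#' @param passes number of full sweeps (default 1).
#' @param subjectId registry key for the new subject (defaults to the
#'   adaptation windows' subject).
#' @return The adapted model.
#' @export
adaptToSubject <- function(model, adaptation, passes = 1L,
                           subjectId = NULL) {
  stopifnot(inherits(model, "EmgCnn"), is(adaptation, "WindowSet"))
  y <- checkedLabels(model, adaptation)
  present <- sort(unique(y))
  missing <- setdiff(seq_len(model$net$nClasses) - 1L, present)
  if (length(missing))
    stop("adaptation set missing gesture(s): ",
         paste(missing, collapse = ", "))
  perGesture <- tapply(repetitionIds(adaptation), y,
                       function(r) length(unique(r)))
  if (any(perGesture != 1L))
    stop("adaptation set must contain exactly one repetition per gesture")
  if (is.null(subjectId)) subjectId <- unique(subjectIds(adaptation))
  stopifnot(length(subjectId) == 1L)
  base <- if (length(model$trainSubjects))
    averageBnStates(model$bn[model$trainSubjects])
  else model$bn$shared
  model$bn[[subjectId]] <- base
  if (passes > 0) {
    sl <- windowsToSlices(adaptation)
    for (p in seq_len(passes)) {
      fwd <- netForward(model, sl, "train", bnKeys = subjectId,
                        dropout = FALSE, updateBn = TRUE,
                        keepCache = FALSE)
      model$bn <- fwd$bn
    }
  }
  model
}

#' Predict gesture labels for a WindowSet
#'
#' Eval-mode forward pass using the named subject's running
#' batch-normalization statistics ("shared" for the plain CNN or the
#' average entry of an ADANN); the highest class score wins, with ties
#' broken to the lowest class id.
#'
#' @param model a trained \code{"EmgCnn"} / \code{"AdannModel"}.
#' @param windowset a \linkS4class{WindowSet}.
#' @param subjectBn batch-normalization registry key (default
#'   "shared").
#' @param chunk windows per forward chunk (memory control).
#' @return Integer vector of zero-based predicted labels.
#' @export
predictWindows <- function(model, windowset, subjectBn = "shared",
                           chunk = 512L) {
  stopifnot(inherits(model, "EmgCnn"), is(windowset, "WindowSet"))
  if (is.null(model$bn[[subjectBn]]))
    stop("unknown batch-normalization registry entry: ", subjectBn)
  sl <- windowsToSlices(windowset)
  n <- sl$n
  out <- integer(n)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    slb <- list(X = sl$X[, windowColumns(idx, sl$C, sl$T), drop = FALSE],
                n = length(idx), C = sl$C, T = sl$T)
    fwd <- netForward(model, slb, "eval", bnKeys = subjectBn)
    out[idx] <- apply(fwd$gScores, 2, which.max) - 1L
  }
  out
}

#' Class probabilities for a WindowSet
#'
#' @inheritParams predictWindows
#' @return n x nClasses matrix of softmax probabilities.
#' @export
predictProbabilities <- function(model, windowset, subjectBn = "shared") {
  sl <- windowsToSlices(windowset)
  fwd <- netForward(model, sl, "eval", bnKeys = subjectBn)
  t(softmaxColumns(fwd$gScores))
}
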