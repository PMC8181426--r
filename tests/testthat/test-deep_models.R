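# Tiny multi-subject two-class window sets for fast network tests.
tinyAdannWindows <- function(nPerSubj = 20, subjects = c("A", "B", "C"),
                             T = 25, scale = NULL, seed = 17) {
  set.seed(seed)
  n <- nPerSubj * length(subjects)
  w <- array(0, c(n, 1, T))
  labels <- integer(n); subj <- character(n); reps <- integer(n)
  i <- 0
  for (s in seq_along(subjects)) {
    sc <- if (is.null(scale)) 1 else scale[s]
    for (j in seq_len(nPerSubj)) {
      i <- i + 1
      labels[i] <- j %% 2L
      subj[i] <- subjects[s]
      reps[i] <- (j - 1L) %/% max(1L, nPerSubj %/% 4L)
      w[i, 1, ] <- rnorm(T, mean = 2 * labels[i], sd = 0.4) * sc
    }
  }
  WindowSet(w, labels, subj, reps, 1000)
}

tinyNet2 <- function(...) networkConfig(nBlocks = 1, kernels = 2,
                                        kernelLength = 21, nChannels = 1,
                                        samplesPerFrame = 25, nClasses = 2,
                                        dropoutP = 0, ...)

test_that("the full-scale architecture has the stated shape", {
  m <- buildCnn(networkConfig(), seed = 2)
  expect_equal(bnParametersPerBlock(m), 128)       # 2 x 64 per block
  expect_length(m$blocks, 6)
  expect_identical(dim(m$blocks[[1]]$W), c(64L, 21L))
  expect_identical(dim(m$blocks[[3]]$W), c(64L, 64L * 21L))
  expect_identical(dim(m$linW), c(7L, 640L))       # 64 features x 10 channels
  expect_identical(dim(m$domW), c(2L, 640L))       # two-neuron domain head
  frame <- array(rnorm(10 * 151), c(1, 10, 151))
  ws <- WindowSet(frame, 0L, "x", 0L, 1000)
  p <- predictProbabilities(m, ws, "shared")
  expect_identical(dim(p), c(1L, 7L))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  m2 <- buildCnn(networkConfig(), seed = 2)
  expect_identical(m$blocks, m2$blocks)
  expect_identical(m$linW, m2$linW)
})

test_that("batch normalization matches its stated transform", {
  # fixed point: standardized batch, running stats (0, 1)
  set.seed(4)
  x <- matrix(rnorm(3 * 4000), 3)
  x <- (x - rowMeans(x)) / sqrt(rowMeans(x^2) - rowMeans(x)^2)
  st <- list(mean = rep(0, 3), var = rep(1, 3))
  out <- batchNormForward(x, st, "train")
  expect_equal(out$activations, x, tolerance = 1e-4)
  # constant batch normalizes to zero (epsilon-guarded variance)
  cst <- batchNormForward(matrix(7, 2, 10), list(mean = c(0, 0),
                                                 var = c(1, 1)), "train")
  expect_true(all(cst$activations == 0))
  # momentum blend: the momentum weights the new batch statistics
  blend <- batchNormForward(matrix(5, 1, 100),
                            list(mean = 0, var = 1), "train",
                            momentum = 0.99)
  expect_equal(blend$state$mean, 0.99 * 5 + 0.01 * 0)
  # eval mode uses running statistics
  ev <- batchNormForward(matrix(c(2, 4), 1), list(mean = 3, var = 1),
                         "eval")
  expect_equal(as.numeric(ev$activations),
               c(-1, 1) / sqrt(1 + emgadapt:::BN_EPS))
  expect_error(batchNormForward(matrix(0, 2, 0), st, "train"),
               "zero-size")
})

test_that("the plateau schedule decrements by 5 every 15 flat epochs and
          halts below 1e-8", {
  s <- plateauScheduler(0.04047, 15, 5, 1e-8)
  lrs <- c()
  epoch <- 0
  while (!s$finished()) {
    epoch <- epoch + 1
    lrs <- c(lrs, s$observe(1))    # frozen monitored loss
    if (epoch > 500) break
  }
  decrEpochs <- which(diff(c(0.04047, lrs)) != 0)
  expect_equal(decrEpochs, seq(16, by = 15, length.out = length(decrEpochs)))
  expect_equal(length(decrEpochs), 10)             # 0.04047 / 5^10 < 1e-8
  expect_equal(lrs[16], 0.04047 / 5)
  expect_equal(lrs[31], 0.04047 / 25)
  expect_lt(tail(lrs, 1), 1e-8)
  expect_equal(tail(lrs, 1), 0.04047 / 5^10)
  # a new minimum resets the patience counter
  s2 <- plateauScheduler(1, 3, 2, 1e-3)
  expect_equal(s2$observe(0.5), 1)
  expect_equal(s2$observe(0.6), 1)
  expect_equal(s2$observe(0.4), 1)   # new minimum
  expect_equal(s2$observe(0.5), 1)
  expect_equal(s2$observe(0.5), 1)
  expect_equal(s2$observe(0.5), 0.5) # 3 flat epochs
})

test_that("training learns separable data deterministically", {
  ws <- separableWindows(n = 64, nChannels = 1, T = 25)
  net <- tinyNet2()
  tc <- trainingConfig(batchSize = 16, maxEpochs = 6, seed = 11)
  m <- trainCnn(buildCnn(net, 11), ws, NULL, tc)
  expect_lt(m$history$trainLoss[5], m$history$trainLoss[1])
  acc <- accuracy(predictWindows(m, ws, "shared"), gestureLabels(ws))
  expect_gte(acc, 0.95)
  m2 <- trainCnn(buildCnn(net, 11), ws, NULL, tc)
  expect_identical(m$blocks, m2$blocks)
  expect_identical(m$linW, m2$linW)
  expect_error(trainCnn(buildCnn(net, 1),
                        WindowSet(array(0, c(2, 1, 25)), c(0L, 5L),
                                  c("a", "a"), c(0L, 0L), 1000),
                        NULL, tc),
               "out of range")
})

test_that("gradient reversal scales the convolutional domain gradient
          by -lambda (finite differences)", {
  set.seed(21)
  lambda <- 0.1
  net <- tinyNet2()
  model <- buildCnn(net, 3)
  model$bn$A <- model$bn$B <- model$bn$shared   # per-subject BN states
  ws <- tinyAdannWindows(nPerSubj = 4, subjects = c("A", "B"), T = 25)
  sl <- emgadapt:::windowsToSlices(ws)
  dLabels <- as.integer(subjectIds(ws) == "A")
  domainLoss <- function(m) {
    fwd <- emgadapt:::netForward(m, sl, "train", bnKeys = subjectIds(ws),
                                 dropout = FALSE, updateBn = FALSE)
    emgadapt:::softmaxCrossEntropy(fwd$dScores, dLabels)$loss
  }
  fwd <- emgadapt:::netForward(model, sl, "train",
                               bnKeys = subjectIds(ws), dropout = FALSE,
                               updateBn = FALSE, keepCache = TRUE)
  ceD <- emgadapt:::softmaxCrossEntropy(fwd$dScores, dLabels)
  zeroG <- matrix(0, 2, ncol(fwd$gScores))
  grads <- emgadapt:::netBackward(model, fwd, zeroG, ceD$dScores, lambda)
  eps <- 1e-5
  for (idx in sample(length(model$blocks[[1]]$W), 6)) {
    up <- model; up$blocks[[1]]$W[idx] <- up$blocks[[1]]$W[idx] + eps
    dn <- model; dn$blocks[[1]]$W[idx] <- dn$blocks[[1]]$W[idx] - eps
    fd <- (domainLoss(up) - domainLoss(dn)) / (2 * eps)
    expect_equal(grads$blocks[[1]][idx], -lambda * fd,
                 tolerance = 1e-4)
  }
  # the domain head itself trains unreversed
  fdW <- local({
    up <- model; up$domW[1, 1] <- up$domW[1, 1] + eps
    dn <- model; dn$domW[1, 1] <- dn$domW[1, 1] - eps
    (domainLoss(up) - domainLoss(dn)) / (2 * eps)
  })
  expect_equal(grads$domW[1, 1], fdW, tolerance = 1e-4)
})

test_that("a null adversary (lambda = 0) leaves the trunk identical to a
          gesture-only run", {
  ws <- tinyAdannWindows(nPerSubj = 16, seed = 5)
  net <- tinyNet2()
  tc0 <- trainingConfig(batchSize = 12, maxEpochs = 2, seed = 7,
                        adversarialLambda = 0)
  mA <- trainAdann(buildCnn(net, 7), ws, NULL, tc0)
  mB <- trainAdann(buildCnn(net, 7), ws, NULL, tc0, domainHead = FALSE)
  expect_identical(mA$blocks, mB$blocks)
  expect_identical(mA$linW, mB$linW)
})

test_that("every subject is eventually drawn as the selected subject", {
  ws <- tinyAdannWindows(nPerSubj = 6,
                         subjects = c("A", "B", "C", "D", "E", "F"),
                         seed = 6)
  tc <- trainingConfig(batchSize = 12, maxEpochs = 60, seed = 1)
  m <- trainAdann(buildCnn(tinyNet2(), 1), ws, NULL, tc)
  expect_setequal(unique(m$selectedLog), c("A", "B", "C", "D", "E", "F"))
})

test_that("adaptation changes only batch-normalization statistics", {
  ws <- tinyAdannWindows(nPerSubj = 16, seed = 8)
  tc <- trainingConfig(batchSize = 12, maxEpochs = 2, seed = 3)
  m <- trainAdann(buildCnn(tinyNet2(), 3), ws, NULL, tc)
  # one repetition of each gesture from a new subject
  set.seed(9)
  adW <- array(rnorm(2 * 1 * 25), c(2, 1, 25))
  adW[2, 1, ] <- adW[2, 1, ] + 2
  adapt <- WindowSet(adW, c(0L, 1L), c("new", "new"), c(0L, 0L), 1000)
  m2 <- adaptToSubject(m, adapt)
  expect_identical(m2$blocks, m$blocks)
  expect_identical(m2$linW, m$linW)
  expect_identical(m2$linb, m$linb)
  expect_identical(m2$domW, m$domW)
  expect_false(identical(m2$bn$new, m$bn$shared))
  # zero-pass adaptation equals shared-statistics inference
  m0 <- adaptToSubject(m, adapt, passes = 0)
  te <- tinyAdannWindows(nPerSubj = 10, subjects = "Z", seed = 10)
  expect_identical(predictWindows(m0, te, "new"),
                   predictWindows(m, te, "shared"))
  # adaptation set must cover every gesture exactly once
  onlyClass0 <- WindowSet(adW[1, , , drop = FALSE], 0L, "new", 0L, 1000)
  expect_error(adaptToSubject(m, onlyClass0), "missing gesture")
})

test_that("adapted statistics match the matched subject's distribution", {
  scale <- c(1, 5, 1)
  ws <- tinyAdannWindows(nPerSubj = 24, subjects = c("A", "B", "C"),
                         scale = scale, seed = 12)
  tc <- trainingConfig(batchSize = 24, maxEpochs = 4, seed = 5)
  m <- trainAdann(buildCnn(tinyNet2(), 5), ws, NULL, tc)
  # adaptation data drawn from A's distribution (scale 1)
  set.seed(13)
  adW <- array(rnorm(2 * 25, mean = rep(c(0, 2), each = 25) * 0),
               c(2, 1, 25))
  adW[1, 1, ] <- rnorm(25, 0, 0.4)
  adW[2, 1, ] <- rnorm(25, 2, 0.4)
  adapt <- WindowSet(adW, c(0L, 1L), c("new", "new"), c(0L, 0L), 1000)
  m2 <- adaptToSubject(m, adapt)
  dTo <- function(s) sum(abs(log(m2$bn$new[[1]]$var /
                                   m2$bn[[s]][[1]]$var)))
  expect_lt(dTo("A"), dTo("B"))
})

test_that("prediction is deterministic and batching-invariant", {
  ws <- tinyAdannWindows(nPerSubj = 12, seed = 14)
  tc <- trainingConfig(batchSize = 12, maxEpochs = 2, seed = 2)
  m <- trainCnn(buildCnn(tinyNet2(), 2), ws, NULL, tc)
  all1 <- predictWindows(m, ws, "shared")
  all2 <- predictWindows(m, ws, "shared", chunk = 5L)
  single <- vapply(seq_len(nWindows(ws)), function(i)
    predictWindows(m, emgadapt:::subsetWindows(ws, i), "shared"),
    integer(1))
  expect_identical(all1, all2)
  expect_identical(all1, single)
  zero <- WindowSet(array(0, c(1, 1, 25)), 0L, "z", 0L, 1000)
  expect_identical(predictWindows(m, zero, "shared"),
                   predictWindows(m, zero, "shared"))
  p <- predictProbabilities(m, ws, "shared")
  expect_equal(rowSums(p), rep(1, nWindows(ws)), tolerance = 1e-6)
  expect_error(predictWindows(m, ws, "nobody"), "unknown")
})
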