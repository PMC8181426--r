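randomFeatureMatrix <- function(n = 700, d = 12, nClasses = 7, seed = 1,
                                subject = "a") {
  set.seed(seed)
  FeatureMatrix(matrix(rnorm(n * d), n, d), "TD",
                rep(seq_len(nClasses) - 1L, length.out = n),
                rep(subject, n), rep(0L, n))
}

test_that("standardization gives zero mean, unit population variance", {
  fm <- FeatureMatrix(matrix(c(1, 3, 5, 7), 2, 2), "TD", c(0L, 1L),
                      c("a", "a"), c(0L, 0L))
  s <- standardizeFeatures(fm)
  expect_equal(featureValues(s$features)[, 1], c(-1, 1))  # population sd
  expect_equal(s$center, c(2, 6))
  expect_equal(s$scale, c(1, 1))
  # idempotence
  s2 <- standardizeFeatures(s$features)
  expect_equal(featureValues(s2$features), featureValues(s$features),
               tolerance = 1e-12)
  # constant column maps to zero with a message
  fm3 <- FeatureMatrix(cbind(c(1, 2, 3), 5), "TD", c(0L, 1L, 0L),
                       rep("a", 3), rep(0L, 3))
  expect_message(s3 <- standardizeFeatures(fm3), "zero-variance")
  expect_equal(featureValues(s3$features)[, 2], c(0, 0, 0))
})

test_that("class pairing truncates to per-class minima in order", {
  e <- randomFeatureMatrix(70, 4, 7, seed = 2)
  t1 <- randomFeatureMatrix(70, 4, 7, seed = 3)
  p <- pairByClass(e, t1)
  expect_equal(nrow(p@expertSamples), 70)
  expect_identical(p@labels, rep(0:6, each = 10))
  # unbalanced counts: class truncated to the minimum
  t2 <- randomFeatureMatrix(35, 4, 7, seed = 4)
  p2 <- pairByClass(e, t2)
  expect_equal(nrow(p2@expertSamples), 35)
  # identical inputs pair rowwise
  p3 <- pairByClass(e, e)
  expect_identical(p3@expertSamples, p3@targetSamples)
  # missing class is named
  tMiss <- randomFeatureMatrix(60, 4, 6, seed = 5)
  expect_error(pairByClass(e, tMiss), "6")
})

test_that("identity is recovered when target equals expert", {
  fm <- randomFeatureMatrix(700, 12, seed = 6)
  s <- standardizeFeatures(fm)
  proj <- fitProjection(pairByClass(s$features, s$features), 1e-8)
  expect_lt(max(abs(proj@W - diag(12))), 1e-3)
})

test_that("a linear domain shift is recovered (per-column r >= 0.95)", {
  fm <- randomFeatureMatrix(700, 12, seed = 7)
  set.seed(8)
  A <- matrix(rnorm(144), 12)
  while (abs(det(A)) < 0.5) A <- matrix(rnorm(144), 12)
  shifted <- FeatureMatrix(featureValues(fm) %*% t(A), "TD",
                           gestureLabels(fm), rep("b", 700), rep(0L, 700))
  sE <- standardizeFeatures(fm)
  sT <- standardizeFeatures(shifted)
  proj <- fitProjection(pairByClass(sE$features, sT$features), 0.04)
  projected <- featureValues(projectFeatures(proj, sT$features))
  cors <- vapply(1:12, function(j)
    cor(projected[, j], featureValues(sE$features)[, j]), numeric(1))
  expect_true(all(cors >= 0.95))
})

test_that("lambda defaults to 0.04 and the residual is ridge-monotone", {
  fm <- randomFeatureMatrix(200, 6, seed = 9)
  s <- standardizeFeatures(fm)
  set.seed(10)
  noisy <- FeatureMatrix(featureValues(s$features) +
                           matrix(rnorm(1200, 0, 0.5), 200, 6),
                         "TD", gestureLabels(fm), rep("b", 200),
                         rep(0L, 200))
  sT <- standardizeFeatures(noisy)
  p <- pairByClass(s$features, sT$features)
  proj <- fitProjection(p)
  expect_equal(proj@lambda, 0.04)
  obj <- function(lambda) {
    W <- fitProjection(p, lambda)@W
    sum((p@targetSamples %*% W - p@expertSamples)^2)
  }
  # the least-squares residual is non-increasing as lambda -> 0
  expect_gte(obj(0.5), obj(0.04))
  expect_gte(obj(0.04), obj(1e-6))
})

test_that("projection shapes, identity and null maps behave", {
  fm <- randomFeatureMatrix(70, 4, 7, seed = 11)
  s <- standardizeFeatures(fm)
  proj <- fitProjection(pairByClass(s$features, s$features), 1e-6)
  projI <- proj
  projI@W <- diag(4)
  expect_equal(featureValues(projectFeatures(projI, s$features)),
               featureValues(s$features))
  projI@W <- matrix(0, 4, 4)
  expect_true(all(featureValues(projectFeatures(projI, s$features)) == 0))
  expect_error(projectFeatures(proj, matrix(0, 3, 7)), "dimension")
  expect_error(fitProjection(pairByClass(
    randomFeatureMatrix(14, 20, 7, seed = 1),
    randomFeatureMatrix(14, 20, 7, seed = 2)), 0.04),
    "adaptation data")
})

test_that("projection shrinks class-centroid distance under a linear
          shift", {
  set.seed(14)
  centers <- matrix(rnorm(7 * 6, 0, 3), 7, 6)
  x <- centers[rep(1:7, each = 40), ] + matrix(rnorm(280 * 6), 280, 6)
  fm <- FeatureMatrix(x, "TD", rep(0:6, each = 40), rep("a", 280),
                      rep(0L, 280))
  A <- diag(6) + matrix(rnorm(36, 0, 0.4), 6)
  shifted <- FeatureMatrix(x %*% t(A), "TD", rep(0:6, each = 40),
                           rep("b", 280), rep(0L, 280))
  sE <- standardizeFeatures(fm)
  sT <- standardizeFeatures(shifted)
  proj <- fitProjection(pairByClass(sE$features, sT$features), 0.04)
  cdist <- function(a, b) {
    mean(vapply(0:6, function(cl) {
      sqrt(sum((colMeans(a[gestureLabels(fm) == cl, , drop = FALSE]) -
                  colMeans(b[gestureLabels(fm) == cl, , drop = FALSE]))^2))
    }, numeric(1)))
  }
  before <- cdist(featureValues(sT$features), featureValues(sE$features))
  after <- cdist(featureValues(projectFeatures(proj, sT$features)),
                 featureValues(sE$features))
  expect_lte(after, before)
})

test_that("with no inter-subject variability the CCA pipeline matches
          within-subject accuracy", {
  cfg <- simConfig(nSubjects = 3, nRepetitions = 16, durationS = 0.6,
                   nChannels = 4, nSources = 4, seed = 23,
                   mixingSd = 0, gainSd = 0, cornerJitter = 0,
                   activationSd = 0)
  ds <- generateDataset(cfg)
  fs <- featureSpec("TD")
  res <- runCcaPipeline(ds, "S3", "all", fs, filter = NULL,
                        window = TINY_WSPEC)
  trF <- extractFeatures(windowsForSubset(ds, "S3", 0:7, filter = NULL,
                                          window = TINY_WSPEC), fs)
  teF <- extractFeatures(windowsForSubset(ds, "S3", 9:15, filter = NULL,
                                          window = TINY_WSPEC), fs)
  within <- accuracy(predictLda(fitLda(trF), teF), gestureLabels(teF))
  expect_lt(abs(accuracies(res)[["S3"]] - within), 0.05)
})

test_that("scrambling adaptation labels degrades the CCA pipeline", {
  ds <- TINY_DS
  fs <- featureSpec("TD")
  good <- accuracies(runCcaPipeline(ds, "S3", "S1", fs, filter = NULL,
                                    window = TINY_WSPEC))[["S3"]]
  # corrupt: permute the gesture identities of the adaptation windows by
  # relabeling recordings of the adaptation repetition
  recs <- recordings(ds)
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    if (r@subjectId == "S3" && r@repetitionId == 8L)
      r@gestureId <- (r@gestureId + 3L) %% 7L
    recs[[i]] <- r
  }
  scrambled <- EmgDataset(recs, classNames(ds))
  bad <- accuracies(runCcaPipeline(scrambled, "S3", "S1", fs,
                                   filter = NULL,
                                   window = TINY_WSPEC))[["S3"]]
  expect_lt(bad, good)
})
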