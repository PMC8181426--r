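test_that("subject models are deterministic and distinct across subjects", {
  cfg <- tinyConfig()
  m1 <- makeSubjectModel(cfg, 0, seed = 5)
  m2 <- makeSubjectModel(cfg, 0, seed = 5)
  expect_identical(m1@mixing, m2@mixing)
  expect_identical(m1@gestureActivations, m2@gestureActivations)
  m3 <- makeSubjectModel(cfg, 1, seed = 5)
  expect_gt(norm(m1@mixing - m3@mixing, "F"), 0)
  expect_error(makeSubjectModel(cfg, 99, seed = 5), "out of range")
})

test_that("identityMixing flag forces an identity mixing matrix", {
  cfg <- tinyConfig(identityMixing = TRUE)
  m <- makeSubjectModel(cfg, 0)
  expect_identical(m@mixing, diag(4))
  expect_error(simConfig(nChannels = 4, nSources = 3,
                         identityMixing = TRUE),
               "identityMixing")
})

test_that("zero activation row yields near-zero output", {
  cfg <- tinyConfig(noiseFloor = 0)
  m <- makeSubjectModel(cfg, 0)
  m@gestureActivations[3, ] <- 0
  # skip validity (distinct-rows invariant is deliberately broken here)
  rec <- simulateRepetition(m, 2L, cfg, seed = 8)
  expect_lt(sqrt(mean(rec@signal^2)), 1e-6 * m@gain)
})

test_that("identical seeds reproduce a repetition exactly", {
  cfg <- tinyConfig()
  m <- makeSubjectModel(cfg, 1)
  r1 <- simulateRepetition(m, 3L, cfg, seed = 77)
  r2 <- simulateRepetition(m, 3L, cfg, seed = 77)
  expect_identical(r1@signal, r2@signal)
  r3 <- simulateRepetition(m, 3L, cfg, seed = 78)
  expect_false(identical(r1@signal, r3@signal))
})

test_that("steady state RMS dominates early ramp RMS in >= 95% of reps", {
  cfg <- tinyConfig(rampFraction = 0.2)
  m <- makeSubjectModel(cfg, 0)
  n <- round(cfg@durationS * cfg@samplingRate)
  rampEnd <- round(0.2 * n)
  early <- 1:round(0.1 * rampEnd + 1)
  steady <- (rampEnd + 1):n
  ok <- vapply(1:20, function(i) {
    s <- simulateRepetition(m, 4L, cfg, seed = 1000 + i)@signal
    sqrt(mean(s[, steady]^2)) >= sqrt(mean(s[, early]^2))
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("generateDataset has the full factorial structure, reproducibly", {
  cfg <- tinyConfig(seed = 13)
  ds <- generateDataset(cfg)
  expect_length(recordings(ds), 3 * 7 * 16)
  expect_length(subjectIds(ds), 3)
  ds2 <- generateDataset(cfg)
  expect_identical(lapply(recordings(ds), slot, "signal"),
                   lapply(recordings(ds2), slot, "signal"))
})

test_that("linear subject transforms act on the named subject only", {
  ds <- TINY_DS
  C <- channelCount(ds)
  expect_identical(
    lapply(recordings(applyLinearSubjectTransform(ds, "S1", diag(C))),
           slot, "signal"),
    lapply(recordings(ds), slot, "signal"))
  doubled <- applyLinearSubjectTransform(ds, "S1", diag(2, C))
  for (i in seq_along(recordings(ds))) {
    r0 <- recordings(ds)[[i]]; r1 <- recordings(doubled)[[i]]
    f <- if (r0@subjectId == "S1") 2 else 1
    expect_equal(r1@signal, f * r0@signal)
  }
  P <- diag(C)[c(2:C, 1), ]
  perm <- applyLinearSubjectTransform(ds, "S2", P)
  i <- which(vapply(recordings(ds), slot, character(1),
                    "subjectId") == "S2")[1]
  expect_identical(recordings(perm)[[i]]@signal,
                   recordings(ds)[[i]]@signal[c(2:C, 1), ])
  expect_error(applyLinearSubjectTransform(ds, "S1", matrix(0, C, C)),
               "singular")
})

test_that("synthetic classes are learnable within subject and transfer
          imperfectly across subjects", {
  cfg <- simConfig(nSubjects = 2, nRepetitions = 16, durationS = 2,
                   seed = 19)
  ds <- generateDataset(cfg)
  fs <- featureSpec("TD")
  trF <- extractFeatures(windowsForSubset(ds, "S1", 0:7), fs)
  teF <- extractFeatures(windowsForSubset(ds, "S1", 8:15), fs)
  model <- fitLda(trF)
  within <- accuracy(predictLda(model, teF), gestureLabels(teF))
  expect_gte(within, 0.90)
  otherF <- extractFeatures(windowsForSubset(ds, "S2", 8:15), fs)
  cross <- accuracy(predictLda(model, otherF), gestureLabels(otherF))
  expect_lt(cross, within)
})
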