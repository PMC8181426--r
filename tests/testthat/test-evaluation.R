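test_that("framework repetition splits are disjoint and correctly sized", {
  w <- frameworkSplits("within_subject")
  expect_identical(w$train, 0:7)
  expect_identical(w$test, 8:15)
  expect_length(intersect(w$train, w$test), 0)
  s <- frameworkSplits("single_repetition")
  expect_identical(s$train, 0L)
  expect_identical(s$test, 8:15)
  expect_length(intersect(s$train, s$test), 0)
  x <- frameworkSplits("cross_subject")
  expect_identical(x$trainerTrain, 0:7)
  expect_identical(x$trainerVal, 8:15)
  expect_identical(x$targetUnused, 0:7)
  expect_identical(x$targetAdapt, 8L)
  expect_identical(x$targetTest, 9:15)
  expect_length(intersect(x$targetAdapt, x$targetTest), 0)
  expect_length(intersect(x$targetUnused,
                          c(x$targetAdapt, x$targetTest)), 0)
  expect_length(x$targetUnused, 8)
  expect_length(x$targetTest, 7)
})

test_that("within-subject evaluation covers each subject independently", {
  res <- runWithinSubject(TINY_DS, "TD", filter = NULL,
                          window = TINY_WSPEC)
  expect_s4_class(res, "EvaluationResult")
  expect_setequal(names(accuracies(res)), subjectIds(TINY_DS))
  cm <- confusionMatrices(res)[["S1"]]
  expect_equal(sum(diag(cm)) / sum(cm), accuracies(res)[["S1"]])
  # per-subject test window counts: 8 reps x 7 gestures x windows/rec
  expect_equal(sum(cm), 8 * 7 * (floor((600 - 151) / 100) + 1))
  res2 <- runWithinSubject(TINY_DS, "TD", filter = NULL,
                           window = TINY_WSPEC)
  expect_identical(accuracies(res), accuracies(res2))
  expect_identical(res@fingerprint, res2@fingerprint)
})

test_that("single-repetition evaluation refuses deep pipelines and
          trails the full protocol on average", {
  expect_error(runSingleRepetition(TINY_DS, "CNN"), "handcrafted")
  within <- runWithinSubject(TINY_DS, "TD", filter = NULL,
                             window = TINY_WSPEC)
  single <- runSingleRepetition(TINY_DS, "TD", filter = NULL,
                                window = TINY_WSPEC)
  expect_setequal(names(accuracies(single)), subjectIds(TINY_DS))
  expect_gte(mean(accuracies(within)), mean(accuracies(single)))
})

test_that("cross-subject CCA evaluation runs one fold per target", {
  res <- runCrossSubject(TINY_DS, "CCA_TD", filter = NULL,
                         window = TINY_WSPEC, targets = c("S1", "S3"))
  expect_identical(names(accuracies(res)), c("S1", "S3"))
  expect_true(all(accuracies(res) >= 0 & accuracies(res) <= 1))
  full <- runCrossSubject(TINY_DS, "CCA_TD", filter = NULL,
                          window = TINY_WSPEC)
  expect_length(accuracies(full), length(subjectIds(TINY_DS)))
})

test_that("cross-subject deep evaluation respects the split protocol", {
  net <- tinyNet()
  tc <- trainingConfig(batchSize = 64, maxEpochs = 1, seed = 4)
  res <- runCrossSubject(TINY_DS, "ADANN", filter = NULL,
                         window = TINY_WSPEC, net = net, training = tc,
                         targets = "S2")
  expect_identical(names(accuracies(res)), "S2")
  cm <- confusionMatrices(res)[["S2"]]
  expect_equal(sum(cm), 7 * 7 * (floor((600 - 151) / 100) + 1))
  expect_error(runCrossSubject(TINY_DS, "nonsense", targets = "S1"),
               "pipeline")
})

test_that("summaries aggregate with sample standard deviation", {
  mk <- function(pipeline, accs) {
    conf <- lapply(accs, function(a)
      diag(c(round(100 * a), 0)) + matrix(c(0, round(100 * (1 - a)),
                                            0, 0), 2))
    names(conf) <- names(accs)
    EvaluationResult("within_subject", pipeline, accs, conf, "fp")
  }
  r1 <- mk("TD", c(s1 = 0.8, s2 = 1.0))
  r2 <- mk("LSF9", c(s1 = 0.9, s2 = 0.7))
  s <- summarizeResults(list(r1, r2))
  expect_identical(nrow(s$table), 4L)
  expect_setequal(unique(s$table$pipeline), c("TD", "LSF9"))
  td <- s$summary[s$summary$pipeline == "TD", ]
  expect_equal(td$mean, 0.9)
  expect_equal(td$sd, 0.1414, tolerance = 1e-3)
  s2 <- summarizeResults(list(r2, r1))
  expect_identical(s$table, s2$table)   # deterministic ordering
  p <- tempfile(fileext = ".tsv")
  on.exit(unlink(p))
  writeResultsTsv(list(r1, r2), p)
  expect_identical(nrow(read.delim(p)), 4L)
})
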