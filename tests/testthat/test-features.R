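test_that("every feature set matches its loop-based oracle", {
  set.seed(101)
  for (set in c("TD", "TDAR", "TDPSD", "LSF4", "LSF9")) {
    spec <- featureSpec(set)
    fn <- switch(set, TD = featuresTD, TDAR = featuresTDAR,
                 TDPSD = featuresTDPSD, LSF4 = featuresLSF4,
                 LSF9 = featuresLSF9)
    for (rep in 1:40) {
      w <- matrix(rnorm(2 * 151), 2, 151)
      got <- fn(w, spec)
      want <- oracleWindow(w, set)
      expect_equal(got, want, tolerance = 1e-10, ignore_attr = TRUE)
    }
  }
})

test_that("hand-computed TD example holds", {
  w <- matrix(c(1, -1, 1, -1), 1)
  expect_equal(as.numeric(featuresTD(w)), c(1, 3, 2, 6))
})

test_that("per-channel dimensions are (set size) x channels", {
  w <- matrix(rnorm(10 * 151), 10, 151)
  expect_length(featuresTD(w), 40)
  expect_length(featuresTDAR(w), 80)
  expect_length(featuresTDPSD(w), 60)
  expect_length(featuresLSF4(w), 40)
  expect_length(featuresLSF9(w), 90)
})

test_that("AR coefficients follow the polynomial sign convention", {
  set.seed(7)
  x <- as.numeric(stats::arima.sim(list(ar = 0.9), 5000))
  v <- featuresTDAR(matrix(x, 1))
  expect_equal(v[5], -0.9, tolerance = 0.05)
  # cross-check: stats::ar.yw returns the negated (prediction) signs
  yw <- stats::ar.yw(x, aic = FALSE, order.max = 4, demean = FALSE)
  expect_equal(v[5:8], -as.numeric(yw$ar), tolerance = 1e-6)
  # white noise: near-zero coefficients
  set.seed(8)
  wn <- featuresTDAR(matrix(rnorm(151), 1))
  expect_true(all(abs(wn[5:8]) < 0.2))
  # constant window: AR part defined as zero, TD part still valid
  const <- featuresTDAR(matrix(1, 1, 151))
  expect_equal(const[5:8], rep(0, 4))
  expect_equal(const[1], 1)  # MAV
})

test_that("LSF hand examples hold", {
  spec0 <- featureSpec("LSF4")
  z <- featuresLSF4(matrix(0, 1, 4), spec0)
  expect_equal(as.numeric(z), c(-20, 0, 0, 0))  # log floor guard
  spec <- featureSpec("LSF4", wampThreshold = 0.5)
  v <- featuresLSF4(matrix(c(0, 1, 0, 1), 1), spec)
  expect_equal(v[4], 3)  # three unit steps above threshold
  ls <- featuresLSF4(matrix(1:4, 1))[2]
  expect_equal(as.numeric(ls), 5 / 6)
  const <- featuresLSF9(matrix(1, 1, 4))
  # MFL floor, LS, MSR, WAMP, ZC, RMS, IEMG, DASDV, VAR
  expect_equal(as.numeric(const),
               c(-20, 0, 1, 0, 0, 1, 4, 0, 4 / 3))
  zero9 <- featuresLSF9(matrix(0, 1, 6))
  expect_equal(as.numeric(zero9), c(-20, 0, 0, 0, 0, 0, 0, 0, 0))
})

test_that("TDPSD is symmetric across identical channels and rejects
          zero channels", {
  set.seed(12)
  ch <- rnorm(151)
  w <- rbind(ch, ch)
  v <- featuresTDPSD(w)
  expect_equal(v[1:6], v[7:12])
  wz <- rbind(ch, rep(0, 151))
  expect_error(featuresTDPSD(wz), "zero channel")
})

test_that("amplitude scaling acts as documented", {
  set.seed(31)
  w <- matrix(rnorm(3 * 151), 3, 151)
  td1 <- featuresTD(w); td2 <- featuresTD(2.5 * w)
  linear <- rep(c(TRUE, FALSE, FALSE, TRUE), 3)   # MAV, WL scale
  expect_equal(td2[linear], 2.5 * td1[linear])
  expect_equal(td2[!linear], td1[!linear])         # ZC, SSC invariant
  l1 <- featuresLSF9(w); l2 <- featuresLSF9(2.5 * w)
  pick <- function(v, k) v[seq(k, length(v), by = 9)]
  for (k in c(6, 7, 8)) # RMS, IEMG, DASDV linear
    expect_equal(pick(l2, k), 2.5 * pick(l1, k))
  for (k in c(4, 5))    # WAMP (threshold 0), ZC invariant
    expect_equal(pick(l2, k), pick(l1, k))
})

test_that("channel permutation permutes feature blocks", {
  set.seed(13)
  w <- matrix(rnorm(4 * 151), 4, 151)
  perm <- c(3, 1, 4, 2)
  a <- matrix(featuresLSF9(w), nrow = 9)
  b <- matrix(featuresLSF9(w[perm, ]), nrow = 9)
  expect_equal(b, a[, perm])
})

test_that("extractFeatures carries labels, names and dimensions", {
  ws <- windowsForSubset(TINY_DS, "S1", 0:1, filter = NULL,
                         window = TINY_WSPEC)
  fm <- extractFeatures(ws, featureSpec("TD"))
  expect_s4_class(fm, "FeatureMatrix")
  expect_identical(dim(featureValues(fm)),
                   c(nWindows(ws), 4L * channelCount(ws)))
  expect_identical(gestureLabels(fm), gestureLabels(ws))
  expect_identical(featureSetName(fm), "TD")
  fm2 <- extractFeatures(ws, featureSpec("TD"))
  expect_identical(featureValues(fm), featureValues(fm2))
})
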