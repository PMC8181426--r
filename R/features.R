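# The five handcrafted EMG feature sets: TD, TDAR, TDPSD, LSF4, LSF9.
# Each is computed per channel per window; window-level vectors are the
# per-channel blocks concatenated in channel order.

FEATURES_PER_CHANNEL <- c(TD = 4L, TDAR = 8L, TDPSD = 6L, LSF4 = 4L,
                          LSF9 = 9L)

#' Feature extraction specification
#'
#' Deadband thresholds default to 0 (assumption-free in normalized
#' synthetic units); \code{logFloor} replaces the logarithm of an
#' underflowing argument (zero windows occur in rest-like classes).
#'
#' @param setName one of "TD", "TDAR", "TDPSD", "LSF4", "LSF9".
#' @param zcThreshold,sscThreshold,wampThreshold nonnegative amplitude
#'   deadband thresholds.
#' @param arOrder autoregressive model order (default 4).
#' @param logFloor value substituted for log of zero (default -20).
#' @return An object of class \code{"FeatureSpec"}.
#' @export
featureSpec <- function(setName = "TD", zcThreshold = 0, sscThreshold = 0,
                        wampThreshold = 0, arOrder = 4, logFloor = -20) {
  setName <- match.arg(setName, names(FEATURES_PER_CHANNEL))
  stopifnot(zcThreshold >= 0, sscThreshold >= 0, wampThreshold >= 0,
            arOrder >= 1)
  structure(list(setName = setName, zcThreshold = zcThreshold,
                 sscThreshold = sscThreshold,
                 wampThreshold = wampThreshold,
                 arOrder = as.integer(arOrder), logFloor = logFloor),
            class = "FeatureSpec")
}

guardedLog <- function(x, floor = -20, base = exp(1)) {
  out <- log(abs(x), base = base)
  out[!is.finite(out)] <- floor
  out
}

zeroCrossings <- function(x, thr = 0) {
  n <- length(x)
  a <- x[-n]; b <- x[-1]
  sum(a * b < 0 & abs(a - b) >= thr)
}

slopeSignChanges <- function(x, thr = 0) {
  n <- length(x)
  if (n < 3) return(0L)
  d1 <- x[2:(n - 1)] - x[1:(n - 2)]
  d2 <- x[2:(n - 1)] - x[3:n]
  sum(d1 * d2 > 0 & pmax(abs(d1), abs(d2)) >= thr)
}

# Levinson-Durbin on the biased (1/N) autocorrelation, no demeaning.
# Returns coefficients of A(z) = 1 + a_1 z^-1 + ... + a_p z^-p, i.e. the
# negated prediction coefficients (an AR(1) with phi = 0.9 yields
# a_1 ~ -0.9). Constant windows yield all-zero coefficients.
arCoefficients <- function(x, p = 4) {
  n <- length(x)
  if (n <= p) stop("need more than arOrder samples")
  if (max(x) == min(x)) return(rep(0, p))
  r <- vapply(0:p, function(k)
    sum(x[1:(n - k)] * x[(1 + k):n]) / n, numeric(1))
  if (r[1] <= 0) return(rep(0, p))
  phi <- numeric(p)
  e <- r[1]
  for (m in seq_len(p)) {
    k <- (r[m + 1] - if (m > 1) sum(phi[1:(m - 1)] * r[m:2]) else 0) / e
    phiNew <- phi
    phiNew[m] <- k
    if (m > 1) phiNew[1:(m - 1)] <- phi[1:(m - 1)] - k * phi[(m - 1):1]
    phi <- phiNew
    e <- e * (1 - k^2)
    if (e <= 0) { phi[is.na(phi)] <- 0; break }
  }
  -phi
}

tdChannel <- function(x, spec) {
  n <- length(x)
  c(MAV = mean(abs(x)),
    ZC = zeroCrossings(x, spec$zcThreshold),
    SSC = slopeSignChanges(x, spec$sscThreshold),
    WL = sum(abs(diff(x))))
}

tdpsdChannel <- function(x, spec) {
  f6 <- function(y) {
    dy <- diff(y); ddy <- diff(dy)
    m0 <- sqrt(sum(y^2))^0.1 / 0.1
    m2 <- sqrt(sum(dy^2))^0.1 / 0.1
    m4 <- sqrt(sum(ddy^2))^0.1 / 0.1
    sparseness <- m0 / sqrt(abs((m0 - m2) * (m0 - m4)))
    irregularity <- m2 / sqrt(m0 * m4)
    wlr <- sum(abs(dy)) / sum(abs(ddy))
    guardedLog(c(m0, m0 - m2, m0 - m4, sparseness, irregularity, wlr),
               spec$logFloor)
  }
  a <- f6(x)
  b <- f6(log(x^2 + .Machine$double.eps))
  out <- -2 * a * b / (a^2 + b^2)
  out[!is.finite(out)] <- 0
  names(out) <- c("M0", "M0M2", "M0M4", "SPARSE", "IF", "WLR")
  out
}

lsf4Channel <- function(x, spec) {
  n <- length(x)
  dx <- diff(x)
  mfl <- guardedLog(sqrt(sum(dx^2)), spec$logFloor, base = 10)
  xs <- sort(x)
  b0 <- mean(xs)
  b1 <- mean(((seq_len(n) - 1) / (n - 1)) * xs)
  ls <- 2 * b1 - b0
  msr <- abs(sum(sign(x) * sqrt(abs(x)))) / n
  wamp <- sum(abs(dx) > spec$wampThreshold)
  c(MFL = mfl, LS = ls, MSR = msr, WAMP = wamp)
}

lsf9Channel <- function(x, spec) {
  n <- length(x)
  c(lsf4Channel(x, spec),
    ZC = zeroCrossings(x, spec$zcThreshold),
    RMS = sqrt(mean(x^2)),
    IEMG = sum(abs(x)),
    DASDV = sqrt(sum(diff(x)^2) / (n - 1)),
    VAR = sum(x^2) / (n - 1))
}

channelFeatures <- function(x, spec) {
  switch(spec$setName,
    TD = tdChannel(x, spec),
    TDAR = c(tdChannel(x, spec), AR = arCoefficients(x, spec$arOrder)),
    TDPSD = tdpsdChannel(x, spec),
    LSF4 = lsf4Channel(x, spec),
    LSF9 = lsf9Channel(x, spec))
}

windowFeatureVector <- function(window, spec) {
  if (spec$setName == "TDPSD") {
    zero <- apply(window, 1, function(ch) all(ch == 0))
    if (any(zero))
      stop("TDPSD undefined for identically zero channel(s): ",
           paste(which(zero), collapse = ", "))
  }
  minSamples <- switch(spec$setName, TD = 3L, TDAR = spec$arOrder + 1L,
                       TDPSD = 5L, LSF4 = 2L, LSF9 = 2L)
  if (ncol(window) < minSamples)
    stop(spec$setName, " requires at least ", minSamples, " samples")
  # apply() returns features x channels; column-major unlisting yields
  # contiguous per-channel blocks
  as.numeric(apply(window, 1, channelFeatures, spec = spec))
}

#' Hudgins time-domain features (MAV, ZC, SSC, WL)
#'
#' Per channel: mean absolute value, zero crossings (sign change with
#' amplitude difference at least \code{zcThreshold}), slope sign changes
#' (local extrema with deadband \code{sscThreshold}), and waveform
#' length.
#'
#' @param window channels x samples numeric matrix.
#' @param spec a \code{\link{featureSpec}} (thresholds are read from it).
#' @return Numeric vector of length 4 x channels (channel blocks).
#' @export
featuresTD <- function(window, spec = featureSpec("TD"))
  windowFeatureVector(window, modifyList(spec, list(setName = "TD")))

#' TD features plus 4th-order autoregressive coefficients
#'
#' AR coefficients are estimated by Levinson-Durbin recursion on the
#' biased autocorrelation and reported in the polynomial convention
#' A(z) = 1 + sum a_j z^-j (the negated prediction coefficients).
#'
#' @inheritParams featuresTD
#' @return Numeric vector of length 8 x channels.
#' @export
featuresTDAR <- function(window, spec = featureSpec("TDAR"))
  windowFeatureVector(window, modifyList(spec, list(setName = "TDAR")))

#' TDPSD features (power-spectral moments with orientation normalization)
#'
#' Per channel, spectral moments m0, m2, m4 are computed in the time
#' domain from the signal and its first and second differences, power
#' normalized (m^0.1 / 0.1); the six log-features
#' {m0, m0 - m2, m0 - m4, sparseness, irregularity factor, waveform
#' length ratio} are computed for the raw window and its log-scaled
#' version, and combined elementwise as -2ab / (a^2 + b^2).
#'
#' @inheritParams featuresTD
#' @return Numeric vector of length 6 x channels.
#' @export
featuresTDPSD <- function(window, spec = featureSpec("TDPSD"))
  windowFeatureVector(window, modifyList(spec, list(setName = "TDPSD")))

#' LSF4 features (MFL, L-scale, MSR, Willison amplitude)
#'
#' Per channel: maximum fractal length log10(sqrt(sum(diff(x)^2))),
#' L-scale (second L-moment, 2 b1 - b0 over ascending order statistics),
#' mean value of the square root read as
#' |sum(sign(x) sqrt(|x|))| / N, and Willison amplitude (steps with
#' |diff| strictly above \code{wampThreshold}).
#'
#' @inheritParams featuresTD
#' @return Numeric vector of length 4 x channels.
#' @export
featuresLSF4 <- function(window, spec = featureSpec("LSF4"))
  windowFeatureVector(window, modifyList(spec, list(setName = "LSF4")))

#' LSF9 features (LSF4 plus ZC, RMS, IEMG, DASDV, VAR)
#'
#' Adds zero crossings, root mean square, integrated EMG (sum of
#' absolute values), difference absolute standard deviation
#' sqrt(sum(diff^2) / (N - 1)), and the uncentred variance
#' sum(x^2) / (N - 1).
#'
#' @inheritParams featuresTD
#' @return Numeric vector of length 9 x channels.
#' @export
featuresLSF9 <- function(window, spec = featureSpec("LSF9"))
  windowFeatureVector(window, modifyList(spec, list(setName = "LSF9")))

#' Extract a FeatureMatrix from a WindowSet
#'
#' @param windowset a \linkS4class{WindowSet}.
#' @param spec a \code{\link{featureSpec}} naming the set.
#' @return A \linkS4class{FeatureMatrix} with
#'   d = (features per channel) x channels columns; labels carried
#'   through from the windows.
#' @export
extractFeatures <- function(windowset, spec = featureSpec("TD")) {
  stopifnot(is(windowset, "WindowSet"), inherits(spec, "FeatureSpec"))
  n <- nWindows(windowset)
  if (n == 0) stop("empty WindowSet")
  nchan <- dim(windowset@windows)[2]
  d <- FEATURES_PER_CHANNEL[[spec$setName]] * nchan
  values <- matrix(0, n, d)
  w <- dim(windowset@windows)[3]
  for (i in seq_len(n)) {
    v <- windowFeatureVector(matrix(windowset@windows[i, , ], nchan, w),
                             spec)
    if (any(!is.finite(v)))
      stop("non-finite feature in window ", i, " (feature index ",
           which(!is.finite(v))[1], ")")
    values[i, ] <- v
  }
  FeatureMatrix(values, spec$setName, windowset@gestureLabels,
                windowset@subjectIds, windowset@repetitionIds)
}
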