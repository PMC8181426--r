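# Digital filtering (60 Hz notch + 20 Hz high-pass) and overlapped
# windowing (151 / 50 ms defaults).

#' Filter specification
#'
#' A 2nd-order IIR notch (RBJ biquad) against powerline interference and
#' a Butterworth high-pass against motion artifacts. Both are applied
#' forward-backward (zero-phase) by default so windows are not
#' phase-shifted relative to their labels; set \code{causal = TRUE} for
#' single-pass filtering.
#'
#' @param notchHz notch center frequency (Hz), default 60.
#' @param notchQ notch quality factor, default 30.
#' @param highpassHz high-pass cutoff (Hz), default 20.
#' @param highpassOrder Butterworth order, default 4.
#' @param causal single-pass (TRUE) or zero-phase (FALSE, default).
#' @return An object of class \code{"FilterSpec"}.
#' @export
filterSpec <- function(notchHz = 60, notchQ = 30, highpassHz = 20,
                       highpassOrder = 4, causal = FALSE) {
  stopifnot(highpassHz > 0, notchHz > highpassHz, notchQ > 0,
            highpassOrder >= 1)
  structure(list(notchHz = notchHz, notchQ = notchQ,
                 highpassHz = highpassHz,
                 highpassOrder = as.integer(highpassOrder),
                 causal = isTRUE(causal)),
            class = "FilterSpec")
}

#' Window specification
#'
#' @param windowMs window duration in ms (default 151).
#' @param incrementMs window step in ms (default 50).
#' @return An object of class \code{"WindowSpec"}.
#' @export
windowSpec <- function(windowMs = 151, incrementMs = 50) {
  stopifnot(incrementMs > 0, incrementMs <= windowMs)
  structure(list(windowMs = windowMs, incrementMs = incrementMs),
            class = "WindowSpec")
}

# Steady-state initial filter state (per unit step input), solved from
# the direct-form-II-transposed state recursion; scaling it by the
# first sample removes most of the startup transient.
filterZi <- function(b, a) {
  m <- max(length(a), length(b))
  b <- c(b, rep(0, m - length(b)))
  a <- c(a, rep(0, m - length(a)))
  if (m < 2) return(numeric(0))
  comp <- rbind(-a[2:m], cbind(diag(1, m - 2), rep(0, m - 2)))
  B <- b[2:m] - a[2:m] * b[1]
  solve(diag(m - 1) - t(comp), B)
}

# Zero-phase (forward-backward) IIR filtering with odd-reflection
# padding and steady-state initial conditions, so that edge transients
# of ringing filters (the high-Q notch in particular) do not leak into
# the returned signal. signal::filtfilt carries no initial state, which
# leaves the notch's long ring-down in short recordings; this follows
# the standard padded-filtfilt construction instead.
zeroPhaseFilter <- function(b, a, x, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) padlen <- min(n - 1L, 1000L)
  if (padlen > 0) {
    head <- 2 * x[1] - x[(padlen + 1):2]
    tail <- 2 * x[n] - x[(n - 1):(n - padlen)]
    xp <- c(head, x, tail)
  } else xp <- x
  zi <- filterZi(b, a)
  y <- iir_filter(b, a, xp, zi * xp[1])
  y <- rev(as.numeric(iir_filter(b, a, rev(as.numeric(y)),
                                 zi * y[length(y)])))
  y[(padlen + 1):(padlen + n)]
}

# RBJ biquad notch coefficients (unit DC and Nyquist gain).
notchCoefficients <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Apply notch and high-pass filters to a recording
#'
#' @param recording an \linkS4class{EmgRecording}.
#' @param spec a \code{\link{filterSpec}}.
#' @return A filtered \linkS4class{EmgRecording} of identical shape and
#'   metadata.
#' @export
applyFilters <- function(recording, spec = filterSpec()) {
  stopifnot(is(recording, "EmgRecording"), inherits(spec, "FilterSpec"))
  fs <- recording@samplingRate
  if (spec$notchHz >= fs / 2 || spec$highpassHz >= fs / 2)
    stop("filter frequencies must be below the Nyquist frequency (",
         fs / 2, " Hz)")
  if (!(spec$highpassHz < spec$notchHz))
    stop("highpassHz must be below notchHz")
  nc <- notchCoefficients(spec$notchHz, fs, spec$notchQ)
  hp <- signal::butter(spec$highpassOrder, spec$highpassHz / (fs / 2),
                       type = "high")
  run <- function(x) {
    if (spec$causal) {
      y <- signal::filter(nc$b, nc$a, x)
      as.numeric(signal::filter(hp$b, hp$a, y))
    } else {
      y <- zeroPhaseFilter(nc$b, nc$a, x)
      zeroPhaseFilter(hp$b, hp$a, y)
    }
  }
  sig <- t(apply(recording@signal, 1, run))
  recording@signal <- sig
  recording
}

#' Extract overlapped windows from a recording
#'
#' Milliseconds are converted to samples as
#' \code{round(ms * fs / 1000)}; at 1,000 Hz the defaults give 151 and
#' 50 samples. Window count is \code{floor((samples - w) / step) + 1}.
#' Windows never span recording (repetition) boundaries, and every
#' window carries the recording's (subject, gesture, repetition) labels.
#'
#' @param recording an \linkS4class{EmgRecording}.
#' @param spec a \code{\link{windowSpec}}.
#' @return A \linkS4class{WindowSet} (empty, with a warning, when the
#'   recording is shorter than one window).
#' @export
extractWindows <- function(recording, spec = windowSpec()) {
  stopifnot(is(recording, "EmgRecording"), inherits(spec, "WindowSpec"))
  fs <- recording@samplingRate
  w <- round(spec$windowMs * fs / 1000)
  step <- round(spec$incrementMs * fs / 1000)
  nchan <- nrow(recording@signal)
  nsamp <- ncol(recording@signal)
  if (nsamp < w) {
    warning("recording shorter than one window; returning empty WindowSet")
    return(WindowSet(array(0, c(0, nchan, w)), integer(0), character(0),
                     integer(0), fs))
  }
  starts <- seq(1L, nsamp - w + 1L, by = step)
  n <- length(starts)
  windows <- array(0, c(n, nchan, w))
  for (i in seq_len(n))
    windows[i, , ] <- recording@signal[, starts[i]:(starts[i] + w - 1L)]
  WindowSet(windows, rep(recording@gestureId, n),
            rep(recording@subjectId, n), rep(recording@repetitionId, n), fs)
}

#' Filter and window a subset of a dataset
#'
#' Selects recordings by subject and repetition, applies the filters,
#' extracts windows, and concatenates them in deterministic
#' (subject, gesture, repetition, time) order.
#'
#' @param dataset an \linkS4class{EmgDataset}.
#' @param subjects subject identifiers (NULL = all), in dataset order.
#' @param repetitions zero-based repetition indices (NULL = all).
#' @param filter a \code{\link{filterSpec}}, or NULL to skip filtering.
#' @param window a \code{\link{windowSpec}}.
#' @return A \linkS4class{WindowSet}.
#' @export
windowsForSubset <- function(dataset, subjects = NULL, repetitions = NULL,
                             filter = filterSpec(), window = windowSpec()) {
  stopifnot(is(dataset, "EmgDataset"))
  allSubj <- subjectIds(dataset)
  if (is.null(subjects)) subjects <- allSubj
  if (!all(subjects %in% allSubj))
    stop("unknown subject(s): ",
         paste(setdiff(subjects, allSubj), collapse = ", "))
  allReps <- sort(unique(repetitionIds(dataset)))
  if (is.null(repetitions)) repetitions <- allReps
  if (!all(repetitions %in% allReps))
    stop("unknown repetition index/indices")
  sel <- Filter(function(r)
    r@subjectId %in% subjects && r@repetitionId %in% repetitions,
    dataset@recordings)
  if (!length(sel)) stop("empty selection")
  ord <- order(match(vapply(sel, function(r) r@subjectId, character(1)),
                     subjects),
               vapply(sel, function(r) r@gestureId, integer(1)),
               vapply(sel, function(r) r@repetitionId, integer(1)))
  sel <- sel[ord]
  parts <- lapply(sel, function(r) {
    if (!is.null(filter)) r <- applyFilters(r, filter)
    extractWindows(r, window)
  })
  bindWindowSets(parts)
}

# Concatenate a list of WindowSet objects (shared geometry assumed).
bindWindowSets <- function(parts) {
  parts <- Filter(function(p) nWindows(p) > 0, parts)
  if (!length(parts)) stop("no windows in selection")
  ns <- vapply(parts, nWindows, integer(1))
  d <- dim(parts[[1]]@windows)
  windows <- array(0, c(sum(ns), d[2], d[3]))
  at <- 0L
  for (p in parts) {
    n <- nWindows(p)
    if (n > 0) windows[at + seq_len(n), , ] <- p@windows
    at <- at + n
  }
  WindowSet(windows,
            unlist(lapply(parts, gestureLabels)),
            unlist(lapply(parts, subjectIds)),
            unlist(lapply(parts, repetitionIds)),
            parts[[1]]@samplingRate)
}

# Subset a WindowSet by row index.
subsetWindows <- function(ws, idx) {
  WindowSet(ws@windows[idx, , , drop = FALSE], ws@gestureLabels[idx],
            ws@subjectIds[idx], ws@repetitionIds[idx], ws@samplingRate)
}
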