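# Multi-subject synthetic surface-EMG generator.
#
# Source model: band-limited Gaussian noise sources, amplitude-modulated
# by gesture-specific activation levels (linear ramp-up then steady
# state), mixed into channels through a per-subject mixing matrix. The
# inter-subject variability knobs emulate the variability sources named
# in the cross-user EMG literature: electrode placement (mixing-matrix
# rotation + perturbation), skin impedance (gain), tissue filtering
# (band-pass corner jitter), and trial-to-trial variation (per-repetition
# multiplicative jitter).

#' SimulationConfig: parameters of the synthetic EMG study
#'
#' Defaults mirror a 15-subject acquisition protocol: 7 gestures,
#' 16 repetitions, 10 channels at 1,000 Hz, 5 s per repetition with a
#' 20% contraction ramp-up.
#'
#' @slot nSubjects,nGestures,nRepetitions,nChannels,nSources counts.
#' @slot durationS seconds per repetition.
#' @slot samplingRate Hz.
#' @slot rampFraction fraction of each repetition occupied by the
#'   contraction ramp-up (in [0, 1)).
#' @slot seed master seed; every stochastic draw derives from it.
#' @slot mixingSd scale of per-subject mixing perturbation (electrode
#'   placement variability; 0 makes all subjects share one mixing).
#' @slot gainSd log-sd of the per-subject gain (skin impedance).
#' @slot cornerJitter relative jitter of the per-subject band-pass
#'   corners around \code{bandHz}.
#' @slot activationSd log-sd of per-subject activation-pattern jitter.
#' @slot repVariability log-sd of per-repetition multiplicative jitter.
#' @slot noiseFloor additive sensor-noise amplitude (signal units).
#' @slot identityMixing force mixing = identity (requires
#'   nSources == nChannels); testing hook.
#' @slot bandHz length-2 nominal band-pass corners in Hz.
#' @export
setClass("SimulationConfig",
  representation(
    nSubjects = "integer", nGestures = "integer", nRepetitions = "integer",
    nChannels = "integer", nSources = "integer",
    durationS = "numeric", samplingRate = "numeric",
    rampFraction = "numeric", seed = "integer",
    mixingSd = "numeric", gainSd = "numeric", cornerJitter = "numeric",
    activationSd = "numeric", repVariability = "numeric",
    noiseFloor = "numeric", identityMixing = "logical", bandHz = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  counts <- c(object@nSubjects, object@nGestures, object@nRepetitions,
              object@nChannels, object@nSources)
  if (any(counts < 1L)) msg <- c(msg, "all counts must be >= 1")
  if (object@rampFraction < 0 || object@rampFraction >= 1)
    msg <- c(msg, "rampFraction must lie in [0, 1)")
  if (object@durationS <= 0 || object@samplingRate <= 0)
    msg <- c(msg, "durationS and samplingRate must be positive")
  if (object@identityMixing && object@nSources != object@nChannels)
    msg <- c(msg, "identityMixing requires nSources == nChannels")
  if (length(object@bandHz) != 2L || object@bandHz[1] <= 0 ||
      object@bandHz[2] <= object@bandHz[1])
    msg <- c(msg, "bandHz must be increasing positive corners")
  if (object@bandHz[2] >= object@samplingRate / 2)
    msg <- c(msg, "upper band corner must be below Nyquist")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' @param nSubjects,nGestures,nRepetitions,nChannels,nSources counts.
#' @param durationS seconds per repetition.
#' @param samplingRate sampling rate in Hz.
#' @param rampFraction contraction ramp-up fraction.
#' @param seed master seed (integer).
#' @param mixingSd,gainSd,cornerJitter,activationSd,repVariability
#'   inter-subject / inter-repetition variability knobs (see class docs).
#' @param noiseFloor additive sensor-noise amplitude.
#' @param identityMixing force an identity mixing matrix (testing hook).
#' @param bandHz nominal band-pass corners in Hz.
#' @return A validated \linkS4class{SimulationConfig}.
#' @export
simConfig <- function(nSubjects = 15, nGestures = 7, nRepetitions = 16,
                      nChannels = 10, nSources = 8, durationS = 5,
                      samplingRate = 1000, rampFraction = 0.2, seed = 1,
                      mixingSd = 1, gainSd = 0.35, cornerJitter = 0.15,
                      activationSd = 0.25, repVariability = 0.10,
                      noiseFloor = 0.01, identityMixing = FALSE,
                      bandHz = c(20, 450)) {
  cfg <- new("SimulationConfig",
    nSubjects = as.integer(nSubjects), nGestures = as.integer(nGestures),
    nRepetitions = as.integer(nRepetitions),
    nChannels = as.integer(nChannels), nSources = as.integer(nSources),
    durationS = as.numeric(durationS),
    samplingRate = as.numeric(samplingRate),
    rampFraction = as.numeric(rampFraction), seed = as.integer(seed),
    mixingSd = as.numeric(mixingSd), gainSd = as.numeric(gainSd),
    cornerJitter = as.numeric(cornerJitter),
    activationSd = as.numeric(activationSd),
    repVariability = as.numeric(repVariability),
    noiseFloor = as.numeric(noiseFloor),
    identityMixing = isTRUE(identityMixing), bandHz = as.numeric(bandHz))
  validObject(cfg)
  cfg
}

#' SubjectModel: the generative model of one synthetic subject
#'
#' @slot subjectId identifier.
#' @slot mixing channels x sources mixing matrix (full column rank).
#' @slot gestureActivations C x sources matrix of nonnegative source
#'   drive levels; rows are pairwise distinct.
#' @slot bandHz per-subject band-pass corners (Hz).
#' @slot gain positive per-subject gain.
#' @slot repVariability log-sd of per-repetition jitter.
#' @export
setClass("SubjectModel",
  representation(
    subjectId = "character", mixing = "matrix",
    gestureActivations = "matrix", bandHz = "numeric",
    gain = "numeric", repVariability = "numeric"
  )
)

setValidity("SubjectModel", function(object) {
  msg <- character()
  if (qr(object@mixing)$rank < ncol(object@mixing))
    msg <- c(msg, "mixing must have full column rank")
  A <- object@gestureActivations
  if (nrow(A) > 1) {
    d <- as.matrix(stats::dist(A))
    if (any(d[upper.tri(d)] <= 0))
      msg <- c(msg, "gesture activation rows must be pairwise distinct")
  }
  if (any(A < 0)) msg <- c(msg, "activations must be nonnegative")
  if (object@gain <= 0) msg <- c(msg, "gain must be positive")
  if (length(msg)) msg else TRUE
})

# Deterministic sub-seed derivation (minstd-style modular hash) so any
# single recording is reproducible in isolation. Documented in the
# methods vignette.
deriveSeed <- function(master, a, b = 0L, c = 0L) {
  h <- as.numeric(master) %% 2147483647
  for (v in c(a, b, c)) h <- (h * 48271 + as.numeric(v) + 1) %% 2147483647
  as.integer(h)
}

# Shared gesture activation prototypes: drawn from the master seed only,
# identical for every subject, so that gestures keep a common cross-user
# structure for adaptation methods to exploit. Gesture 0 is a rest-like
# low-drive class; each other gesture strongly drives 3 sources.
gesturePrototypes <- function(config, seed = config@seed) {
  C <- config@nGestures; S <- config@nSources
  withSeed(deriveSeed(seed, 900001L), {
    P <- matrix(runif(C * S, 0.05, 0.25), C, S)
    P[1, ] <- runif(S, 0.02, 0.06)
    if (C > 1) {
      for (g in 2:C) {
        k <- min(3L, S)
        dom <- sample.int(S, k)
        P[g, dom] <- P[g, dom] + runif(k, 0.7, 1.1)
      }
    }
    P
  })
}

# Run expr with a temporary RNG state seeded by `seed`.
withSeed <- function(seed, expr) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hasSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Build the generative model of one synthetic subject
#'
#' Deterministic given \code{(config, subjectIndex, seed)}. The mixing
#' matrix is a smooth electrode-footprint matrix (channels and sources on
#' a ring) rotated and perturbed per subject; gain, band-pass corners and
#' activation patterns receive per-subject jitter around shared values.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param subjectIndex zero-based subject index in [0, nSubjects).
#' @param seed master seed (defaults to \code{config@seed}).
#' @return A \linkS4class{SubjectModel}.
#' @export
makeSubjectModel <- function(config, subjectIndex, seed = config@seed) {
  stopifnot(is(config, "SimulationConfig"))
  if (subjectIndex < 0 || subjectIndex >= config@nSubjects)
    stop("subjectIndex out of range")
  C <- config@nChannels; S <- config@nSources
  P <- gesturePrototypes(config, seed)
  withSeed(deriveSeed(seed, subjectIndex, 777L), {
    if (config@identityMixing) {
      M <- diag(C)
    } else {
      rot <- rnorm(1, 0, 0.8 * config@mixingSd)   # electrode ring rotation
      width <- 0.9 * exp(rnorm(1, 0, 0.15 * config@mixingSd))
      chAng <- (seq_len(C) - 1) / C * S            # in source spacings
      srcAng <- seq_len(S) - 1
      dmat <- outer(chAng + rot, srcAng, function(a, b) {
        d <- abs(a - b) %% S
        pmin(d, S - d)
      })
      M <- exp(-dmat^2 / (2 * width^2)) +
        0.15 * config@mixingSd * matrix(rnorm(C * S), C, S)
    }
    gain <- exp(rnorm(1, 0, config@gainSd))
    corners <- config@bandHz *
      (1 + config@cornerJitter * runif(2, -1, 1))
    corners[2] <- min(corners[2], 0.95 * config@samplingRate / 2)
    A <- P * exp(config@activationSd * matrix(rnorm(length(P)), nrow(P)))
    model <- new("SubjectModel",
      subjectId = paste0("S", subjectIndex + 1L),
      mixing = M, gestureActivations = A, bandHz = corners,
      gain = gain, repVariability = config@repVariability)
    validObject(model)
    model
  })
}

# Band-limited unit-RMS Gaussian source signal.
bandlimitedNoise <- function(n, fs, bandHz) {
  bf <- signal::butter(2, bandHz / (fs / 2), type = "pass")
  x <- signal::filter(bf, rnorm(n + 200))[-(1:200)]   # drop startup transient
  x <- as.numeric(x)
  r <- sqrt(mean(x^2))
  if (r > 0) x / r else x
}

#' Simulate a single repetition of a gesture
#'
#' Generates band-limited Gaussian source noise, amplitude-modulates it
#' by the gesture's activation row (linear ramp over
#' \code{rampFraction}, then steady state), mixes it through the
#' subject's mixing matrix, applies the subject gain and one
#' per-repetition multiplicative jitter factor, and adds the sensor
#' noise floor.
#'
#' @param model a \linkS4class{SubjectModel}.
#' @param gestureId zero-based gesture label in [0, C).
#' @param config a \linkS4class{SimulationConfig}.
#' @param seed seed for this repetition's draws.
#' @param repetitionId repetition index recorded in the output metadata.
#' @return An \linkS4class{EmgRecording}.
#' @export
simulateRepetition <- function(model, gestureId, config, seed,
                               repetitionId = 0L) {
  stopifnot(is(model, "SubjectModel"), is(config, "SimulationConfig"))
  Cg <- nrow(model@gestureActivations)
  if (gestureId < 0 || gestureId >= Cg) stop("gestureId out of range")
  n <- round(config@durationS * config@samplingRate)
  S <- ncol(model@mixing)
  withSeed(seed, {
    env <- if (config@rampFraction > 0) {
      pmin(seq_len(n) / (config@rampFraction * n), 1)
    } else rep(1, n)
    act <- model@gestureActivations[gestureId + 1L, ]
    src <- matrix(0, S, n)
    for (s in seq_len(S)) {
      if (act[s] != 0)
        src[s, ] <- act[s] * env *
          bandlimitedNoise(n, config@samplingRate, model@bandHz)
    }
    jitter <- exp(rnorm(1, 0, model@repVariability))
    sig <- model@gain * jitter * (model@mixing %*% src)
    if (config@noiseFloor > 0)
      sig <- sig + config@noiseFloor *
        matrix(rnorm(length(sig)), nrow(sig))
    EmgRecording(sig, model@subjectId, gestureId, repetitionId,
                 config@samplingRate)
  })
}

#' Generate a full multi-subject synthetic dataset
#'
#' Fully determined by \code{config@seed}: each subject model and each
#' (subject, gesture, repetition) recording uses a documented derived
#' sub-seed, so any recording is reproducible in isolation.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return An \linkS4class{EmgDataset} with
#'   \code{nSubjects * nGestures * nRepetitions} recordings.
#' @export
generateDataset <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  gestureNames <- if (config@nGestures == 7L) {
    c("no_movement", "wrist_flexion", "wrist_extension", "wrist_pronation",
      "wrist_supination", "power_grip", "hand_open")
  } else paste0("gesture_", seq_len(config@nGestures) - 1L)
  recs <- vector("list",
                 config@nSubjects * config@nGestures * config@nRepetitions)
  i <- 0L
  for (subj in seq_len(config@nSubjects) - 1L) {
    model <- makeSubjectModel(config, subj, config@seed)
    for (g in seq_len(config@nGestures) - 1L) {
      for (rep in seq_len(config@nRepetitions) - 1L) {
        i <- i + 1L
        recs[[i]] <- simulateRepetition(
          model, g, config,
          seed = deriveSeed(config@seed, subj, g + 1000L, rep),
          repetitionId = rep)
      }
    }
  }
  ds <- EmgDataset(recs, gestureNames)
  validObject(ds)
  ds
}

#' Apply a linear channel transform to one subject's recordings
#'
#' Left-multiplies every recording of \code{subjectId} by
#' \code{transform} (channels x channels, invertible), leaving all other
#' subjects untouched. Used to create ground-truth linear domain shifts
#' for adaptation-recovery experiments.
#'
#' @param dataset an \linkS4class{EmgDataset}.
#' @param subjectId subject to transform.
#' @param transform invertible channels x channels matrix.
#' @return A new \linkS4class{EmgDataset}.
#' @export
applyLinearSubjectTransform <- function(dataset, subjectId, transform) {
  stopifnot(is(dataset, "EmgDataset"))
  if (nrow(transform) != dataset@channelCount ||
      ncol(transform) != dataset@channelCount)
    stop("transform must be channels x channels")
  if (rcond(transform) < .Machine$double.eps * 100)
    stop("transform is singular (or numerically so)")
  recs <- lapply(dataset@recordings, function(r) {
    if (r@subjectId == subjectId) r@signal <- transform %*% r@signal
    r
  })
  EmgDataset(recs, dataset@classNames)
}
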