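# Shared fixtures: one small synthetic dataset reused across test files
# (3 subjects, 7 gestures, 16 repetitions, 4 channels, 0.6 s) and a tiny
# network configuration. Everything is generated in code at load time.

tinyConfig <- function(seed = 42, ...) {
  simConfig(nSubjects = 3, nGestures = 7, nRepetitions = 16,
            nChannels = 4, nSources = 4, durationS = 0.6, seed = seed,
            ...)
}

TINY_DS <- generateDataset(tinyConfig())
TINY_WSPEC <- windowSpec(151, 100)

tinyNet <- function(...) {
  networkConfig(nBlocks = 1, kernels = 4, nChannels = 4,
                samplesPerFrame = 151, nClasses = 7, ...)
}

# Hand-built two-class window set: class 0 is low-amplitude noise,
# class 1 is high-amplitude, linearly separable for a mean-pooling
# network. Geometry: nChannels x T.
separableWindows <- function(n = 60, nChannels = 2, T = 31, seed = 9) {
  set.seed(seed)
  w <- array(0, c(n, nChannels, T))
  labels <- rep(0:1, length.out = n)
  for (i in seq_len(n))
    w[i, , ] <- matrix(rnorm(nChannels * T, mean = labels[i] * 2,
                             sd = 0.3), nChannels, T)
  WindowSet(w, labels, rep(c("A", "B"), length.out = n),
            rep(0L, n), 1000)
}
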