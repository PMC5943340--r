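# Shared fixtures, built in code at test time.

# Independent direct-DFT periodogram average: the oracle against which
# epochPSD is checked. Plain O(N^2) transform via explicit cos/sin sums,
# coded without reference to the FFT path.
directDFTPSD <- function(x, fs, windowLen = 5, maxFreq = 44) {
  L <- windowLen * fs
  nSub <- length(x) %/% L
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(L) - 1) / L))
  kMax <- floor(maxFreq * windowLen)
  n <- 0:(L - 1)
  C <- outer(n, seq_len(kMax), function(n, k) cos(2 * pi * k * n / L))
  S <- outer(n, seq_len(kMax), function(n, k) sin(2 * pi * k * n / L))
  acc <- 0
  for (j in seq_len(nSub)) {
    seg <- x[((j - 1) * L + 1):(j * L)] * w
    acc <- acc + (drop(seg %*% C)^2 + drop(seg %*% S)^2)
  }
  acc / nSub * 2 / (fs * sum(w^2))
}

# A small recording: nCh channels of white noise, nEpochs 30-s epochs.
noiseRecording <- function(nCh = 4, nEpochs = 3, fs = 100, seed = 42,
                           sd = 10) {
  withr::with_seed(seed,
    EEGRecording(matrix(rnorm(nCh * nEpochs * 30 * fs, sd = sd), nCh),
                 fs))
}

altHypnogram <- function(nEpochs, block = 10) {
  Hypnogram(rep(rep(c("S2", "REM"), each = block),
                length.out = nEpochs))
}

# One processed signal-level subject, cached across test files (generation
# is the expensive step).
.fixtureCache <- new.env(parent = emptyenv())

signalSubjectFixture <- function() {
  if (!is.null(.fixtureCache$subject)) return(.fixtureCache$subject)
  ace <- ACEParams(a2 = 0.6, c2 = 0.3, templateVar = 0.3, nChannels = 58L,
                   smoothness = 1)
  cs <- CohortSpec(nMZPairs = 1L, nDZPairs = 0L, nTimepoints = 1L,
                   seed = 11L)
  gen <- generateTwinMaps(ace, cs, mode = "compositional")
  hyp <- altHypnogram(200)
  ss <- SignalSpec(samplingRate = 100, nEpochs = 200L, artifactRate = 0.05,
                   artifactGain = 10)
  out <- generateSubjectRecording(gen$maps[[1]], hyp, ss, seed = 5L)
  proc <- processSubject(out$recording, hyp)
  .fixtureCache$subject <- list(map = gen$maps[[1]], hyp = hyp, spec = ss,
                                artifacts = out$artifacts, proc = proc)
  .fixtureCache$subject
}

# A small on-disk signal cohort for pipeline/IO tests.
fileCohortFixture <- function(dir) {
  ace <- ACEParams(a2 = 0.6, c2 = 0.3, templateVar = 0.3, nChannels = 12L,
                   smoothness = 1)
  cs <- CohortSpec(nMZPairs = 2L, nDZPairs = 2L, nTimepoints = 1L,
                   seed = 3L)
  ss <- SignalSpec(samplingRate = 100, nEpochs = 60L, artifactRate = 0.02,
                   artifactGain = 10,
                   stageTransition = balancedStageTransition())
  simulateSignalCohort(ace, cs, ss, outDir = dir)
}
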