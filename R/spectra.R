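## Preprocessing and per-epoch power density spectra: anti-aliased integer
## decimation, average referencing, and the 6 x 5-s Hanning periodogram
## average at 0.2-Hz resolution.

#' Downsample a recording with anti-alias filtering
#'
#' Integer-factor decimation preceded by a zero-phase FIR low-pass (Hamming-
#' windowed, cutoff at 0.8 x the new Nyquist, applied forward and backward so
#' the effective stopband attenuation at the new Nyquist exceeds 60 dB).
#' Signals are reflection-padded before filtering so edges are transient-free.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param targetRate target sampling rate in Hz; must divide the current rate
#'   and exceed 88 Hz (twice the highest analysis frequency).
#' @return the downsampled \linkS4class{EEGRecording}.
#' @export
downsampleRecording <- function(recording, targetRate) {
  stopifnot(is(recording, "EEGRecording"))
  fs <- recording@samplingRate
  if (targetRate <= 88)
    stop("targetRate must exceed 88 Hz (2 x 44 Hz)")
  r <- fs / targetRate
  if (abs(r - round(r)) > 1e-9)
    stop("targetRate must divide the sampling rate (non-integer decimation)")
  r <- as.integer(round(r))
  if (r == 1L) return(recording)

  ord <- 128L
  b <- as.numeric(signal::fir1(ord, 0.8 / r, type = "low"))
  b <- b / sum(b)  # unity DC gain: constant signals pass unchanged
  x <- recording@samples
  pad <- ord
  n <- ncol(x)
  idx <- c(rev(seq_len(pad) + 1L), seq_len(n), n - seq_len(pad))
  y <- t(apply(x[, idx, drop = FALSE], 1, function(ch)
    signal::filtfilt(b, 1, ch)))
  y <- y[, (pad + 1L):(pad + n), drop = FALSE]
  y <- y[, seq(1L, n, by = r), drop = FALSE]
  new("EEGRecording", samples = y, samplingRate = targetRate,
      channelLabels = recording@channelLabels,
      channelPositions = recording@channelPositions,
      subjectId = recording@subjectId, timePoint = recording@timePoint)
}

#' Re-reference a recording to the average of good channels
#'
#' Subtracts, at every sample, the mean over the good channels from every
#' channel (bad channels are re-referenced against the same good-channel
#' mean). After re-referencing, the mean over good channels is zero at every
#' sample.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param goodChannels indices or labels of channels entering the reference;
#'   defaults to all channels.
#' @return the re-referenced \linkS4class{EEGRecording}.
#' @export
averageReference <- function(recording, goodChannels = NULL) {
  stopifnot(is(recording, "EEGRecording"))
  x <- recording@samples
  if (is.null(goodChannels)) goodChannels <- seq_len(nrow(x))
  if (is.character(goodChannels))
    goodChannels <- match(goodChannels, recording@channelLabels)
  if (any(is.na(goodChannels)) || length(goodChannels) < 2)
    stop("at least 2 known good channels are required")
  ref <- colMeans(x[goodChannels, , drop = FALSE])
  x <- sweep(x, 2, ref)
  new("EEGRecording", samples = x, samplingRate = recording@samplingRate,
      channelLabels = recording@channelLabels,
      channelPositions = recording@channelPositions,
      subjectId = recording@subjectId, timePoint = recording@timePoint)
}

## periodic Hann window (standard for averaged periodograms)
hannWindow <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

#' Per-epoch power density spectra
#'
#' For every 30-s scoring epoch and channel, the power density spectrum is the
#' average of six contiguous non-overlapping 5-s Hanning-windowed
#' periodograms, giving 0.2-Hz frequency resolution. One-sided density
#' scaling divides by the sampling rate times the window power, so the
#' integral of the density approximates the time-domain variance. The DC bin
#' is discarded; bins are identified by center frequency and retained up to
#' \code{maxFreq}.
#'
#' @param recording an \linkS4class{EEGRecording}; 5 s must be an integer
#'   number of samples.
#' @param hypnogram a \linkS4class{Hypnogram}; epoch k covers samples
#'   \eqn{[k \cdot 30 \cdot rate, (k+1) \cdot 30 \cdot rate)}, 0-based. A
#'   trailing partial epoch is an error; a hypnogram shorter than the
#'   recording truncates it.
#' @param maxFreq highest retained bin center (Hz).
#' @param windowLen sub-window length in seconds.
#' @return an \linkS4class{EpochSpectra} with an all-TRUE validity mask.
#' @export
epochPSD <- function(recording, hypnogram, maxFreq = 44, windowLen = 5) {
  stopifnot(is(recording, "EEGRecording"), is(hypnogram, "Hypnogram"))
  fs <- recording@samplingRate
  L <- windowLen * fs
  if (abs(L - round(L)) > 1e-9)
    stop("the sub-window must be an integer number of samples")
  L <- as.integer(round(L))
  epochSamples <- as.integer(round(hypnogram@epochLen * fs))
  nSub <- epochSamples %/% L
  if (nSub * L != epochSamples)
    stop("epoch length must be a multiple of the sub-window length")
  nEpochs <- length(hypnogram@stages)
  if (nEpochs * epochSamples > ncol(recording@samples))
    stop("recording shorter than the hypnogram")
  nCh <- nrow(recording@samples)

  w <- hannWindow(L)
  df <- 1 / windowLen
  kMax <- as.integer(floor(maxFreq / df + 1e-9))
  binCenters <- df * seq_len(kMax)
  scale <- 2 / (fs * sum(w^2))

  power <- array(0, dim = c(nEpochs, nCh, kMax))
  B <- 32L  # epochs per FFT batch
  for (b0 in seq(1L, nEpochs, by = B)) {
    b1 <- min(b0 + B - 1L, nEpochs)
    nb <- b1 - b0 + 1L
    seg <- recording@samples[, ((b0 - 1L) * epochSamples + 1L):
                               (b1 * epochSamples), drop = FALSE]
    # time x channels; each channel column splits into nSub x nb sub-windows
    m <- t(seg)
    dim(m) <- c(L, nSub * nb * nCh)
    X <- stats::mvfft(m * w)
    X <- X[2L:(kMax + 1L), , drop = FALSE]
    p <- (Re(X)^2 + Im(X)^2) * scale
    dim(p) <- c(kMax, nSub, nb, nCh)
    # average the sub-window periodograms within each epoch
    q <- p[, 1L, , , drop = FALSE]
    for (j in 2L:nSub) q <- q + p[, j, , , drop = FALSE]
    dim(q) <- c(kMax, nb, nCh)
    power[b0:b1, , ] <- aperm(q / nSub, c(2, 3, 1))
  }

  new("EpochSpectra", power = power, binCenters = binCenters,
      valid = matrix(TRUE, nEpochs, nCh), stages = hypnogram@stages,
      channelLabels = recording@channelLabels)
}
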