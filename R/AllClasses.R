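#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core data containers
## ---------------------------------------------------------------------------

#' Multichannel EEG recording
#'
#' One subject-night of multichannel EEG. Samples are stored channels x time in
#' microvolts. Channel positions are optional 2-D coordinates used only for
#' nearest-neighbour interpolation of excluded channels; a synthetic circular
#' layout is supplied when real electrode geometry is unavailable.
#'
#' @slot samples numeric matrix, channels x time (microvolts).
#' @slot samplingRate sampling rate in Hz.
#' @slot channelLabels character vector, one label per row of \code{samples}.
#' @slot channelPositions numeric matrix channels x 2, or a 0-row matrix when
#'   no geometry is known.
#' @slot subjectId subject identifier.
#' @slot timePoint assessment index (1 or 2).
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(
    samples = "matrix",
    samplingRate = "numeric",
    channelLabels = "character",
    channelPositions = "matrix",
    subjectId = "character",
    timePoint = "integer"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (nrow(object@samples) != length(object@channelLabels))
    msg <- c(msg, "channelLabels length must equal the number of sample rows")
  if (nrow(object@channelPositions) > 0 &&
      nrow(object@channelPositions) != nrow(object@samples))
    msg <- c(msg, "channelPositions must have one row per channel (or none)")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param samples channels x time numeric matrix (microvolts).
#' @param samplingRate sampling rate in Hz.
#' @param channelLabels channel labels; defaults to \code{E1, E2, ...}.
#' @param channelPositions optional channels x 2 coordinate matrix; defaults to
#'   a synthetic circular layout.
#' @param subjectId subject identifier.
#' @param timePoint assessment index.
#' @return an \linkS4class{EEGRecording}.
#' @export
EEGRecording <- function(samples, samplingRate,
                         channelLabels = paste0("E", seq_len(nrow(samples))),
                         channelPositions = circularLayout(nrow(samples)),
                         subjectId = "S1", timePoint = 1L) {
  new("EEGRecording",
      samples = samples, samplingRate = samplingRate,
      channelLabels = channelLabels,
      channelPositions = channelPositions,
      subjectId = as.character(subjectId), timePoint = as.integer(timePoint))
}

#' Per-epoch sleep-stage sequence
#'
#' Stage labels for consecutive fixed-length scoring epochs. Allowed labels are
#' \code{Wake, S1, S2, SWS, REM, Movement}; common aliases (AASM N1--N3) are
#' normalized by \code{\link{readHypnogram}}.
#'
#' @slot stages character vector of per-epoch labels.
#' @slot epochLen epoch length in seconds (30 in the standard scoring scheme).
#' @exportClass Hypnogram
setClass("Hypnogram",
  representation(stages = "character", epochLen = "numeric"))

.STAGE_LEVELS <- c("Wake", "S1", "S2", "SWS", "REM", "Movement")

setValidity("Hypnogram", function(object) {
  msg <- character()
  if (length(object@epochLen) != 1L || object@epochLen <= 0)
    msg <- c(msg, "epochLen must be a single positive number")
  bad <- setdiff(unique(object@stages), .STAGE_LEVELS)
  if (length(bad))
    msg <- c(msg, paste0("unknown stage label(s): ", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a Hypnogram
#' @param stages character vector of per-epoch stage labels.
#' @param epochLen epoch length in seconds.
#' @return a \linkS4class{Hypnogram}.
#' @export
Hypnogram <- function(stages, epochLen = 30) {
  new("Hypnogram", stages = as.character(stages), epochLen = epochLen)
}

#' Per-epoch power density spectra
#'
#' Power density (microvolt^2/Hz) for every scoring epoch, channel and 0.2-Hz
#' frequency bin, with a per-epoch-per-channel validity mask filled in by the
#' artifact-rejection stage.
#'
#' @slot power numeric array epochs x channels x bins.
#' @slot binCenters bin center frequencies (Hz), 0.2-Hz spaced starting at 0.2.
#' @slot valid logical matrix epochs x channels.
#' @slot stages per-epoch stage labels (copied from the hypnogram).
#' @slot channelLabels channel labels.
#' @exportClass EpochSpectra
setClass("EpochSpectra",
  representation(
    power = "array",
    binCenters = "numeric",
    valid = "matrix",
    stages = "character",
    channelLabels = "character"
  )
)

setValidity("EpochSpectra", function(object) {
  msg <- character()
  d <- dim(object@power)
  if (length(d) != 3L)
    msg <- c(msg, "power must be a 3-D array (epochs x channels x bins)")
  else {
    if (d[3] != length(object@binCenters))
      msg <- c(msg, "binCenters length must equal the third power dimension")
    if (!all(dim(object@valid) == d[1:2]))
      msg <- c(msg, "valid mask must be epochs x channels")
    if (length(object@stages) != d[1])
      msg <- c(msg, "stages length must equal the number of epochs")
    if (length(object@channelLabels) != d[2])
      msg <- c(msg, "channelLabels length must equal the number of channels")
  }
  if (length(object@binCenters) > 1) {
    steps <- diff(object@binCenters)
    if (any(abs(steps - 0.2) > 1e-9))
      msg <- c(msg, "bin spacing must be exactly 0.2 Hz")
  }
  if (any(object@power < 0, na.rm = TRUE))
    msg <- c(msg, "power must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Normalized topographic map
#'
#' Channels x bands normalized power fractions for one subject, state and time
#' point. In the standard (normalized) form every band column is non-negative
#' and sums to 1 across channels. Maps produced by the linear-mode synthetic
#' generator are deliberately unnormalized (they may be negative); these carry
#' \code{normalized = FALSE} and skip the sum-to-one validity check.
#'
#' @slot values numeric matrix channels x bands.
#' @slot state sleep state, \code{"NREM"} or \code{"REM"}.
#' @slot subjectId subject identifier.
#' @slot timePoint assessment index.
#' @slot nEpochsUsed number of clean epochs averaged into the map.
#' @slot normalized logical; whether the sum-to-one invariant applies.
#' @exportClass TopographyMap
setClass("TopographyMap",
  representation(
    values = "matrix",
    state = "character",
    subjectId = "character",
    timePoint = "integer",
    nEpochsUsed = "integer",
    normalized = "logical"
  )
)

setValidity("TopographyMap", function(object) {
  msg <- character()
  if (!object@state %in% c("NREM", "REM"))
    msg <- c(msg, "state must be 'NREM' or 'REM'")
  if (isTRUE(object@normalized)) {
    ok <- !is.na(object@values)
    if (any(object@values[ok] < -1e-12))
      msg <- c(msg, "normalized map values must be non-negative")
    sums <- colSums(object@values)
    if (any(abs(sums - 1) > 1e-9, na.rm = TRUE))
      msg <- c(msg, "each band must sum to 1 across channels (within 1e-9)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TopographyMap
#' @param values channels x bands numeric matrix; column names are band labels.
#' @param state \code{"NREM"} or \code{"REM"}.
#' @param subjectId subject identifier.
#' @param timePoint assessment index.
#' @param nEpochsUsed number of clean epochs behind the map (0 for synthetic).
#' @param normalized whether the per-band sum-to-one invariant applies.
#' @return a \linkS4class{TopographyMap}.
#' @export
TopographyMap <- function(values, state = "NREM", subjectId = "S1",
                          timePoint = 1L, nEpochsUsed = 0L,
                          normalized = TRUE) {
  new("TopographyMap", values = values, state = state,
      subjectId = as.character(subjectId), timePoint = as.integer(timePoint),
      nEpochsUsed = as.integer(nEpochsUsed), normalized = normalized)
}

## ---------------------------------------------------------------------------
## Parameter objects
## ---------------------------------------------------------------------------

#' ACE variance-decomposition parameters
#'
#' Generative counterpart of the quantities a twin analysis estimates: the
#' fractions of a unit deviation variance attributable to additive genetics
#' (\code{a2}, correlated 1 in MZ and 0.5 in DZ co-twins), common environment
#' (\code{c2}, shared within a pair) and unique environment (\code{e2}).
#' \code{templateVar} is the spatial variance of the population template shared
#' by all subjects, expressed relative to the unit deviation variance;
#' \code{smoothness} is the half-width (in channels) of the circular
#' moving-average filter applied to every spatial field.
#'
#' @slot a2,c2,e2 variance fractions, non-negative, summing to 1.
#' @slot templateVar template spatial variance (>= 0).
#' @slot nChannels number of channels.
#' @slot smoothness spatial smoothing half-width in channels (>= 0).
#' @exportClass ACEParams
setClass("ACEParams",
  representation(a2 = "numeric", c2 = "numeric", e2 = "numeric",
                 templateVar = "numeric", nChannels = "integer",
                 smoothness = "numeric"))

setValidity("ACEParams", function(object) {
  msg <- character()
  fr <- c(object@a2, object@c2, object@e2)
  if (any(fr < 0) || any(fr > 1))
    msg <- c(msg, "a2, c2, e2 must lie in [0, 1]")
  if (abs(sum(fr) - 1) > 1e-9)
    msg <- c(msg, "a2 + c2 + e2 must equal 1")
  if (object@templateVar < 0)
    msg <- c(msg, "templateVar must be >= 0")
  if (object@nChannels < 3)
    msg <- c(msg, "nChannels must be >= 3")
  if (object@smoothness < 0)
    msg <- c(msg, "smoothness must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct ACEParams
#' @param a2,c2,e2 variance fractions (must sum to 1).
#' @param templateVar spatial variance of the shared population template
#'   relative to the unit deviation variance.
#' @param nChannels number of channels (58 in the high-density montage after
#'   dropping ocular/myographic leads).
#' @param smoothness spatial correlation half-width in channels.
#' @return an \linkS4class{ACEParams}.
#' @export
ACEParams <- function(a2 = 0.4, c2 = 0.4, e2 = 1 - a2 - c2,
                      templateVar = 0.5, nChannels = 58L, smoothness = 2) {
  new("ACEParams", a2 = a2, c2 = c2, e2 = e2, templateVar = templateVar,
      nChannels = as.integer(nChannels), smoothness = smoothness)
}

#' Twin-cohort layout specification
#'
#' @slot nMZPairs,nDZPairs pair counts.
#' @slot nTimepoints 1 or 2 assessments.
#' @slot retestStability correlation applied to the unique-environment field
#'   between the two assessments (additive-genetic and common-environment
#'   fields persist unchanged).
#' @slot bands ordered band labels.
#' @slot seed integer master seed.
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(nMZPairs = "integer", nDZPairs = "integer",
                 nTimepoints = "integer", retestStability = "numeric",
                 bands = "character", seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nMZPairs < 0 || object@nDZPairs < 0)
    msg <- c(msg, "pair counts must be >= 0")
  if (object@nMZPairs + object@nDZPairs < 1)
    msg <- c(msg, "at least one twin pair is required")
  if (!object@nTimepoints %in% 1:2)
    msg <- c(msg, "nTimepoints must be 1 or 2")
  if (object@retestStability < 0 || object@retestStability > 1)
    msg <- c(msg, "retestStability must lie in [0, 1]")
  if (!length(object@bands))
    msg <- c(msg, "at least one band label is required")
  if (length(msg)) msg else TRUE
})

#' Construct a CohortSpec
#'
#' Defaults mirror the study design this package emulates: 14 MZ and 11 DZ
#' same-sex pairs assessed twice, 6 months apart.
#' @param nMZPairs,nDZPairs numbers of monozygotic / dizygotic pairs.
#' @param nTimepoints number of assessments (1 or 2).
#' @param retestStability between-assessment correlation of the unique
#'   environmental field.
#' @param bands ordered band labels.
#' @param seed master seed; all generator stages draw from named substreams of
#'   this seed.
#' @return a \linkS4class{CohortSpec}.
#' @export
CohortSpec <- function(nMZPairs = 14L, nDZPairs = 11L, nTimepoints = 2L,
                       retestStability = 0.85,
                       bands = defaultBandScheme()$label, seed = 1L) {
  new("CohortSpec", nMZPairs = as.integer(nMZPairs),
      nDZPairs = as.integer(nDZPairs), nTimepoints = as.integer(nTimepoints),
      retestStability = retestStability, bands = bands,
      seed = as.integer(seed))
}

#' Raw-signal synthesis specification
#'
#' Parameters of the band-limited-noise signal model used to render synthetic
#' topography maps as multichannel recordings: per-stage per-band global
#' amplitudes, a first-order Markov stage process, a common 1/f background and
#' multiplicative epoch artifacts.
#'
#' @slot samplingRate Hz; must exceed twice the highest band edge (44 Hz).
#' @slot epochLen epoch length in seconds.
#' @slot nEpochs number of scoring epochs.
#' @slot stageTransition row-stochastic stage transition matrix with dimnames
#'   over \code{Wake, S1, S2, SWS, REM}.
#' @slot bandAmplitude stages x bands amplitude scale matrix.
#' @slot artifactRate fraction of epochs corrupted.
#' @slot artifactGain amplitude multiplier applied to corrupted channels.
#' @slot artifactChannels number of channels corrupted per artifact epoch.
#' @slot backgroundScale amplitude of the common 1/f background relative to
#'   the mean band amplitude.
#' @exportClass SignalSpec
setClass("SignalSpec",
  representation(samplingRate = "numeric", epochLen = "numeric",
                 nEpochs = "integer", stageTransition = "matrix",
                 bandAmplitude = "matrix", artifactRate = "numeric",
                 artifactGain = "numeric", artifactChannels = "integer",
                 backgroundScale = "numeric"))

setValidity("SignalSpec", function(object) {
  msg <- character()
  if (object@samplingRate <= 88)
    msg <- c(msg, "samplingRate must exceed 88 Hz (2 x highest band edge)")
  if (object@epochLen <= 0 || object@nEpochs < 1)
    msg <- c(msg, "epochLen and nEpochs must be positive")
  tm <- object@stageTransition
  if (nrow(tm) != ncol(tm) || is.null(rownames(tm)) ||
      !identical(rownames(tm), colnames(tm)))
    msg <- c(msg, "stageTransition must be square with matching dimnames")
  else if (any(abs(rowSums(tm) - 1) > 1e-9) || any(tm < 0))
    msg <- c(msg, "stageTransition rows must be non-negative and sum to 1")
  if (object@artifactRate < 0 || object@artifactRate > 1)
    msg <- c(msg, "artifactRate must lie in [0, 1]")
  if (object@artifactRate > 0 && object@artifactGain <= 1)
    msg <- c(msg, "artifactGain must exceed 1")
  if (length(msg)) msg else TRUE
})

#' Default sleep-stage transition matrix
#'
#' First-order Markov dwell/transition probabilities producing hypnogram-like
#' sequences: long S2/SWS runs, consolidated REM episodes, brief wake.
#' @return 5 x 5 row-stochastic matrix with stage dimnames.
#' @export
defaultStageTransition <- function() {
  st <- c("Wake", "S1", "S2", "SWS", "REM")
  m <- matrix(c(
    0.60, 0.30, 0.10, 0.00, 0.00,   # Wake
    0.05, 0.40, 0.50, 0.00, 0.05,   # S1
    0.01, 0.02, 0.85, 0.08, 0.04,   # S2
    0.00, 0.00, 0.10, 0.88, 0.02,   # SWS
    0.01, 0.03, 0.06, 0.00, 0.90),  # REM
    nrow = 5, byrow = TRUE, dimnames = list(st, st))
  m
}

#' Balanced two-state transition matrix for compact validation cohorts
#'
#' A stage chain whose stationary distribution puts equal mass on S2 and
#' REM and none elsewhere, so even short simulated nights contain both
#' analyzed states with near-certainty. Intended for small synthetic
#' cohorts; real-night structure comes from
#' \code{\link{defaultStageTransition}}.
#' @param pSwitch per-epoch probability of switching between S2 and REM.
#' @return 5 x 5 row-stochastic matrix with stage dimnames.
#' @export
balancedStageTransition <- function(pSwitch = 0.3) {
  m <- defaultStageTransition()
  m[, ] <- 0
  m["Wake", "S2"] <- m["S1", "S2"] <- m["SWS", "S2"] <- 1
  m["S2", "S2"] <- 1 - pSwitch; m["S2", "REM"] <- pSwitch
  m["REM", "REM"] <- 1 - pSwitch; m["REM", "S2"] <- pSwitch
  m
}

#' Construct a SignalSpec
#' @param samplingRate synthesis rate in Hz.
#' @param epochLen scoring epoch length (s).
#' @param nEpochs number of epochs per night.
#' @param stageTransition row-stochastic transition matrix
#'   (\code{\link{defaultStageTransition}}).
#' @param bandAmplitude stages x bands amplitude matrix; the default gives the
#'   classical profile (high delta in SWS/S2, reduced delta and spindle power
#'   in REM).
#' @param artifactRate fraction of epochs corrupted.
#' @param artifactGain amplitude multiplier on corrupted channels.
#' @param artifactChannels channels corrupted per artifact epoch.
#' @param backgroundScale relative amplitude of the common 1/f background.
#' @param bands band labels used to build the default amplitude matrix.
#' @return a \linkS4class{SignalSpec}.
#' @export
SignalSpec <- function(samplingRate = 250, epochLen = 30, nEpochs = 960L,
                       stageTransition = defaultStageTransition(),
                       bandAmplitude = defaultBandAmplitude(bands),
                       artifactRate = 0, artifactGain = 10,
                       artifactChannels = 4L,
                       backgroundScale = 0.05,
                       bands = defaultBandScheme()$label) {
  new("SignalSpec", samplingRate = samplingRate, epochLen = epochLen,
      nEpochs = as.integer(nEpochs), stageTransition = stageTransition,
      bandAmplitude = bandAmplitude, artifactRate = artifactRate,
      artifactGain = artifactGain,
      artifactChannels = as.integer(artifactChannels),
      backgroundScale = backgroundScale)
}

#' Default per-stage per-band amplitude scales
#'
#' Microvolt-scale amplitudes echoing the canonical spectral profile of each
#' stage: dominant slow activity in SWS, intermediate in S2, attenuated slow
#' and spindle-free spectra in REM and Wake.
#' @param bands band labels (subset of the default scheme's labels).
#' @return stages x bands numeric matrix.
#' @export
defaultBandAmplitude <- function(bands = defaultBandScheme()$label) {
  base <- c(delta = 30, theta = 12, alpha = 8, sigma = 6,
            beta1 = 3, beta2 = 2, gamma1 = 1.2, gamma2 = 0.8)
  stageScale <- rbind(
    Wake = c(0.3, 0.6, 1.2, 0.4, 1.0, 1.0, 1.0, 1.0),
    S1   = c(0.5, 1.0, 0.8, 0.5, 0.9, 0.9, 0.9, 0.9),
    S2   = c(1.0, 1.0, 0.8, 1.0, 0.8, 0.8, 0.8, 0.8),
    SWS  = c(1.6, 1.1, 0.7, 0.8, 0.7, 0.7, 0.7, 0.7),
    REM  = c(0.4, 0.8, 0.7, 0.3, 0.9, 0.9, 1.0, 1.0))
  colnames(stageScale) <- names(base)
  if (!all(bands %in% names(base)))
    stop("no default amplitude for band(s): ",
         paste(setdiff(bands, names(base)), collapse = ", "))
  amp <- sweep(stageScale[, bands, drop = FALSE], 2, base[bands], `*`)
  amp
}

#' Artifact-rejection policy
#'
#' Thresholding constants for the semi-automated spectral artifact screen:
#' a channel-epoch is flagged when its summed power in the low (default
#' 0.8--4.6 Hz) or high (default 20--40 Hz) band exceeds a multiple of the
#' centered moving median of that channel-band series within the same stage
#' class.
#'
#' @slot lowBand,highBand frequency intervals (Hz).
#' @slot kLow,kHigh threshold multipliers (> 1).
#' @slot window moving-median half-width in epochs.
#' @slot channelBadFraction flagged-epoch fraction condemning a channel.
#' @slot epochBadFraction flagged-good-channel fraction condemning an epoch.
#' @exportClass ArtifactPolicy
setClass("ArtifactPolicy",
  representation(lowBand = "numeric", highBand = "numeric",
                 kLow = "numeric", kHigh = "numeric", window = "integer",
                 channelBadFraction = "numeric", epochBadFraction = "numeric"))

setValidity("ArtifactPolicy", function(object) {
  msg <- character()
  if (length(object@lowBand) != 2L || length(object@highBand) != 2L ||
      diff(object@lowBand) <= 0 || diff(object@highBand) <= 0)
    msg <- c(msg, "lowBand and highBand must be increasing length-2 intervals")
  if (any(c(object@lowBand, object@highBand) < 0))
    msg <- c(msg, "band edges must be non-negative")
  if (object@kLow <= 1 || object@kHigh <= 1)
    msg <- c(msg, "threshold multipliers must exceed 1")
  if (object@window < 1)
    msg <- c(msg, "window must be >= 1 epoch")
  fr <- c(object@channelBadFraction, object@epochBadFraction)
  if (any(fr <= 0) || any(fr > 1))
    msg <- c(msg, "bad fractions must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct an ArtifactPolicy
#' @param lowBand,highBand frequency intervals (Hz) screened for artifact
#'   power; defaults 0.8--4.6 and 20--40 Hz.
#' @param kLow,kHigh multiplicative thresholds over the moving median.
#' @param window moving-median half-width in epochs.
#' @param channelBadFraction flagged fraction above which a channel is
#'   excluded outright.
#' @param epochBadFraction flagged-good-channel fraction above which an epoch
#'   is dropped.
#' @return an \linkS4class{ArtifactPolicy}.
#' @export
ArtifactPolicy <- function(lowBand = c(0.8, 4.6), highBand = c(20, 40),
                           kLow = 4, kHigh = 3, window = 10L,
                           channelBadFraction = 0.2, epochBadFraction = 0.1) {
  new("ArtifactPolicy", lowBand = lowBand, highBand = highBand,
      kLow = kLow, kHigh = kHigh, window = as.integer(window),
      channelBadFraction = channelBadFraction,
      epochBadFraction = epochBadFraction)
}

#' Canonical frequency-band scheme
#'
#' The eight-band partition of the 0.2--44 Hz range used throughout: delta
#' 1--4.6, theta 4.8--7.8, alpha 8--10.8, sigma 11--16, beta1 16.2--20, beta2
#' 20.2--24, gamma1 24.2--34 and gamma2 34.2--44 Hz. Band membership is by
#' 0.2-Hz bin center, inclusive of both printed edges; adjacent bands are one
#' bin step apart so no bin is double-counted.
#'
#' @return data.frame with columns \code{label}, \code{lo}, \code{hi} (Hz).
#' @export
defaultBandScheme <- function() {
  data.frame(
    label = c("delta", "theta", "alpha", "sigma",
              "beta1", "beta2", "gamma1", "gamma2"),
    lo = c(1, 4.8, 8, 11, 16.2, 20.2, 24.2, 34.2),
    hi = c(4.6, 7.8, 10.8, 16, 20, 24, 34, 44),
    stringsAsFactors = FALSE)
}

#' Validate a band scheme
#'
#' Checks ordering, non-overlap and 0.2-Hz grid alignment of a band-scheme
#' data.frame as returned by \code{\link{defaultBandScheme}}.
#' @param scheme data.frame with columns \code{label}, \code{lo}, \code{hi}.
#' @return the scheme, invisibly, or an error.
#' @export
validateBandScheme <- function(scheme) {
  stopifnot(is.data.frame(scheme),
            all(c("label", "lo", "hi") %in% names(scheme)))
  if (any(scheme$hi < scheme$lo))
    stop("band edges must be increasing within each band")
  edges <- c(scheme$lo, scheme$hi)
  if (any(abs(edges / 0.2 - round(edges / 0.2)) > 1e-9))
    stop("every band edge must be a multiple of 0.2 Hz")
  n <- nrow(scheme)
  if (n > 1 && any(scheme$lo[-1] <= scheme$hi[-n]))
    stop("bands must be ascending and non-overlapping")
  invisible(scheme)
}

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: subject %s (time %d)\n", object@subjectId,
              object@timePoint))
  cat(sprintf("  %d channels x %d samples at %g Hz (%.1f min)\n",
              nrow(object@samples), ncol(object@samples),
              object@samplingRate,
              ncol(object@samples) / object@samplingRate / 60))
})

setMethod("show", "Hypnogram", function(object) {
  tab <- table(factor(object@stages, levels = .STAGE_LEVELS))
  cat(sprintf("Hypnogram: %d epochs of %g s\n", length(object@stages),
              object@epochLen))
  print(tab)
})

setMethod("show", "EpochSpectra", function(object) {
  d <- dim(object@power)
  cat(sprintf("EpochSpectra: %d epochs x %d channels x %d bins (%.1f-%.1f Hz)\n",
              d[1], d[2], d[3], min(object@binCenters), max(object@binCenters)))
  cat(sprintf("  valid channel-epochs: %d / %d\n", sum(object@valid),
              length(object@valid)))
})

setMethod("show", "TopographyMap", function(object) {
  cat(sprintf("TopographyMap: subject %s, %s, time %d (%d epochs; %s)\n",
              object@subjectId, object@state, object@timePoint,
              object@nEpochsUsed,
              if (object@normalized) "normalized" else "linear-mode"))
  cat(sprintf("  %d channels x %d bands [%s]\n", nrow(object@values),
              ncol(object@values),
              paste(colnames(object@values), collapse = ", ")))
})

## ---------------------------------------------------------------------------
## Accessor generics
## ---------------------------------------------------------------------------

#' @rdname accessors
#' @param object a package data object.
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("stages", function(object) standardGeneric("stages"))
#' @rdname accessors
#' @export
setGeneric("mapValues", function(object) standardGeneric("mapValues"))
#' @rdname accessors
#' @export
setGeneric("binCenters", function(object) standardGeneric("binCenters"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))

#' Accessors for sleeptopo data objects
#'
#' Small accessors exposing the slots of \linkS4class{EEGRecording},
#' \linkS4class{Hypnogram}, \linkS4class{EpochSpectra} and
#' \linkS4class{TopographyMap} without direct slot access.
#' @name accessors
NULL

#' @rdname accessors
setMethod("samplingRate", "EEGRecording", function(object) object@samplingRate)
#' @rdname accessors
setMethod("channelLabels", "EEGRecording", function(object) object@channelLabels)
#' @rdname accessors
setMethod("channelLabels", "EpochSpectra", function(object) object@channelLabels)
#' @rdname accessors
setMethod("stages", "Hypnogram", function(object) object@stages)
#' @rdname accessors
setMethod("stages", "EpochSpectra", function(object) object@stages)
#' @rdname accessors
setMethod("mapValues", "TopographyMap", function(object) object@values)
#' @rdname accessors
setMethod("binCenters", "EpochSpectra", function(object) object@binCenters)
#' @rdname accessors
setMethod("validMask", "EpochSpectra", function(object) object@valid)
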