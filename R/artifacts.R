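## Semi-automated artifact rejection: spectral-power thresholding against a
## stage-aware moving median, channel screening, epoch consolidation and
## map-level repair of excluded channels.

## internal: summed power in a frequency interval, epochs x channels
bandPower <- function(spectra, band) {
  sel <- spectra@binCenters >= band[1] - 1e-9 &
    spectra@binCenters <= band[2] + 1e-9
  if (!any(sel)) stop("band contains no frequency bins")
  rowSums(spectra@power[, , sel, drop = FALSE], dims = 2)
}

## internal: NREM/REM stage class per epoch (NA outside both classes)
stageClass <- function(stages) {
  cls <- rep(NA_character_, length(stages))
  cls[stages %in% c("S2", "SWS")] <- "NREM"
  cls[stages == "REM"] <- "REM"
  cls
}

## internal: centered moving median with the window clipped to the series
movingMedian <- function(x, halfWidth) {
  n <- length(x)
  k <- min(2L * halfWidth + 1L, if (n %% 2L == 1L) n else n - 1L)
  if (k < 3L) return(rep(stats::median(x), n))
  stats::runmed(x, k, endrule = "median")
}

#' Flag artifactual channel-epochs by spectral power thresholds
#'
#' A channel-epoch is flagged when its summed power in the low or the high
#' screening band exceeds \code{kLow} (resp. \code{kHigh}) times the centered
#' moving median of that channel-band power series, computed within the same
#' stage class (NREM = S2 + SWS, REM). The stage-aware reference prevents
#' REM's lower slow-wave power from inflating NREM flags, and the
#' multiplicative threshold makes flagging invariant to global rescaling of a
#' subject's recording. Epochs outside both stage classes are never flagged
#' (they do not enter topographic averaging).
#'
#' @param spectra an \linkS4class{EpochSpectra}.
#' @param policy an \linkS4class{ArtifactPolicy}.
#' @return logical matrix epochs x channels; TRUE = flagged.
#' @export
flagEpochs <- function(spectra, policy) {
  stopifnot(is(spectra, "EpochSpectra"), is(policy, "ArtifactPolicy"))
  validObject(policy)
  nyq <- max(spectra@binCenters)
  if (policy@highBand[2] > nyq + 1e-9)
    stop("screening band exceeds the available frequency range")
  low <- bandPower(spectra, policy@lowBand)
  high <- bandPower(spectra, policy@highBand)
  cls <- stageClass(spectra@stages)
  flags <- matrix(FALSE, nrow(low), ncol(low))
  for (cl in unique(cls[!is.na(cls)])) {
    idx <- which(cls == cl)
    for (ch in seq_len(ncol(low))) {
      lo <- low[idx, ch]
      hi <- high[idx, ch]
      if (all(lo == 0) && all(hi == 0))
        stop("degenerate all-zero channel ", ch)
      flags[idx, ch] <- lo > policy@kLow * movingMedian(lo, policy@window) |
        hi > policy@kHigh * movingMedian(hi, policy@window)
    }
  }
  flags
}

#' Screen channels by their flagged-epoch fraction
#'
#' A channel is condemned when its fraction of flagged epochs (over the
#' epochs belonging to the NREM/REM stage classes) exceeds
#' \code{channelBadFraction}.
#'
#' @param flags logical matrix from \code{\link{flagEpochs}}.
#' @param policy an \linkS4class{ArtifactPolicy}.
#' @param stages optional per-epoch stage labels; when supplied, only epochs
#'   in the NREM/REM classes enter the fraction.
#' @return sorted integer vector of bad-channel indices (possibly empty).
#' @export
screenChannels <- function(flags, policy, stages = NULL) {
  use <- if (is.null(stages)) seq_len(nrow(flags))
         else which(!is.na(stageClass(stages)))
  if (!length(use)) return(integer())
  frac <- colMeans(flags[use, , drop = FALSE])
  sort(which(frac > policy@channelBadFraction))
}

#' Consolidate flags into a per-epoch keep mask
#'
#' An epoch is dropped when the fraction of flagged good channels exceeds
#' \code{epochBadFraction}, or when a user-supplied drop list (the stand-in
#' for interactive visual inspection) names it. Channel validity combines the
#' bad-channel list with the per-channel-epoch flags.
#'
#' @param flags logical matrix epochs x channels from \code{\link{flagEpochs}}.
#' @param badChannels integer indices from \code{\link{screenChannels}}.
#' @param policy an \linkS4class{ArtifactPolicy}.
#' @param userMask optional integer vector of 1-based epoch indices to drop
#'   unconditionally.
#' @return list with \code{keepEpoch} (logical per epoch), \code{goodChannels}
#'   (integer indices) and \code{valid} (logical epochs x channels: epoch
#'   kept, channel good, not flagged).
#' @export
consolidateEpochMask <- function(flags, badChannels, policy, userMask = NULL) {
  nEpochs <- nrow(flags)
  good <- setdiff(seq_len(ncol(flags)), badChannels)
  if (!length(good)) stop("no good channels remain")
  frac <- rowMeans(flags[, good, drop = FALSE])
  keep <- frac <= policy@epochBadFraction
  if (!is.null(userMask)) {
    if (any(userMask < 1 | userMask > nEpochs))
      stop("user mask indexes epochs outside the recording")
    keep[userMask] <- FALSE
  }
  valid <- !flags
  valid[!keep, ] <- FALSE
  valid[, badChannels] <- FALSE
  list(keepEpoch = keep, goodChannels = good, valid = valid)
}

#' Repair excluded channels in a topographic map
#'
#' Replaces each bad channel's normalized power by the inverse-distance-
#' weighted mean of its 3 nearest good channels (unweighted mean under equal
#' distances), then renormalizes each band to sum to 1, so every subject
#' contributes a full channel vector to the similarity analysis.
#'
#' @param map a normalized \linkS4class{TopographyMap} (bad channels may hold
#'   NA or arbitrary values).
#' @param badChannels integer indices of channels to repair.
#' @param positions channels x 2 coordinate matrix.
#' @return the repaired \linkS4class{TopographyMap}.
#' @export
interpolateChannelMaps <- function(map, badChannels, positions) {
  stopifnot(is(map, "TopographyMap"))
  if (!length(badChannels)) return(map)
  v <- map@values
  nCh <- nrow(v)
  if (nrow(positions) != nCh)
    stop("positions must have one row per channel")
  good <- setdiff(seq_len(nCh), badChannels)
  if (length(good) < 3) stop("need at least 3 good channels to interpolate")
  for (b in badChannels) {
    d <- sqrt(rowSums((positions[good, , drop = FALSE] -
                         matrix(positions[b, ], length(good), 2,
                                byrow = TRUE))^2))
    if (all(!is.finite(d)) || min(d) <= 0)
      stop("bad channel ", b, " has no usable neighbors")
    nn <- good[order(d)[1:3]]
    wt <- 1 / d[order(d)[1:3]]
    v[b, ] <- colSums(v[nn, , drop = FALSE] * wt) / sum(wt)
  }
  v <- sweep(v, 2, colSums(v), `/`)
  TopographyMap(v, state = map@state, subjectId = map@subjectId,
                timePoint = map@timePoint, nEpochsUsed = map@nEpochsUsed,
                normalized = TRUE)
}
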