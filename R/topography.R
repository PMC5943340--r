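## From per-epoch spectra to per-state normalized topographic maps:
## within-pair epoch matching, state averaging, per-bin normalization across
## derivations, band and 1-Hz aggregation, grand averages.

#' Match clean epoch counts within a twin pair
#'
#' Within a pair, the maximal common number of clean NREM and REM epochs is
#' used for analysis: per state, n = min of the two twins' clean counts, and
#' each twin contributes its first n clean epochs in chronological order.
#'
#' @param cleanCountsA,cleanCountsB named numeric vectors of clean epoch
#'   counts per state for the two twins.
#' @return named integer vector of matched counts per state.
#' @export
matchPairEpochs <- function(cleanCountsA, cleanCountsB) {
  states <- union(names(cleanCountsA), names(cleanCountsB))
  n <- pmin(cleanCountsA[states], cleanCountsB[states])
  names(n) <- states
  if (any(is.na(n) | n < 1))
    stop("no common clean epochs for state(s): ",
         paste(states[is.na(n) | n < 1], collapse = ", "))
  stats::setNames(as.integer(n), states)
}

## internal: 1-based indices of clean epochs of a state class, chronological
cleanEpochIndices <- function(spectra, keepEpoch, state) {
  cls <- stageClass(spectra@stages)
  which(!is.na(cls) & cls == state & keepEpoch)
}

#' Average clean epochs of one state
#'
#' Arithmetic mean of the per-epoch power density over the first
#' \code{nEpochs} clean epochs of the state class (NREM = S2 + SWS, REM), per
#' channel and frequency bin. Within the selected epochs, channel-epochs
#' marked invalid in the spectra's mask (isolated artifact flags on otherwise
#' clean epochs) are excluded from that channel's mean.
#'
#' @param spectra an \linkS4class{EpochSpectra}.
#' @param keepEpoch logical per-epoch keep mask from
#'   \code{\link{consolidateEpochMask}}.
#' @param state \code{"NREM"} or \code{"REM"}.
#' @param nEpochs number of clean epochs to average; defaults to all.
#' @return channels x bins matrix of mean power density; channels with no
#'   valid epoch at all (condemned channels) are NA.
#' @export
stateAverage <- function(spectra, keepEpoch, state, nEpochs = NULL) {
  idx <- cleanEpochIndices(spectra, keepEpoch, state)
  if (is.null(nEpochs)) nEpochs <- length(idx)
  if (length(idx) < nEpochs || nEpochs < 1)
    stop("insufficient clean ", state, " epochs (", length(idx),
         " available, ", nEpochs, " requested)")
  idx <- idx[seq_len(nEpochs)]
  P <- spectra@power[idx, , , drop = FALSE]
  V <- array(spectra@valid[idx, , drop = FALSE], dim = dim(P))
  counts <- colSums(spectra@valid[idx, , drop = FALSE])
  m <- colSums(P * V) / counts
  m[counts == 0, ] <- NA_real_
  dimnames(m) <- list(spectra@channelLabels, NULL)
  m
}

#' Normalize power per frequency bin across derivations
#'
#' Divides the power at each derivation and frequency bin by the total power
#' across all (good) derivations at that bin, so each bin's channel values sum
#' to 1. Invariant to global rescaling of the input. Channels excluded from
#' the normalization are returned as NA, to be repaired at the map level.
#'
#' @param meanSpectra channels x bins matrix of mean power.
#' @param goodChannels channels entering the normalization total; defaults to
#'   all channels.
#' @return channels x bins matrix of fractions (good channels sum to 1 per
#'   bin).
#' @export
normalizeBins <- function(meanSpectra, goodChannels = NULL) {
  if (is.null(goodChannels)) goodChannels <- seq_len(nrow(meanSpectra))
  tot <- colSums(meanSpectra[goodChannels, , drop = FALSE])
  if (any(tot <= 0)) stop("all-zero frequency bin cannot be normalized")
  out <- sweep(meanSpectra, 2, tot, `/`)
  out[setdiff(seq_len(nrow(meanSpectra)), goodChannels), ] <- NA_real_
  out
}

## internal: bin-center selector for one band (inclusive of both edges)
bandBins <- function(binCenters, lo, hi) {
  which(binCenters >= lo - 1e-9 & binCenters <= hi + 1e-9)
}

#' Aggregate normalized bins into canonical frequency bands
#'
#' The band value per channel is the unweighted mean of the band's 0.2-Hz-bin
#' fractions (band membership by bin center, inclusive of both edges). The
#' mean of per-bin sum-to-one vectors again sums to 1 per band.
#'
#' @param fractions channels x bins matrix from \code{\link{normalizeBins}}.
#' @param binCenters bin center frequencies (Hz).
#' @param scheme band scheme (\code{\link{defaultBandScheme}}).
#' @param state,subjectId,timePoint,nEpochsUsed metadata for the returned map.
#' @return a \linkS4class{TopographyMap} (channels x bands). Channels that
#'   were NA in the input remain NA and must be repaired with
#'   \code{\link{interpolateChannelMaps}} before the map validates as
#'   normalized.
#' @export
aggregateBands <- function(fractions, binCenters, scheme = defaultBandScheme(),
                           state = "NREM", subjectId = "S1", timePoint = 1L,
                           nEpochsUsed = 0L) {
  validateBandScheme(scheme)
  out <- matrix(NA_real_, nrow(fractions), nrow(scheme),
                dimnames = list(rownames(fractions), scheme$label))
  for (i in seq_len(nrow(scheme))) {
    sel <- bandBins(binCenters, scheme$lo[i], scheme$hi[i])
    if (!length(sel))
      stop("band ", scheme$label[i], " outside the available bin range")
    out[, i] <- rowMeans(fractions[, sel, drop = FALSE])
  }
  hasNA <- anyNA(out)
  new("TopographyMap", values = out, state = state,
      subjectId = as.character(subjectId), timePoint = as.integer(timePoint),
      nEpochsUsed = as.integer(nEpochsUsed), normalized = !hasNA)
}

#' Aggregate normalized bins into 1-Hz maps
#'
#' Bin k (k = 1..44, labelled by its upper edge) is the mean of the five
#' 0.2-Hz bins centered at k - 0.8, ..., k Hz; channel sums remain 1 per
#' 1-Hz bin.
#'
#' @param fractions channels x bins matrix from \code{\link{normalizeBins}}.
#' @param binCenters bin center frequencies (Hz).
#' @param maxFreq highest 1-Hz bin upper edge.
#' @return channels x maxFreq matrix of fractions.
#' @export
oneHzMaps <- function(fractions, binCenters, maxFreq = 44) {
  out <- matrix(NA_real_, nrow(fractions), maxFreq,
                dimnames = list(rownames(fractions), seq_len(maxFreq)))
  for (k in seq_len(maxFreq)) {
    sel <- bandBins(binCenters, k - 0.8, k)
    if (length(sel) != 5L)
      stop("1-Hz bin ", k, " does not cover five 0.2-Hz bins")
    out[, k] <- rowMeans(fractions[, sel, drop = FALSE])
  }
  out
}

#' Grand-average topographic map across subjects
#'
#' Unweighted mean of the subjects' normalized maps, renormalized per band
#' (a mean of sum-to-one vectors already sums to one; renormalization guards
#' against accumulated rounding).
#'
#' @param maps list of normalized \linkS4class{TopographyMap} objects sharing
#'   state and band scheme.
#' @return a \linkS4class{TopographyMap} with subject id
#'   \code{"grand-average"}.
#' @export
grandAverageMap <- function(maps) {
  if (!length(maps)) stop("empty map collection")
  states <- unique(vapply(maps, function(m) m@state, character(1)))
  if (length(states) != 1L) stop("maps mix sleep states")
  v <- Reduce(`+`, lapply(maps, mapValues)) / length(maps)
  v <- sweep(v, 2, colSums(v), `/`)
  TopographyMap(v, state = states, subjectId = "grand-average",
                timePoint = maps[[1]]@timePoint,
                nEpochsUsed = 0L, normalized = TRUE)
}

#' Plot a topographic map band as a scalp map
#'
#' Minimal scalp-map utility: channels drawn at their layout positions,
#' colored by normalized power.
#'
#' @param map a \linkS4class{TopographyMap}.
#' @param band band label (column of the map).
#' @param positions channels x 2 coordinate matrix.
#' @param ... passed to \code{plot}.
#' @return invisibly, the plotted values.
#' @export
plotTopographyMap <- function(map, band, positions =
                                circularLayout(nrow(mapValues(map))), ...) {
  v <- mapValues(map)[, band]
  pal <- grDevices::hcl.colors(100, "viridis")
  col <- pal[cut(v, 100, labels = FALSE)]
  graphics::plot(positions, col = col, pch = 16, cex = 2, asp = 1,
                 xlab = "", ylab = "",
                 main = sprintf("%s %s (%s)", map@subjectId, band, map@state),
                 ...)
  invisible(v)
}
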