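## Synthetic twin cohorts with known ACE structure, at the topography-map
## level (closed-form-checkable) and at the raw-signal level (exercises the
## full pipeline).

#' Expected pair correlation under the linear-mode ACE generator
#'
#' Closed-form expectation of the across-channel Pearson correlation between
#' the topographic maps of two subjects, as a function of the ACE parameters
#' and the relationship: with template variance \eqn{v} and deviation
#' correlation \eqn{\rho = a^2 \rho_A + c^2 \rho_C}, the expected correlation
#' is \eqn{(v + \rho) / (v + 1)}. \eqn{\rho_A} is 1 for MZ co-twins, 0.5 for
#' DZ co-twins and 0 for unrelated subjects; \eqn{\rho_C} is 1 for co-twins
#' and 0 otherwise. Exact for linear-mode maps with white channel fields.
#'
#' @param ace an \linkS4class{ACEParams}.
#' @param relationship one of \code{"MZ"}, \code{"DZ"}, \code{"NR"}.
#' @return expected Pearson correlation.
#' @export
expectedPairCorrelation <- function(ace, relationship) {
  stopifnot(is(ace, "ACEParams"))
  rhoA <- switch(relationship, MZ = 1, DZ = 0.5, NR = 0,
                 stop("unknown relationship: ", relationship))
  rhoC <- if (relationship %in% c("MZ", "DZ")) 1 else 0
  rho <- ace@a2 * rhoA + ace@c2 * rhoC
  (ace@templateVar + rho) / (ace@templateVar + 1)
}

#' Generate a twin cohort of topographic maps under an ACE model
#'
#' Each subject's per-band map is a shared population template plus a unit-
#' variance deviation \eqn{\sqrt{a^2} A + \sqrt{c^2} C + \sqrt{e^2} E}: the
#' additive-genetic field \eqn{A} is identical in MZ co-twins and correlated
#' 0.5 in DZ co-twins (constructed as \eqn{0.5 A_1 + \sqrt{0.75} A'}), the
#' common-environment field \eqn{C} is shared within a pair, and \eqn{E} is
#' unique. Across the two assessments \eqn{A} and \eqn{C} persist and \eqn{E}
#' is partially re-drawn with correlation \code{retestStability}.
#'
#' Two rendering modes: \code{"linear"} maps are template + deviation (may be
#' negative; the closed form \code{\link{expectedPairCorrelation}} applies);
#' \code{"compositional"} maps are \eqn{\exp(template + deviation)}
#' renormalized per band, hence positive and summing to 1 across channels.
#'
#' @param ace an \linkS4class{ACEParams}, or a named list of them (one per
#'   band in \code{spec@bands}).
#' @param spec a \linkS4class{CohortSpec}.
#' @param mode \code{"compositional"} or \code{"linear"}.
#' @param state state label attached to the generated maps.
#' @return list with elements \code{maps} (named list of
#'   \linkS4class{TopographyMap}, keyed \code{subject|time|state}) and
#'   \code{truth} (manifest data.frame, per-band ACE parameters, mode, and an
#'   empty artifact log filled in by the signal-level generator).
#' @export
generateTwinMaps <- function(ace, spec, mode = c("compositional", "linear"),
                             state = "NREM") {
  mode <- match.arg(mode)
  stopifnot(is(spec, "CohortSpec"))
  bands <- spec@bands
  if (is(ace, "ACEParams")) {
    ace <- stats::setNames(rep(list(ace), length(bands)), bands)
  }
  if (!identical(sort(names(ace)), sort(bands)))
    stop("band labels of 'ace' do not match spec@bands")
  ace <- ace[bands]
  nCh <- unique(vapply(ace, function(a) a@nChannels, integer(1)))
  if (length(nCh) != 1L)
    stop("all per-band ACEParams must agree on nChannels")
  for (a in ace) validObject(a)

  fams <- c(if (spec@nMZPairs > 0) sprintf("MZ%02d", seq_len(spec@nMZPairs)),
            if (spec@nDZPairs > 0) sprintf("DZ%02d", seq_len(spec@nDZPairs)))
  zyg <- rep(c("MZ", "DZ"), c(spec@nMZPairs, spec@nDZPairs))
  manifest <- data.frame(
    subject_id = paste0(rep(fams, each = 2), c("a", "b")),
    family_id = rep(fams, each = 2),
    zygosity = rep(zyg, each = 2),
    sex = rep(rep(c("F", "M"), length.out = length(fams)), each = 2),
    stringsAsFactors = FALSE)

  nT <- spec@nTimepoints
  s <- spec@retestStability
  maps <- list()
  vals <- array(0, dim = c(nCh, length(bands), nrow(manifest), nT))

  withSubstream(spec@seed, "maps", {
    for (bi in seq_along(bands)) {
      a <- ace[[bi]]
      field <- function() smoothField(stats::rnorm(nCh), a@smoothness)
      template <- sqrt(a@templateVar) * field()
      for (fi in seq_along(fams)) {
        A1 <- field()
        A2 <- if (zyg[fi] == "MZ") A1 else 0.5 * A1 + sqrt(0.75) * field()
        C <- field()
        for (tw in 1:2) {
          A <- if (tw == 1) A1 else A2
          E1 <- field()
          dev1 <- sqrt(a@a2) * A + sqrt(a@c2) * C + sqrt(a@e2) * E1
          si <- 2L * (fi - 1L) + tw
          vals[, bi, si, 1] <- template + dev1
          if (nT == 2) {
            E2 <- s * E1 + sqrt(1 - s^2) * field()
            vals[, bi, si, 2] <- template +
              sqrt(a@a2) * A + sqrt(a@c2) * C + sqrt(a@e2) * E2
          }
        }
      }
    }
  })

  for (si in seq_len(nrow(manifest))) {
    for (tp in seq_len(nT)) {
      v <- vals[, , si, tp, drop = TRUE]
      v <- matrix(v, nrow = nCh, dimnames = list(NULL, bands))
      if (mode == "compositional") {
        v <- exp(v)
        v <- sweep(v, 2, colSums(v), `/`)
      }
      m <- TopographyMap(v, state = state,
                         subjectId = manifest$subject_id[si],
                         timePoint = tp, nEpochsUsed = 0L,
                         normalized = (mode == "compositional"))
      maps[[mapKey(manifest$subject_id[si], tp, state)]] <- m
    }
  }

  truth <- list(manifest = manifest, ace = ace, mode = mode, state = state,
                maps = maps,
                artifacts = data.frame(subject_id = character(),
                                       time_point = integer(),
                                       epoch = integer(), channel = integer(),
                                       stringsAsFactors = FALSE))
  list(maps = maps, truth = truth)
}

#' Generate a first-order Markov hypnogram
#'
#' Simulates a per-epoch stage sequence over \code{Wake, S1, S2, SWS, REM}
#' from the transition matrix in \code{spec}, starting from the chain's
#' stationary distribution (or the first stage if no stationary distribution
#' exists).
#'
#' @param spec a \linkS4class{SignalSpec}.
#' @param seed integer seed (substream \code{"hypnogram"} of this seed).
#' @return a \linkS4class{Hypnogram} of length \code{spec@nEpochs}.
#' @export
generateHypnogram <- function(spec, seed = 1L) {
  stopifnot(is(spec, "SignalSpec"))
  validObject(spec)
  P <- spec@stageTransition
  st <- rownames(P)
  pi0 <- stationaryDistribution(P)
  withSubstream(seed, "hypnogram", {
    out <- character(spec@nEpochs)
    cur <- sample(length(st), 1, prob = pi0)
    out[1] <- st[cur]
    for (e in seq_len(spec@nEpochs - 1L)) {
      cur <- sample(length(st), 1, prob = P[cur, ])
      out[e + 1L] <- st[cur]
    }
    Hypnogram(out, spec@epochLen)
  })
}

#' Stationary distribution of a stage transition matrix
#'
#' Left eigenvector of the transition matrix for eigenvalue 1, normalized to a
#' probability vector; used both to initialize simulated hypnograms and as an
#' independent oracle for their long-run stage fractions.
#' @param P row-stochastic matrix.
#' @return numeric probability vector.
#' @export
stationaryDistribution <- function(P) {
  if (any(abs(rowSums(P) - 1) > 1e-9)) stop("transition rows must sum to 1")
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

#' Render one subject's topographic map as a multichannel recording
#'
#' Synthesizes each 30-s epoch in the frequency domain: every channel receives
#' independent band-limited Gaussian noise whose amplitude within band
#' \eqn{b} is proportional to \eqn{\sqrt{map[ch, b]}} times the stage's band
#' amplitude, plus a 1/f background component common to all channels (which
#' average referencing later removes). Artifact epochs have randomly chosen
#' channels multiplied by \code{artifactGain} and are logged.
#'
#' @param map a positive \linkS4class{TopographyMap} (compositional mode).
#' @param hypnogram a \linkS4class{Hypnogram} with \code{spec@nEpochs} epochs.
#' @param spec a \linkS4class{SignalSpec}; band labels of
#'   \code{spec@bandAmplitude} must match the map's bands.
#' @param scheme band scheme giving each band's frequency interval.
#' @param seed integer seed (substreams \code{"signal"} and
#'   \code{"artifacts"}).
#' @return list with \code{recording} (\linkS4class{EEGRecording}) and
#'   \code{artifacts} (data.frame epoch, channel; 1-based).
#' @export
generateSubjectRecording <- function(map, hypnogram, spec,
                                     scheme = defaultBandScheme(),
                                     seed = 1L) {
  stopifnot(is(map, "TopographyMap"), is(hypnogram, "Hypnogram"),
            is(spec, "SignalSpec"))
  validObject(spec)
  validateBandScheme(scheme)
  vals <- map@values
  if (any(vals < 0)) stop("signal synthesis requires a positive map")
  bands <- colnames(vals)
  if (!all(bands %in% colnames(spec@bandAmplitude)))
    stop("bandAmplitude lacks amplitudes for some map bands")
  if (max(scheme$hi[scheme$label %in% bands]) * 2 >= spec@samplingRate)
    stop("band edge at or above Nyquist")
  if (length(hypnogram@stages) != spec@nEpochs)
    stop("hypnogram length must equal spec@nEpochs")

  nCh <- nrow(vals)
  N <- as.integer(round(spec@epochLen * spec@samplingRate))
  if (N %% 2L != 0L) stop("epoch sample count must be even")
  nF <- N %/% 2L
  freq <- seq_len(nF - 1L) / spec@epochLen  # positive non-Nyquist frequencies

  # band index per synthesis frequency (+-0.1 Hz covers the 0.2-Hz bin width)
  bandOf <- integer(nF - 1L)
  for (bi in seq_along(bands)) {
    row <- scheme[scheme$label == bands[bi], ]
    bandOf[freq >= row$lo - 0.1 & freq <= row$hi + 0.1] <- bi
  }

  stagesPresent <- unique(hypnogram@stages)
  gains <- list()   # per stage: (nF-1) x nCh amplitude gains
  bg <- list()      # per stage: common 1/f background amplitude per freq
  for (s in stagesPresent) {
    amp <- spec@bandAmplitude[s, bands]
    g <- matrix(0, nF - 1L, nCh)
    inband <- bandOf > 0
    g[inband, ] <- sqrt(nCh * t(vals)[bandOf[inband], , drop = FALSE]) *
      amp[bandOf[inband]]
    gains[[s]] <- g
    # common 1/f background, supported over the analyzed range only
    bg[[s]] <- spec@backgroundScale * mean(amp) / sqrt(freq) *
      (freq <= max(scheme$hi) + 4)
  }

  artifacts <- withSubstream(seed, "artifacts", {
    ep <- which(stats::runif(spec@nEpochs) < spec@artifactRate)
    if (length(ep)) {
      do.call(rbind, lapply(ep, function(e)
        data.frame(epoch = e,
                   channel = sort(sample.int(nCh, min(spec@artifactChannels,
                                                      nCh))))))
    } else data.frame(epoch = integer(), channel = integer())
  })

  samples <- matrix(0, nCh, N * spec@nEpochs)
  scale <- sqrt(N / 2)
  B <- 16L  # epochs per synthesis batch
  withSubstream(seed, "signal", {
    for (b0 in seq(1L, spec@nEpochs, by = B)) {
      b1 <- min(b0 + B - 1L, spec@nEpochs)
      nb <- b1 - b0 + 1L
      nc <- nb * nCh  # batch columns, grouped by epoch then channel
      Z <- complex(real = stats::rnorm((nF - 1L) * nc),
                   imaginary = stats::rnorm((nF - 1L) * nc)) / sqrt(2)
      dim(Z) <- c(nF - 1L, nc)
      Zbg <- complex(real = stats::rnorm((nF - 1L) * nb),
                     imaginary = stats::rnorm((nF - 1L) * nb)) / sqrt(2)
      dim(Zbg) <- c(nF - 1L, nb)
      st <- hypnogram@stages[b0:b1]
      G <- do.call(cbind, lapply(st, function(s) gains[[s]]))
      bgAmp <- vapply(st, function(s) bg[[s]], numeric(nF - 1L))
      S <- G * Z + (bgAmp * Zbg)[, rep(seq_len(nb), each = nCh)]
      X <- matrix(0i, N, nc)
      X[2:nF, ] <- S
      X[N:(nF + 2L), ] <- Conj(S)
      x <- Re(stats::mvfft(X, inverse = TRUE)) / N * scale
      dim(x) <- c(N, nCh, nb)
      if (nrow(artifacts)) {
        for (j in seq_len(nb)) {
          ch <- artifacts$channel[artifacts$epoch == b0 + j - 1L]
          if (length(ch)) x[, ch, j] <- x[, ch, j] * spec@artifactGain
        }
      }
      samples[, ((b0 - 1L) * N + 1L):(b1 * N)] <-
        matrix(aperm(x, c(2, 1, 3)), nCh)
    }
  })

  rec <- EEGRecording(samples, spec@samplingRate,
                      subjectId = map@subjectId, timePoint = map@timePoint)
  list(recording = rec, artifacts = artifacts)
}

#' Render a whole synthetic cohort as recordings
#'
#' Loops \code{\link{generateSubjectRecording}} over every subject and time
#' point in the cohort truth, generating one hypnogram per subject-night.
#' With \code{outDir} set, recordings are written as EDF and hypnograms as
#' two-column text, and only file paths are returned (memory-safe for large
#' cohorts); otherwise the objects themselves are returned.
#'
#' @param maps named map list from \code{\link{generateTwinMaps}}
#'   (compositional mode).
#' @param truth matching truth object.
#' @param spec a \linkS4class{SignalSpec}.
#' @param scheme band scheme.
#' @param seed master seed; per-subject substreams are derived from it.
#' @param outDir optional output directory for EDF/hypnogram files.
#' @return list with \code{recordings}, \code{hypnograms} (objects or paths)
#'   and \code{artifacts} (data.frame subject_id, time_point, epoch, channel).
#' @export
generateSignalCohort <- function(maps, truth, spec,
                                 scheme = defaultBandScheme(), seed = 1L,
                                 outDir = NULL) {
  manifest <- truth$manifest
  state <- truth$state
  nT <- max(vapply(maps, function(m) m@timePoint, integer(1)))
  recs <- list(); hyps <- list(); logs <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$subject_id[i]
    for (tp in seq_len(nT)) {
      key <- mapKey(sid, tp, state)
      m <- maps[[key]]
      if (is.null(m)) stop("no map for ", key)
      subSeed <- deriveSeed(seed, paste0("subject|", sid, "|", tp))
      hyp <- generateHypnogram(spec, seed = subSeed)
      out <- generateSubjectRecording(m, hyp, spec, scheme, seed = subSeed)
      if (nrow(out$artifacts))
        logs[[key]] <- data.frame(subject_id = sid, time_point = tp,
                                  out$artifacts)
      if (is.null(outDir)) {
        recs[[key]] <- out$recording
        hyps[[key]] <- hyp
      } else {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        rp <- file.path(outDir, paste0(sid, "_t", tp, ".edf"))
        hp <- file.path(outDir, paste0(sid, "_t", tp, "_hypnogram.tsv"))
        writeEDF(out$recording, rp)
        writeHypnogram(hyp, hp)
        recs[[key]] <- rp
        hyps[[key]] <- hp
      }
    }
  }
  artifacts <- if (length(logs)) do.call(rbind, c(logs, make.row.names = FALSE))
               else truth$artifacts
  list(recordings = recs, hypnograms = hyps, artifacts = artifacts)
}
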