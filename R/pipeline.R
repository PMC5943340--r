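## End-to-end orchestration: per-subject preprocessing, within-pair epoch
## matching, cohort topographies, similarity, heritability, cross-state
## tables, and deterministic TSV export.

#' Preprocess one subject-night into masked spectra
#'
#' Runs the per-subject half of the pipeline: optional decimation to the
#' analysis rate, average referencing, a spectral pass for artifact
#' screening, channel screening, and epoch consolidation. If channels are
#' condemned, the original signal is re-referenced over the surviving
#' channels only (exclusion precedes the final referencing, so condemned
#' channels never contaminate the reference) and the spectra are recomputed.
#' The returned validity mask combines epoch flags, bad channels and the
#' optional user drop list.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param hypnogram the matching \linkS4class{Hypnogram}.
#' @param policy an \linkS4class{ArtifactPolicy}.
#' @param targetRate analysis rate; recordings above it are decimated.
#' @param userMask optional 1-based epoch indices to drop unconditionally.
#' @return list: \code{spectra} (masked \linkS4class{EpochSpectra} of the
#'   referenced signal), \code{keepEpoch}, \code{badChannels},
#'   \code{cleanCounts} (clean epochs per state class), \code{positions}.
#' @export
processSubject <- function(recording, hypnogram, policy = ArtifactPolicy(),
                           targetRate = NULL, userMask = NULL) {
  if (!is.null(targetRate) && recording@samplingRate > targetRate)
    recording <- downsampleRecording(recording, targetRate)
  recRef <- averageReference(recording)
  spectra <- epochPSD(recRef, hypnogram)
  rm(recRef)
  flags <- flagEpochs(spectra, policy)
  bad <- screenChannels(flags, policy, stages = spectra@stages)
  mask <- consolidateEpochMask(flags, bad, policy, userMask)
  if (length(bad)) {
    recRef <- averageReference(recording, goodChannels = mask$goodChannels)
    spectra <- epochPSD(recRef, hypnogram)
    rm(recRef)
  }
  spectra@valid <- mask$valid
  counts <- vapply(c(NREM = "NREM", REM = "REM"), function(st)
    length(cleanEpochIndices(spectra, mask$keepEpoch, st)), numeric(1))
  list(spectra = spectra, keepEpoch = mask$keepEpoch, badChannels = bad,
       cleanCounts = counts, positions = recording@channelPositions,
       flags = flags)
}

#' Build a subject's per-state topographic maps
#'
#' State-averages the first \code{n} clean epochs, normalizes each frequency
#' bin across good derivations, aggregates bands and 1-Hz bins, and repairs
#' excluded channels by nearest-neighbour interpolation.
#'
#' @param processed output of \code{\link{processSubject}}.
#' @param nEpochs named vector of matched epoch counts per state (from
#'   \code{\link{matchPairEpochs}}).
#' @param scheme band scheme.
#' @param subjectId,timePoint map metadata.
#' @return list per state: \code{map} (\linkS4class{TopographyMap}) and
#'   \code{oneHz} (channels x 44 fractions, bad channels repaired).
#' @export
subjectMaps <- function(processed, nEpochs, scheme = defaultBandScheme(),
                        subjectId = "S1", timePoint = 1L) {
  good <- setdiff(seq_len(ncol(processed$spectra@valid)),
                  processed$badChannels)
  out <- list()
  for (st in names(nEpochs)) {
    mean <- stateAverage(processed$spectra, processed$keepEpoch, st,
                         nEpochs[[st]])
    frac <- normalizeBins(mean, goodChannels = good)
    map <- aggregateBands(frac, processed$spectra@binCenters, scheme,
                          state = st, subjectId = subjectId,
                          timePoint = timePoint,
                          nEpochsUsed = nEpochs[[st]])
    map <- interpolateChannelMaps(map, processed$badChannels,
                                  processed$positions)
    oneHz <- oneHzMaps(frac, processed$spectra@binCenters)
    if (length(processed$badChannels)) {
      oneHzMap <- interpolateChannelMaps(
        TopographyMap(oneHz, state = st, subjectId = subjectId,
                      timePoint = timePoint, normalized = FALSE),
        processed$badChannels, processed$positions)
      oneHz <- mapValues(oneHzMap)
    }
    out[[st]] <- list(map = map, oneHz = oneHz)
  }
  out
}

## internal: fetch one subject-night (in-memory cohort or files on disk)
loadSubjectNight <- function(cfg, cohort, sid, tp, manifestRow) {
  if (!is.null(cohort)) {
    key <- mapKey(sid, tp, cfg$states[1])
    k2 <- paste(sid, tp, sep = "|")
    rec <- cohort$recordings[[key]]
    hyp <- cohort$hypnograms[[key]]
    if (is.null(rec)) { rec <- cohort$recordings[[k2]]
                        hyp <- cohort$hypnograms[[k2]] }
    if (is.null(rec)) stop("cohort lacks recording for ", sid, " time ", tp)
    if (is.character(rec)) rec <- readEDF(rec, subjectId = sid,
                                          timePoint = tp)
    if (is.character(hyp)) hyp <- readHypnogram(hyp)
    return(list(recording = rec, hypnogram = hyp))
  }
  recCol <- paste0("recording_t", tp)
  hypCol <- paste0("hypnogram_t", tp)
  rp <- if (recCol %in% names(manifestRow)) manifestRow[[recCol]]
        else paste0(sid, "_t", tp, ".edf")
  hp <- if (hypCol %in% names(manifestRow)) manifestRow[[hypCol]]
        else paste0(sid, "_t", tp, "_hypnogram.tsv")
  list(recording = readEDF(file.path(cfg$dataDir, rp), subjectId = sid,
                           timePoint = tp),
       hypnogram = readHypnogram(file.path(cfg$dataDir, hp)))
}

#' Run the full topographic-heritability pipeline
#'
#' Executes spectra -> artifact rejection -> topography -> similarity ->
#' heritability on a cohort, family by family (the two co-twins are held in
#' memory together so their clean epoch counts can be matched, then
#' released). Writes all tables as TSV plus a YAML run manifest into
#' \code{cfg$outDir}. Deterministic given the configuration and seed.
#'
#' @param cfg a \code{\link{runConfig}} list.
#' @param cohort optional in-memory cohort: named lists \code{recordings}
#'   and \code{hypnograms} keyed \code{subject|time} or
#'   \code{subject|time|state} (as returned by
#'   \code{\link{generateSignalCohort}}); when NULL, files named in the
#'   manifest are read from \code{cfg$dataDir}.
#' @return list with \code{maps}, \code{similarity}, \code{heritability},
#'   \code{crossState}, \code{grand} (per-state grand-average maps),
#'   \code{badChannels}, \code{counts} and \code{files} (paths written).
#' @export
runPipeline <- function(cfg, cohort = NULL) {
  stopifnot(inherits(cfg, "sleeptopoConfig"))
  manifest <- if (is.data.frame(cfg$manifest)) cfg$manifest
              else readManifest(cfg$manifest)
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  famSize <- table(manifest$family_id)
  if (any(famSize != 2))
    stop("family ", paste(names(famSize)[famSize != 2], collapse = ", "),
         " does not have exactly 2 subjects")

  maps <- list(); oneHz <- list()
  badChannels <- list(); countsLog <- list()
  for (fam in unique(manifest$family_id)) {
    rows <- which(manifest$family_id == fam)
    for (tp in cfg$timePoints) {
      proc <- list()
      for (i in rows) {
        sid <- manifest$subject_id[i]
        night <- loadSubjectNight(cfg, cohort, sid, tp, manifest[i, ])
        proc[[sid]] <- tryCatch(
          processSubject(night$recording, night$hypnogram, cfg$policy,
                         targetRate = cfg$targetRate),
          error = function(e) stop("stage 'spectra/artifacts' failed for ",
                                   sid, ": ", conditionMessage(e)))
        rm(night)
      }
      sids <- manifest$subject_id[rows]
      n <- matchPairEpochs(proc[[sids[1]]]$cleanCounts[cfg$states],
                           proc[[sids[2]]]$cleanCounts[cfg$states])
      names(n) <- cfg$states
      for (sid in sids) {
        sm <- subjectMaps(proc[[sid]], n, cfg$scheme, subjectId = sid,
                          timePoint = tp)
        for (st in cfg$states) {
          maps[[mapKey(sid, tp, st)]] <- sm[[st]]$map
          oneHz[[mapKey(sid, tp, st)]] <- sm[[st]]$oneHz
        }
        badChannels[[paste(sid, tp, sep = "|")]] <-
          proc[[sid]]$badChannels
        countsLog[[length(countsLog) + 1L]] <- data.frame(
          subject_id = sid, time_point = tp,
          state = cfg$states, n_epochs_used = as.integer(n[cfg$states]),
          n_bad_channels = length(proc[[sid]]$badChannels),
          stringsAsFactors = FALSE)
      }
      rm(proc)
    }
  }

  groups <- buildPairGroups(manifest, cfg$excludeSubjects)
  sim <- groupMeanSimilarity(groups, maps, bands = cfg$scheme$label,
                             states = cfg$states,
                             timePoints = cfg$timePoints)
  herit <- heritabilityTable(sim, domain = cfg$heritabilityDomain,
                             clip = cfg$clipEstimates)

  gaTime <- cfg$timePoints[length(cfg$timePoints)]
  grand <- list()
  grandOneHz <- list()
  for (st in cfg$states) {
    sel <- maps[vapply(maps, function(m)
      m@state == st && m@timePoint == gaTime, logical(1))]
    grand[[st]] <- grandAverageMap(sel)
    oh <- oneHz[vapply(names(oneHz), function(k)
      endsWith(k, paste0("|", gaTime, "|", st)), logical(1))]
    g <- Reduce(`+`, oh) / length(oh)
    grandOneHz[[st]] <- sweep(g, 2, colSums(g), `/`)
  }
  crossState <- if (all(c("NREM", "REM") %in% cfg$states))
    crossStateCorrelation(grand$NREM, grand$REM) else NULL

  counts <- do.call(rbind, countsLog)
  files <- c(
    similarity_pairs = writeTSV(sim$pairs,
                                file.path(cfg$outDir, "similarity_pairs.tsv")),
    similarity_summary = writeTSV(sim$summary,
                                  file.path(cfg$outDir,
                                            "similarity_summary.tsv")),
    heritability = writeTSV(herit, file.path(cfg$outDir, "heritability.tsv")),
    counts = writeTSV(counts, file.path(cfg$outDir, "epoch_counts.tsv")))
  if (!is.null(crossState))
    files["cross_state"] <- writeTSV(crossState,
                                     file.path(cfg$outDir, "cross_state.tsv"))
  for (st in names(grand)) {
    gdf <- data.frame(channel = seq_len(nrow(mapValues(grand[[st]]))),
                      mapValues(grand[[st]]))
    files[paste0("grand_", st)] <-
      writeTSV(gdf, file.path(cfg$outDir, paste0("grand_average_",
                                                 tolower(st), ".tsv")))
    odf <- data.frame(channel = seq_len(nrow(grandOneHz[[st]])),
                      grandOneHz[[st]], check.names = FALSE)
    names(odf) <- c("channel", paste0("hz", seq_len(ncol(grandOneHz[[st]]))))
    files[paste0("one_hz_", st)] <-
      writeTSV(odf, file.path(cfg$outDir, paste0("one_hz_",
                                                 tolower(st), ".tsv")))
  }
  yaml::write_yaml(configManifest(cfg),
                   file.path(cfg$outDir, "run_manifest.yaml"))
  files["run_manifest"] <- file.path(cfg$outDir, "run_manifest.yaml")

  list(maps = maps, similarity = sim, heritability = herit,
       crossState = crossState, grand = grand, grandOneHz = grandOneHz,
       badChannels = badChannels, counts = counts, files = files)
}

#' Simulate a signal-level twin cohort to disk
#'
#' Generates ACE-structured topographies, renders them as EDF recordings with
#' hypnograms and injected artifacts, and writes the cohort manifest, truth
#' tables and a YAML run manifest — a complete synthetic input set for
#' \code{\link{runPipeline}}.
#'
#' @param ace an \linkS4class{ACEParams} or named per-band list.
#' @param cohortSpec a \linkS4class{CohortSpec}.
#' @param signalSpec a \linkS4class{SignalSpec}.
#' @param outDir output directory.
#' @param scheme band scheme.
#' @return list with \code{manifestPath}, \code{dir}, \code{truth} and the
#'   generated file paths.
#' @export
simulateSignalCohort <- function(ace, cohortSpec, signalSpec,
                                 outDir, scheme = defaultBandScheme()) {
  gen <- generateTwinMaps(ace, cohortSpec, mode = "compositional")
  sig <- generateSignalCohort(gen$maps, gen$truth, signalSpec,
                              scheme = scheme, seed = cohortSpec@seed,
                              outDir = outDir)
  manifest <- gen$truth$manifest
  nT <- cohortSpec@nTimepoints
  for (tp in seq_len(nT)) {
    manifest[[paste0("recording_t", tp)]] <-
      basename(unlist(sig$recordings[mapKey(manifest$subject_id, tp,
                                            gen$truth$state)]))
    manifest[[paste0("hypnogram_t", tp)]] <-
      basename(unlist(sig$hypnograms[mapKey(manifest$subject_id, tp,
                                            gen$truth$state)]))
  }
  manifestPath <- file.path(outDir, "manifest.tsv")
  writeTSV(manifest, manifestPath)
  truthLong <- do.call(rbind, lapply(names(gen$maps), function(k) {
    m <- gen$maps[[k]]
    data.frame(subject_id = m@subjectId, time_point = m@timePoint,
               channel = seq_len(nrow(mapValues(m))), mapValues(m),
               stringsAsFactors = FALSE)
  }))
  files <- c(
    truth_maps = writeTSV(truthLong, file.path(outDir, "truth_maps.tsv")),
    artifacts = writeTSV(sig$artifacts,
                         file.path(outDir, "truth_artifacts.tsv")))
  yaml::write_yaml(list(
    seed = cohortSpec@seed,
    n_mz_pairs = cohortSpec@nMZPairs, n_dz_pairs = cohortSpec@nDZPairs,
    n_timepoints = cohortSpec@nTimepoints,
    retest_stability = cohortSpec@retestStability,
    sampling_rate = signalSpec@samplingRate,
    n_epochs = signalSpec@nEpochs,
    artifact_rate = signalSpec@artifactRate,
    artifact_gain = signalSpec@artifactGain,
    ace = lapply(gen$truth$ace, function(a)
      list(a2 = a@a2, c2 = a@c2, e2 = a@e2, template_var = a@templateVar,
           smoothness = a@smoothness))),
    file.path(outDir, "simulation_manifest.yaml"))
  list(manifestPath = manifestPath, dir = outDir, truth = gen$truth,
       files = files)
}
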