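## Hypnogram text files, the spectra cache, cohort manifests and run
## configuration.

.STAGE_ALIASES <- c(
  Wake = "Wake", W = "Wake", "0" = "Wake",
  S1 = "S1", N1 = "S1", "1" = "S1",
  S2 = "S2", N2 = "S2", "2" = "S2",
  S3 = "SWS", S4 = "SWS", N3 = "SWS", SWS = "SWS", "3" = "SWS", "4" = "SWS",
  REM = "REM", R = "REM", "5" = "REM",
  Movement = "Movement", MT = "Movement")

#' Read a hypnogram from delimited text
#'
#' Expects one row per 30-s epoch with columns \code{epoch_index} (0-based)
#' and \code{stage}. Stage labels are normalized through an alias table
#' covering classic (S1--S4) and AASM (N1--N3) conventions, with S3/S4/N3
#' mapped to SWS.
#'
#' @param path file path (tab- or comma-delimited, optional header).
#' @param nEpochsExpected optional expected epoch count; a mismatch is an
#'   error.
#' @param epochLen epoch length in seconds.
#' @return a \linkS4class{Hypnogram}.
#' @export
readHypnogram <- function(path, nEpochsExpected = NULL, epochLen = 30) {
  if (!file.exists(path)) stop("hypnogram file not found: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else "\t"
  hasHeader <- grepl("stage", first, ignore.case = TRUE)
  d <- utils::read.table(path, sep = sep, header = hasHeader,
                         stringsAsFactors = FALSE)
  stageCol <- as.character(d[[2]])
  mapped <- .STAGE_ALIASES[stageCol]
  if (anyNA(mapped))
    stop("unknown stage label(s): ",
         paste(unique(stageCol[is.na(mapped)]), collapse = ", "))
  if (!is.null(nEpochsExpected) && length(mapped) != nEpochsExpected)
    stop("hypnogram has ", length(mapped), " epochs, expected ",
         nEpochsExpected)
  Hypnogram(unname(mapped), epochLen)
}

#' Write a hypnogram as two-column text
#' @param hypnogram a \linkS4class{Hypnogram}.
#' @param path output path (TSV with header \code{epoch_index, stage};
#'   0-based epoch indices).
#' @return the path, invisibly.
#' @export
writeHypnogram <- function(hypnogram, path) {
  writeTSV(data.frame(epoch_index = seq_along(hypnogram@stages) - 1L,
                      stage = hypnogram@stages), path)
}

#' Persist per-epoch spectra as a gzipped array with a JSON sidecar
#'
#' The power array is stored flattened as a gzipped numeric text stream; bin
#' centers, stage labels, channel labels, dimensions and the validity mask go
#' to a JSON sidecar at \code{paste0(path, ".json")}. Round-trips exactly.
#'
#' @param spectra an \linkS4class{EpochSpectra}.
#' @param path output path (e.g. \code{"spectra.txt.gz"}).
#' @return the path, invisibly.
#' @export
writeSpectra <- function(spectra, path) {
  con <- gzfile(path, "w")
  writeLines(formatC(as.numeric(spectra@power), digits = 17, format = "g"),
             con)
  close(con)
  side <- list(dim = dim(spectra@power), bin_centers = spectra@binCenters,
               stages = spectra@stages,
               channel_labels = spectra@channelLabels,
               valid = as.logical(spectra@valid))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' Read a spectra cache written by \code{\link{writeSpectra}}
#' @param path cache path.
#' @return an \linkS4class{EpochSpectra}.
#' @export
readSpectra <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- gzfile(path, "r")
  vals <- as.numeric(readLines(con))
  close(con)
  new("EpochSpectra",
      power = array(vals, dim = side$dim),
      binCenters = side$bin_centers, stages = side$stages,
      channelLabels = side$channel_labels,
      valid = matrix(side$valid, side$dim[1], side$dim[2]))
}

#' Read a cohort manifest
#'
#' Delimited text with columns \code{subject_id}, \code{family_id},
#' \code{zygosity} (MZ/DZ) and optionally \code{sex} and per-time-point file
#' columns (\code{recording_t1}, \code{hypnogram_t1}, ...).
#'
#' @param path manifest path (TSV or CSV with header).
#' @return data.frame.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else "\t"
  m <- utils::read.table(path, sep = sep, header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("subject_id", "family_id", "zygosity")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (!all(m$zygosity %in% c("MZ", "DZ")))
    stop("zygosity must be MZ or DZ")
  m
}

#' Assemble a run configuration
#'
#' Bundles every tunable of the pipeline into one list that serializes to
#' YAML unchanged. Unknown band labels and malformed policies are rejected at
#' construction, before any computation.
#'
#' @param manifest manifest path or data.frame.
#' @param dataDir directory holding recordings and hypnograms (ignored for
#'   in-memory cohorts).
#' @param outDir output directory for tables and the run manifest.
#' @param targetRate analysis sampling rate (Hz); recordings at a higher rate
#'   are decimated to it.
#' @param scheme band scheme data.frame.
#' @param policy an \linkS4class{ArtifactPolicy}.
#' @param states states analyzed.
#' @param timePoints assessment indices analyzed.
#' @param excludeSubjects subject ids dropped from pairing.
#' @param heritabilityDomain \code{"r"} or \code{"z"} (Falconer input domain).
#' @param clipEstimates clip h2/c2 into [0, 1]?
#' @param seed integer seed recorded in the run manifest.
#' @return list of class \code{sleeptopoConfig}.
#' @export
runConfig <- function(manifest, dataDir = NULL, outDir = tempfile("sleeptopo"),
                      targetRate = 250, scheme = defaultBandScheme(),
                      policy = ArtifactPolicy(), states = c("NREM", "REM"),
                      timePoints = 1L, excludeSubjects = character(),
                      heritabilityDomain = "r", clipEstimates = FALSE,
                      seed = 1L) {
  validateBandScheme(scheme)
  validObject(policy)
  stopifnot(heritabilityDomain %in% c("r", "z"))
  cfg <- list(manifest = manifest, dataDir = dataDir, outDir = outDir,
              targetRate = targetRate, scheme = scheme, policy = policy,
              states = states, timePoints = as.integer(timePoints),
              excludeSubjects = excludeSubjects,
              heritabilityDomain = heritabilityDomain,
              clipEstimates = clipEstimates, seed = as.integer(seed))
  class(cfg) <- "sleeptopoConfig"
  cfg
}

#' Read a YAML run configuration
#' @param path YAML file with the fields of \code{\link{runConfig}} (paths,
#'   spectral settings, band scheme, artifact policy, group options, seed).
#' @return list of class \code{sleeptopoConfig}.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  scheme <- if (is.null(y$scheme)) defaultBandScheme()
            else do.call(data.frame, c(y$scheme, stringsAsFactors = FALSE))
  pol <- if (is.null(y$policy)) ArtifactPolicy()
         else do.call(ArtifactPolicy, y$policy)
  runConfig(manifest = y$manifest, dataDir = y$dataDir,
            outDir = if (is.null(y$outDir)) tempfile("sleeptopo") else y$outDir,
            targetRate = if (is.null(y$targetRate)) 250 else y$targetRate,
            scheme = scheme, policy = pol,
            states = if (is.null(y$states)) c("NREM", "REM") else y$states,
            timePoints = if (is.null(y$timePoints)) 1L else y$timePoints,
            excludeSubjects = if (is.null(y$excludeSubjects)) character()
                              else y$excludeSubjects,
            heritabilityDomain = if (is.null(y$heritabilityDomain)) "r"
                                 else y$heritabilityDomain,
            clipEstimates = isTRUE(y$clipEstimates),
            seed = if (is.null(y$seed)) 1L else y$seed)
}

## internal: serialize the config (minus live objects) into the run manifest
configManifest <- function(cfg) {
  pol <- cfg$policy
  list(targetRate = cfg$targetRate,
       scheme = as.list(cfg$scheme),
       policy = list(lowBand = pol@lowBand, highBand = pol@highBand,
                     kLow = pol@kLow, kHigh = pol@kHigh,
                     window = pol@window,
                     channelBadFraction = pol@channelBadFraction,
                     epochBadFraction = pol@epochBadFraction),
       states = cfg$states, timePoints = cfg$timePoints,
       excludeSubjects = cfg$excludeSubjects,
       heritabilityDomain = cfg$heritabilityDomain,
       clipEstimates = cfg$clipEstimates, seed = cfg$seed,
       version = as.character(utils::packageVersion("sleeptopo")))
}
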