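## Comparison groups (MZ, DZ, NR, Self), topographic Pearson correlations
## over channel vectors, and Fisher-z averaging.

#' Fisher z transform and inverse
#'
#' Variance-stabilizing transform applied to correlation coefficients before
#' averaging: \eqn{z = \mathrm{arctanh}(r)}; the inverse is \eqn{\tanh}.
#' @param r correlation(s) with |r| < 1.
#' @return transformed value(s).
#' @export
fisherZ <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1 for the Fisher z transform")
  atanh(r)
}

#' @rdname fisherZ
#' @param z Fisher-z value(s).
#' @export
fisherZInv <- function(z) tanh(z)

#' Topographic correlation between two maps
#'
#' Pearson product-moment correlation across channels of one band's
#' normalized values of two maps sharing channel set and ordering. A
#' zero-variance channel vector (uniform map) makes the correlation
#' undefined; this is reported as NA with a warning and excluded upstream.
#'
#' @param mapA,mapB \linkS4class{TopographyMap} objects.
#' @param band band label.
#' @return Pearson correlation, or NA if undefined.
#' @export
topoCorrelation <- function(mapA, mapB, band) {
  a <- mapValues(mapA)[, band]
  b <- mapValues(mapB)[, band]
  if (length(a) != length(b) || length(a) < 3)
    stop("maps must share a channel set of at least 3 channels")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero-variance map vector; correlation undefined for band ", band)
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Build the four comparison groups from a cohort manifest
#'
#' MZ and DZ groups are the co-twin pairs of the respective zygosity; NR is
#' every unordered pair of subjects from different families (both zygosity
#' groups pooled) at the same time point; Self pairs a subject's first and
#' second assessment.
#'
#' @param manifest data.frame with columns \code{subject_id},
#'   \code{family_id}, \code{zygosity} (exactly 2 subjects per family,
#'   co-twins sharing zygosity).
#' @param excludeSubjects optional subject ids dropped before pairing (for
#'   cohorts where some subjects are unavailable).
#' @return list of data.frames \code{MZ}, \code{DZ}, \code{NR} (columns
#'   \code{idA}, \code{idB}) and \code{Self} (column \code{id}).
#' @export
buildPairGroups <- function(manifest, excludeSubjects = character()) {
  famSize0 <- table(manifest$family_id)
  if (any(famSize0 != 2))
    stop("every family must have exactly 2 subjects; offending: ",
         paste(names(famSize0)[famSize0 != 2], collapse = ", "))
  m <- manifest[!manifest$subject_id %in% excludeSubjects, , drop = FALSE]
  famSize <- table(m$family_id)
  # families reduced to one subject by exclusions still feed NR and Self
  whole <- names(famSize)[famSize == 2]
  zygByFam <- tapply(m$zygosity, m$family_id, function(z) {
    if (length(unique(z)) != 1) stop("co-twins must share zygosity")
    z[1]
  })
  cotwins <- do.call(rbind, lapply(whole, function(f) {
    ids <- sort(m$subject_id[m$family_id == f])
    data.frame(idA = ids[1], idB = ids[2], zyg = zygByFam[[f]],
               stringsAsFactors = FALSE)
  }))
  ids <- sort(m$subject_id)
  fam <- m$family_id[match(ids, m$subject_id)]
  nr <- which(upper.tri(diag(length(ids))) &
                outer(fam, fam, `!=`), arr.ind = TRUE)
  list(
    MZ = cotwins[cotwins$zyg == "MZ", c("idA", "idB")],
    DZ = cotwins[cotwins$zyg == "DZ", c("idA", "idB")],
    NR = data.frame(idA = ids[nr[, 1]], idB = ids[nr[, 2]],
                    stringsAsFactors = FALSE),
    Self = data.frame(id = ids, stringsAsFactors = FALSE))
}

#' Group-mean topographic similarity table
#'
#' For every group x band x state x time cell, computes the per-pair
#' topographic Pearson correlations, Fisher-z transforms them, averages in the
#' z domain and back-transforms the mean for reporting. MZ/DZ/NR pairs
#' correlate two subjects at the same time point; Self correlates a subject's
#' two assessments (reported under both time columns only once, as time 0).
#' Undefined (zero-variance) correlations are dropped from their cell with a
#' warning. Per-pair values are retained for export to external ANOVA
#' tooling.
#'
#' @param groups pair lists from \code{\link{buildPairGroups}}.
#' @param maps named list of normalized \linkS4class{TopographyMap} objects
#'   keyed \code{subject|time|state} (see \code{\link{generateTwinMaps}}).
#' @param bands band labels to analyze.
#' @param states states to analyze.
#' @param timePoints assessment indices available in \code{maps}.
#' @return list of class data: \code{pairs} (long data.frame: group, band,
#'   state, time, pair_id, r, z) and \code{summary} (per-cell mean z,
#'   back-transformed mean r, n_pairs).
#' @export
groupMeanSimilarity <- function(groups, maps, bands, states = c("NREM", "REM"),
                                timePoints = 1L) {
  getMap <- function(id, tp, st) {
    m <- maps[[mapKey(id, tp, st)]]
    if (is.null(m)) stop("missing map for subject ", id, " time ", tp,
                         " state ", st)
    m
  }
  # column-standardized band vectors per (time, state, band); pair
  # correlations then reduce to column dot products (fast for the large
  # NR group)
  allIds <- unique(c(unlist(lapply(c("MZ", "DZ", "NR"), function(g)
    c(groups[[g]]$idA, groups[[g]]$idB))), groups$Self$id))
  std <- list()
  for (st in states) for (tp in timePoints) for (b in bands) {
    M <- vapply(allIds, function(id) mapValues(getMap(id, tp, st))[, b],
                numeric(nrow(mapValues(getMap(allIds[1], tp, st)))))
    M <- scale(M)
    std[[paste(st, tp, b, sep = "|")]] <- M / sqrt(nrow(M) - 1)
  }
  pairR <- function(st, tp, b, idA, idB) {
    M <- std[[paste(st, tp, b, sep = "|")]]
    n <- length(idA)
    out <- numeric(n)
    for (i0 in seq(1L, n, by = 50000L)) {     # chunked: NR can be huge
      i1 <- min(i0 + 49999L, n)
      out[i0:i1] <- colSums(M[, idA[i0:i1], drop = FALSE] *
                              M[, idB[i0:i1], drop = FALSE])
    }
    out
  }
  rows <- list()
  for (st in states) for (b in bands) {
    for (tp in timePoints) {
      for (g in c("MZ", "DZ", "NR")) {
        prs <- groups[[g]]
        if (is.null(prs) || !nrow(prs)) next
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, band = b, state = st, time = tp,
          pair_id = paste(prs$idA, prs$idB, sep = ":"),
          r = pairR(st, tp, b, prs$idA, prs$idB), stringsAsFactors = FALSE)
      }
    }
    if (length(timePoints) >= 2 && !is.null(groups$Self) &&
        nrow(groups$Self)) {
      ids <- groups$Self$id
      r <- vapply(ids, function(id)
        topoCorrelation(getMap(id, timePoints[1], st),
                        getMap(id, timePoints[2], st), b), numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        group = "Self", band = b, state = st, time = 0L,
        pair_id = paste(ids, ids, sep = ":"),
        r = unname(r), stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  undef <- is.na(pairs$r)
  if (any(undef)) {
    warning(sum(undef), " undefined pair correlation(s) excluded")
    pairs <- pairs[!undef, , drop = FALSE]
  }
  pairs$z <- fisherZ(pairs$r)
  key <- interaction(pairs$group, pairs$band, pairs$state, pairs$time,
                     drop = TRUE)
  summary <- do.call(rbind, lapply(split(pairs, key), function(d) {
    data.frame(group = d$group[1], band = d$band[1], state = d$state[1],
               time = d$time[1], mean_z = mean(d$z),
               mean_r = fisherZInv(mean(d$z)), n_pairs = nrow(d),
               stringsAsFactors = FALSE)
  }))
  ord <- order(summary$state, match(summary$band, bands), summary$time,
               match(summary$group, c("MZ", "DZ", "NR", "Self")))
  summary <- summary[ord, , drop = FALSE]
  rownames(summary) <- NULL
  rownames(pairs) <- NULL
  list(pairs = pairs, summary = summary)
}
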