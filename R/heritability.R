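## Falconer heritability and shared-environment estimates from group-mean
## correlations, the band x state x time estimate table, and NREM-vs-REM
## cross-state topography correlations.

#' Falconer heritability estimate
#'
#' The classical twin estimate of narrow-sense heritability from group-mean
#' correlations: \eqn{h^2 = 2 (r_{MZ} - r_{DZ})}. Estimates are returned raw;
#' values outside [0, 1] (possible by construction) are flagged by
#' \code{\link{heritabilityTable}}, and clipping is available there as an
#' explicit option.
#'
#' @param rMZ,rDZ group-mean correlations in (-1, 1).
#' @return heritability estimate (unclipped).
#' @export
falconerH2 <- function(rMZ, rDZ) {
  stopifnot(all(abs(rMZ) < 1), all(abs(rDZ) < 1))
  2 * (rMZ - rDZ)
}

#' Shared-environment estimate
#'
#' \eqn{c^2 = r_{MZ} - h^2}, algebraically equal to \eqn{2 r_{DZ} - r_{MZ}}
#' and to \eqn{r_{DZ} - h^2/2}: similarity between identical twins not due to
#' genes is attributed to environment shared within the pair.
#'
#' @param rMZ,rDZ group-mean correlations in (-1, 1).
#' @return shared-environment estimate (unclipped).
#' @export
sharedEnvC2 <- function(rMZ, rDZ) {
  stopifnot(all(abs(rMZ) < 1), all(abs(rDZ) < 1))
  rMZ - falconerH2(rMZ, rDZ)
}

#' Heritability table from a similarity summary
#'
#' For every band x state x time cell, takes the back-transformed Fisher-z
#' group means as \eqn{r_{MZ}} and \eqn{r_{DZ}} (optionally the raw z-domain
#' means) and computes Falconer \eqn{h^2} and \eqn{c^2}. Out-of-range
#' estimates are flagged, and clipped to [0, 1] only when \code{clip = TRUE}
#' (always flagged).
#'
#' @param similarity result of \code{\link{groupMeanSimilarity}} (uses its
#'   \code{summary} element).
#' @param domain \code{"r"} applies Falconer to back-transformed mean
#'   correlations (default), \code{"z"} to the z-domain means.
#' @param clip clip estimates into [0, 1]?
#' @return data.frame per (band, state, time): r_mz, r_dz, n pairs, h2, c2,
#'   and logical flags \code{h2_out_of_range}, \code{c2_out_of_range}.
#' @export
heritabilityTable <- function(similarity, domain = c("r", "z"), clip = FALSE) {
  domain <- match.arg(domain)
  s <- similarity$summary
  cells <- unique(s[s$group %in% c("MZ", "DZ"), c("band", "state", "time")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- s$band == cells$band[i] & s$state == cells$state[i] &
      s$time == cells$time[i]
    mz <- s[sel & s$group == "MZ", , drop = FALSE]
    dz <- s[sel & s$group == "DZ", , drop = FALSE]
    if (nrow(mz) != 1 || nrow(dz) != 1)
      stop("missing MZ or DZ cell for ", cells$band[i], "/", cells$state[i],
           "/time ", cells$time[i])
    rMZ <- if (domain == "r") mz$mean_r else mz$mean_z
    rDZ <- if (domain == "r") dz$mean_r else dz$mean_z
    h2 <- falconerH2(rMZ, rDZ)
    c2 <- sharedEnvC2(rMZ, rDZ)
    h2Flag <- h2 < 0 || h2 > 1
    c2Flag <- c2 < 0 || c2 > 1
    if (clip) {
      h2 <- min(max(h2, 0), 1)
      c2 <- min(max(c2, 0), 1)
    }
    data.frame(band = cells$band[i], state = cells$state[i],
               time = cells$time[i], r_mz = rMZ, r_dz = rDZ,
               n_mz_pairs = mz$n_pairs, n_dz_pairs = dz$n_pairs,
               h2 = h2, c2 = c2, h2_out_of_range = h2Flag,
               c2_out_of_range = c2Flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  bandOrder <- unique(s$band)
  out <- out[order(match(out$band, bandOrder), out$state, out$time), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-state topography correlation table
#'
#' Per band, the Pearson correlation across channels between the NREM and the
#' REM grand-average maps, with a two-sided p-value from the correlation
#' t-statistic \eqn{t = r \sqrt{(n - 2) / (1 - r^2)}} on \eqn{n - 2} degrees
#' of freedom (n = number of channels). No spatial-autocorrelation correction
#' is applied.
#'
#' @param grandNREM,grandREM grand-average \linkS4class{TopographyMap}
#'   objects for the two states, sharing channels and bands.
#' @return data.frame with columns band, r, p.
#' @export
crossStateCorrelation <- function(grandNREM, grandREM) {
  a <- mapValues(grandNREM)
  b <- mapValues(grandREM)
  if (!identical(dim(a), dim(b)) ||
      !identical(colnames(a), colnames(b)))
    stop("grand-average maps must share channels and bands")
  n <- nrow(a)
  out <- lapply(colnames(a), function(bd) {
    if (stats::sd(a[, bd]) == 0 || stats::sd(b[, bd]) == 0)
      stop("zero-variance band ", bd)
    r <- stats::cor(a[, bd], b[, bd])
    t <- r * sqrt((n - 2) / (1 - r^2))
    data.frame(band = bd, r = r,
               p = 2 * stats::pt(-abs(t), df = n - 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
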