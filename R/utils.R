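## Seed substreams, synthetic electrode layout, spatial field smoothing.

#' Derive a named substream seed
#'
#' Deterministically maps (master seed, stream name) to an integer seed so each
#' generator stage (maps, hypnogram, signal, artifacts) draws from its own
#' stream: adding draws to one stage never perturbs another.
#' @param seed integer master seed.
#' @param name character stream name.
#' @return a single integer in [0, 2^31 - 2].
#' @export
deriveSeed <- function(seed, name) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime; all arithmetic exact in doubles
  h <- 0
  for (c in utf8ToInt(name)) h <- (h * 31 + c) %% m
  as.integer((h + (as.numeric(seed) %% m) * 48271) %% m)
}

#' Evaluate with a named substream seed
#'
#' Runs \code{expr} under \code{set.seed(deriveSeed(seed, name))}, restoring
#' the caller's RNG state afterwards.
#' @param seed integer master seed.
#' @param name stream name.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
withSubstream <- function(seed, name, expr) {
  withr::with_seed(deriveSeed(seed, name), expr)
}

#' Synthetic circular electrode layout
#'
#' Places \code{n} channels evenly on the unit circle. Real electrode geometry
#' is not required for testing the pipeline; only relative distances matter for
#' nearest-neighbour interpolation.
#' @param n number of channels.
#' @return n x 2 coordinate matrix.
#' @export
circularLayout <- function(n) {
  theta <- 2 * pi * (seq_len(n) - 1) / n
  cbind(x = cos(theta), y = sin(theta))
}

#' Circular moving-average smoothing of a channel field
#'
#' Smooths channel-indexed white noise over a circular layout with an
#' unweighted moving average of half-width \code{s}, then rescales so the
#' marginal variance is preserved (white input of unit variance stays unit
#' variance).
#' @param x numeric vector (channel field).
#' @param s smoothing half-width in channels; 0 returns \code{x} unchanged.
#' @return smoothed numeric vector of the same length.
#' @export
smoothField <- function(x, s) {
  s <- as.integer(round(s))
  if (s <= 0) return(x)
  n <- length(x)
  w <- 2L * s + 1L
  if (w >= n) stop("smoothing window must be smaller than the field")
  idx <- outer(seq_len(n), -s:s, function(i, k) ((i + k - 1L) %% n) + 1L)
  sm <- rowMeans(matrix(x[idx], nrow = n))
  sm * sqrt(w)
}

## internal: key for the per-subject map registry
mapKey <- function(subjectId, timePoint, state) {
  paste(subjectId, timePoint, state, sep = "|")
}

## internal: deterministic TSV writer (fixed formatting => byte-stable output)
writeTSV <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 15, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}
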