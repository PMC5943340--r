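# ACE twin-cohort generator: closed-form oracle, sharing structure,
# compositional invariants, hypnogram chain, signal rendering.

meanPairCor <- function(gen, zyg, band = "delta", tp = 1L) {
  man <- gen$truth$manifest
  fams <- unique(man$family_id[man$zygosity == zyg])
  r <- vapply(fams, function(f) {
    ids <- man$subject_id[man$family_id == f]
    topoCorrelation(gen$maps[[mapKey(ids[1], tp, "NREM")]],
                    gen$maps[[mapKey(ids[2], tp, "NREM")]], band)
  }, numeric(1))
  mean(r)
}

test_that("expectedPairCorrelation matches its closed form and edge cases", {
  ace <- ACEParams(a2 = 0.5, c2 = 0.3, templateVar = 0, smoothness = 0)
  expect_equal(expectedPairCorrelation(ace, "MZ"), 0.8)
  expect_equal(expectedPairCorrelation(ace, "DZ"), 0.55)
  expect_equal(expectedPairCorrelation(ace, "NR"), 0)
  # dominant template drives every relationship towards 1
  aceT <- ACEParams(a2 = 0.5, c2 = 0.3, templateVar = 1e8, smoothness = 0)
  expect_gt(expectedPairCorrelation(aceT, "NR"), 0.999)
  expect_error(expectedPairCorrelation(ace, "cousin"), "unknown relationship")
})

test_that("degenerate ACE settings produce the exact limiting correlations", {
  spec <- CohortSpec(nMZPairs = 60L, nDZPairs = 60L, nTimepoints = 1L,
                     bands = "delta", seed = 2L)
  # pure unique environment: no shared signal, correlations near 0
  aceE <- ACEParams(a2 = 0, c2 = 0, e2 = 1, templateVar = 0, smoothness = 0)
  genE <- generateTwinMaps(aceE, spec, mode = "linear")
  expect_lt(abs(meanPairCor(genE, "MZ")), 0.08)
  # pure additive genetics: MZ co-twin maps are identical
  aceA <- ACEParams(a2 = 1, c2 = 0, e2 = 0, templateVar = 0, smoothness = 0)
  genA <- generateTwinMaps(aceA, spec, mode = "linear")
  ids <- genA$truth$manifest$subject_id[1:2]
  expect_equal(mapValues(genA$maps[[mapKey(ids[1], 1, "NREM")]]),
               mapValues(genA$maps[[mapKey(ids[2], 1, "NREM")]]))
  expect_equal(meanPairCor(genA, "MZ"), 1)
})

test_that("Monte-Carlo pair correlations match the closed form within 3 SE", {
  ace <- ACEParams(a2 = 0.5, c2 = 0.3, templateVar = 0, nChannels = 58L,
                   smoothness = 0)
  spec <- CohortSpec(nMZPairs = 2000L, nDZPairs = 0L, nTimepoints = 1L,
                     bands = "delta", seed = 9L)
  gen <- generateTwinMaps(ace, spec, mode = "linear")
  man <- gen$truth$manifest
  r <- vapply(unique(man$family_id), function(f) {
    ids <- man$subject_id[man$family_id == f]
    topoCorrelation(gen$maps[[mapKey(ids[1], 1, "NREM")]],
                    gen$maps[[mapKey(ids[2], 1, "NREM")]], "delta")
  }, numeric(1))
  se <- sd(r) / sqrt(length(r))
  expect_lt(abs(mean(r) - 0.8), 3 * se)
})

test_that("MZ >= DZ >= NR ordering holds whenever genes contribute", {
  ace <- ACEParams(a2 = 0.5, c2 = 0.2, templateVar = 0, smoothness = 0)
  spec <- CohortSpec(nMZPairs = 500L, nDZPairs = 500L, nTimepoints = 1L,
                     bands = "delta", seed = 4L)
  gen <- generateTwinMaps(ace, spec, mode = "linear")
  man <- gen$truth$manifest
  rMZ <- meanPairCor(gen, "MZ")
  rDZ <- meanPairCor(gen, "DZ")
  # NR estimate from a subsample of cross-family pairs
  nr <- vapply(1:500, function(i)
    topoCorrelation(gen$maps[[mapKey(man$subject_id[2 * i - 1], 1, "NREM")]],
                    gen$maps[[mapKey(man$subject_id[2 * i + 2], 1, "NREM")]],
                    "delta"), numeric(1))
  expect_gt(rMZ, rDZ)
  expect_gt(rDZ, mean(nr))
})

test_that("compositional maps are positive and sum to one per band", {
  ace <- ACEParams(a2 = 0.4, c2 = 0.3, templateVar = 0.5, smoothness = 2)
  spec <- CohortSpec(nMZPairs = 3L, nDZPairs = 3L, seed = 6L)
  gen <- generateTwinMaps(ace, spec, mode = "compositional")
  for (m in gen$maps) {
    v <- mapValues(m)
    expect_true(all(v > 0))
    expect_lt(max(abs(colSums(v) - 1)), 1e-12)
    expect_true(validObject(m))
  }
})

test_that("identical seeds reproduce the cohort exactly; retest correlates", {
  ace <- ACEParams(a2 = 0.4, c2 = 0.3, templateVar = 0, smoothness = 0)
  spec <- CohortSpec(nMZPairs = 300L, nDZPairs = 0L, nTimepoints = 2L,
                     retestStability = 0.85, bands = "delta", seed = 13L)
  g1 <- generateTwinMaps(ace, spec, mode = "linear")
  g2 <- generateTwinMaps(ace, spec, mode = "linear")
  expect_identical(lapply(g1$maps, mapValues), lapply(g2$maps, mapValues))
  # self retest correlation ~ a2 + c2 + e2 * stability = 0.955
  man <- g1$truth$manifest
  rSelf <- mean(vapply(man$subject_id, function(id)
    topoCorrelation(g1$maps[[mapKey(id, 1, "NREM")]],
                    g1$maps[[mapKey(id, 2, "NREM")]], "delta"), numeric(1)))
  expect_lt(abs(rSelf - (0.4 + 0.3 + 0.3 * 0.85)), 0.03)
})

test_that("hypnogram chain honors absorbing states, seeds and stationarity", {
  st <- c("Wake", "S1", "S2", "SWS", "REM")
  absorb <- matrix(0, 5, 5, dimnames = list(st, st))
  absorb[, "REM"] <- 1
  spec <- SignalSpec(samplingRate = 100, nEpochs = 50L,
                     stageTransition = absorb)
  h <- generateHypnogram(spec, seed = 1L)
  expect_true(all(stages(h)[-1] == "REM"))
  # determinism
  spec2 <- SignalSpec(samplingRate = 100, nEpochs = 200L)
  expect_identical(stages(generateHypnogram(spec2, seed = 7L)),
                   stages(generateHypnogram(spec2, seed = 7L)))
  # long-run REM fraction matches the stationary distribution
  spec3 <- SignalSpec(samplingRate = 100, nEpochs = 10000L)
  pi0 <- stationaryDistribution(defaultStageTransition())
  h3 <- generateHypnogram(spec3, seed = 3L)
  expect_lt(abs(mean(stages(h3) == "REM") - pi0[5]), 0.03)
  bad <- defaultStageTransition(); bad[1, 1] <- 0.9
  expect_error(SignalSpec(samplingRate = 100, stageTransition = bad),
               "sum to 1")
})

test_that("signal synthesis respects artifact logging and map gains", {
  # no artifacts requested -> empty log
  ace <- ACEParams(a2 = 0.6, c2 = 0.3, templateVar = 0.3, nChannels = 8L,
                   smoothness = 0)
  cs <- CohortSpec(nMZPairs = 1L, nDZPairs = 0L, nTimepoints = 1L, seed = 2L)
  gen <- generateTwinMaps(ace, cs, mode = "compositional")
  ss0 <- SignalSpec(samplingRate = 100, nEpochs = 10L, artifactRate = 0)
  out0 <- generateSubjectRecording(gen$maps[[1]],
                                   altHypnogram(10), ss0, seed = 1L)
  expect_identical(nrow(out0$artifacts), 0L)
  # uniform map, one effective band -> near-uniform downstream topography
  uni <- TopographyMap(matrix(1 / 8, 8, 8,
                              dimnames = list(NULL,
                                              defaultBandScheme()$label)))
  outU <- generateSubjectRecording(uni, altHypnogram(40),
                                   SignalSpec(samplingRate = 100,
                                              nEpochs = 40L,
                                              backgroundScale = 0),
                                   seed = 4L)
  procU <- processSubject(outU$recording, altHypnogram(40))
  smU <- subjectMaps(procU, c(NREM = 20L, REM = 20L))
  vals <- mapValues(smU$NREM$map)[, "delta"]
  expect_lt(max(abs(vals - 1 / 8)) / (1 / 8), 0.10)
})

test_that("a 3:1 delta gain ratio survives the full pipeline within 10%", {
  # two channel groups with known 3:1 delta power ratio; enough channels
  # that average referencing (which mixes ~2/n of the total back into each
  # channel) does not materially compress the ratio
  nCh <- 32L
  v <- matrix(1 / nCh, nCh, 8,
              dimnames = list(NULL, defaultBandScheme()$label))
  delta <- c(rep(3, nCh / 2), rep(1, nCh / 2)); delta <- delta / sum(delta)
  v[, "delta"] <- delta
  map <- TopographyMap(v)
  hyp <- altHypnogram(60)
  out <- generateSubjectRecording(map, hyp,
                                  SignalSpec(samplingRate = 100,
                                             nEpochs = 60L),
                                  seed = 8L)
  proc <- processSubject(out$recording, hyp)
  sm <- subjectMaps(proc, c(NREM = 30L, REM = 30L))
  rec <- mapValues(sm$NREM$map)[, "delta"]
  ratio <- mean(rec[1:16]) / mean(rec[17:32])
  expect_lt(abs(ratio - 3) / 3, 0.10)
})

test_that("substream seeds isolate generator stages", {
  expect_identical(deriveSeed(7L, "maps"), deriveSeed(7L, "maps"))
  expect_false(deriveSeed(7L, "maps") == deriveSeed(7L, "signal"))
  expect_false(deriveSeed(7L, "maps") == deriveSeed(8L, "maps"))
  a <- withSubstream(1L, "x", rnorm(3))
  b <- withSubstream(1L, "x", rnorm(3))
  expect_identical(a, b)
})
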