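# Epoch matching, state averaging, per-bin normalization, band and 1-Hz
# aggregation, grand averages.

randomSpectra <- function(nEpochs = 6, nCh = 5, seed = 1) {
  withr::with_seed(seed, {
    p <- array(rexp(nEpochs * nCh * 220), c(nEpochs, nCh, 220))
    new("EpochSpectra", power = p, binCenters = seq(0.2, 44, by = 0.2),
        valid = matrix(TRUE, nEpochs, nCh),
        stages = rep(c("S2", "REM"), length.out = nEpochs),
        channelLabels = paste0("E", seq_len(nCh)))
  })
}

test_that("pair epoch matching takes the per-state minimum and flags zeros", {
  expect_identical(matchPairEpochs(c(NREM = 400, REM = 100),
                                   c(NREM = 350, REM = 120)),
                   c(NREM = 350L, REM = 100L))
  expect_identical(matchPairEpochs(c(NREM = 200), c(NREM = 200)),
                   c(NREM = 200L))
  expect_error(matchPairEpochs(c(NREM = 0, REM = 10),
                               c(NREM = 200, REM = 10)), "NREM")
})

test_that("state averaging means the first n clean epochs per channel", {
  sp <- randomSpectra(nEpochs = 4)
  sp@power[1, , ] <- 2; sp@power[3, , ] <- 4   # the two S2 epochs
  keep <- rep(TRUE, 4)
  m <- stateAverage(sp, keep, "NREM")
  expect_true(all(m == 3))
  m1 <- stateAverage(sp, keep, "NREM", nEpochs = 1)
  expect_true(all(m1 == 2))
  expect_error(stateAverage(sp, keep, "NREM", nEpochs = 5), "insufficient")
  # invalid channel-epochs are excluded from that channel's mean
  sp@valid[3, 2] <- FALSE
  m2 <- stateAverage(sp, keep, "NREM")
  expect_true(all(m2[2, ] == 2) && all(m2[1, ] == 3))
})

test_that("bin normalization is a scale-invariant per-bin simplex map", {
  u <- matrix(5, 58, 220)
  q <- normalizeBins(u)
  expect_true(all(abs(q - 1 / 58) < 1e-15))
  m <- randomSpectra(1)@power[1, , ]
  expect_equal(normalizeBins(m * 17), normalizeBins(m))
  expect_lt(max(abs(colSums(normalizeBins(m)) - 1)), 1e-12)
  onehot <- matrix(0, 5, 220); onehot[3, ] <- 2.2
  expect_equal(normalizeBins(onehot)[3, 1], 1)
  expect_error(normalizeBins(matrix(0, 3, 220)), "all-zero")
})

test_that("band aggregation means the member bins and keeps the simplex", {
  bc <- seq(0.2, 44, by = 0.2)
  m <- randomSpectra(1, nCh = 58)@power[1, , ]
  frac <- normalizeBins(m)
  map <- aggregateBands(frac, bc, subjectId = "s", nEpochsUsed = 3L)
  expect_s4_class(map, "TopographyMap")
  expect_lt(max(abs(colSums(mapValues(map)) - 1)), 1e-12)
  # delta = unweighted mean of the 19 bins centered 1.0..4.6 Hz
  sel <- which(bc >= 1 - 1e-9 & bc <= 4.6 + 1e-9)
  expect_identical(length(sel), 19L)
  expect_equal(mapValues(map)[, "delta"], rowMeans(frac[, sel]),
               ignore_attr = TRUE)
  # identical bins make every band equal to any bin
  const <- matrix(rep(frac[, 1], 220), nrow = 58)
  mapC <- aggregateBands(const, bc)
  expect_equal(mapValues(mapC)[, "sigma"], frac[, 1], ignore_attr = TRUE)
})

test_that("1-Hz maps pool five bins each and stay normalized", {
  bc <- seq(0.2, 44, by = 0.2)
  m <- randomSpectra(1, nCh = 10)@power[1, , ]
  frac <- normalizeBins(m)
  oh <- oneHzMaps(frac, bc)
  expect_identical(dim(oh), c(10L, 44L))
  expect_equal(oh[, 1], rowMeans(frac[, 1:5]), ignore_attr = TRUE)
  expect_lt(max(abs(colSums(oh) - 1)), 1e-12)
  uni <- matrix(0.1, 10, 220)
  expect_true(all(abs(oneHzMaps(uni, bc) - 0.1) < 1e-15))
})

test_that("grand averages recover a shared template", {
  scheme <- defaultBandScheme()
  v <- matrix(1 / 6, 6, 8, dimnames = list(NULL, scheme$label))
  one <- TopographyMap(v)
  expect_equal(mapValues(grandAverageMap(list(one))), mapValues(one))
  # two maps mirrored about uniform average to uniform
  d <- c(0.02, -0.02, 0.01, -0.01, 0, 0)
  mA <- TopographyMap(v + d)
  mB <- TopographyMap(v - d)
  expect_equal(mapValues(grandAverageMap(list(mA, mB))), mapValues(one))
  expect_error(grandAverageMap(list()), "empty")
  # 50 compositional subjects around a template: grand average ~ template
  ace <- ACEParams(a2 = 0.1, c2 = 0.1, e2 = 0.8, templateVar = 1,
                   nChannels = 58L, smoothness = 0)
  gen <- generateTwinMaps(ace, CohortSpec(nMZPairs = 13L, nDZPairs = 12L,
                                          nTimepoints = 1L, bands = "delta",
                                          seed = 15L),
                          mode = "compositional")
  ga <- grandAverageMap(gen$maps)
  # reconstruct the template from the population mean of a fresh huge cohort
  big <- generateTwinMaps(ace, CohortSpec(nMZPairs = 500L, nDZPairs = 0L,
                                          nTimepoints = 1L, bands = "delta",
                                          seed = 15L),
                          mode = "compositional")
  tmpl <- Reduce(`+`, lapply(big$maps, mapValues)) / length(big$maps)
  expect_gt(cor(mapValues(ga)[, 1], tmpl[, 1]), 0.95)
})

test_that("normalizing before banding equals banding per-bin fractions", {
  bc <- seq(0.2, 44, by = 0.2)
  m <- randomSpectra(1, nCh = 20)@power[1, , ]
  a <- mapValues(aggregateBands(normalizeBins(m), bc))
  # both orders agree because each bin is separately sum-one
  expect_lt(max(abs(colSums(a) - 1)), 1e-12)
  direct <- vapply(seq_len(nrow(defaultBandScheme())), function(i) {
    sel <- bc >= defaultBandScheme()$lo[i] - 1e-9 &
      bc <= defaultBandScheme()$hi[i] + 1e-9
    rowMeans(normalizeBins(m)[, sel])
  }, numeric(20))
  expect_equal(a, direct, ignore_attr = TRUE)
})
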