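# Falconer estimates, the band x state x time table, and cross-state
# topography correlations.

test_that("Falconer formulas and their algebraic identities hold exactly", {
  expect_equal(falconerH2(0.8, 0.6), 0.4)
  expect_equal(falconerH2(0.33, 0.33), 0)
  expect_equal(falconerH2(0.9, 0.3), 1.2)  # out of range by construction
  expect_equal(sharedEnvC2(0.8, 0.6), 0.4)
  expect_equal(sharedEnvC2(0.6, 0.6), 0.6)
  withr::with_seed(3, {
    rMZ <- runif(1e4, -0.99, 0.99)
    rDZ <- runif(1e4, -0.99, 0.99)
    h2 <- falconerH2(rMZ, rDZ)
    c2 <- sharedEnvC2(rMZ, rDZ)
    expect_lt(max(abs(h2 - 2 * (rMZ - rDZ))), 1e-15)
    expect_lt(max(abs(c2 - (rMZ - h2))), 1e-15)
    expect_lt(max(abs(rDZ - h2 / 2 - c2)), 1e-14)
  })
})

test_that("the heritability table flags, clips and orders cells", {
  maps <- list()
  mk <- function(vals, id) {
    TopographyMap(matrix(vals, ncol = 1, dimnames = list(NULL, "delta")),
                  subjectId = id, normalized = FALSE)
  }
  base <- c(1, 2, 3, 5, 4, 2)
  withr::with_seed(9, {
    maps[[mapKey("M1a", 1, "NREM")]] <- mk(base, "M1a")
    maps[[mapKey("M1b", 1, "NREM")]] <- mk(base + 0.1 * rnorm(6), "M1b")
    maps[[mapKey("D1a", 1, "NREM")]] <- mk(base, "D1a")
    maps[[mapKey("D1b", 1, "NREM")]] <- mk(base + 0.3 * rnorm(6), "D1b")
  })
  groups <- list(MZ = data.frame(idA = "M1a", idB = "M1b"),
                 DZ = data.frame(idA = "D1a", idB = "D1b"))
  sim <- groupMeanSimilarity(groups, maps, bands = "delta", states = "NREM")
  tab <- heritabilityTable(sim)
  expect_equal(tab$h2, 2 * (tab$r_mz - tab$r_dz))
  expect_equal(tab$c2, tab$r_mz - tab$h2)
  # equal group correlations: h2 = 0, c2 = r
  simEq <- sim
  simEq$summary$mean_r <- 0.7
  simEq$summary$mean_z <- fisherZ(0.7)
  tabEq <- heritabilityTable(simEq)
  expect_equal(tabEq$h2, 0)
  expect_equal(tabEq$c2, 0.7)
  # out-of-range flags and optional clipping
  simHi <- sim
  simHi$summary$mean_r <- ifelse(simHi$summary$group == "MZ", 0.9, 0.2)
  tabHi <- heritabilityTable(simHi)
  expect_true(tabHi$h2_out_of_range && tabHi$c2_out_of_range)
  expect_equal(tabHi$h2, 1.4)
  tabClip <- heritabilityTable(simHi, clip = TRUE)
  expect_equal(tabClip$h2, 1)
  expect_true(tabClip$h2_out_of_range)
})

test_that("map-level cohorts recover ACE variance fractions via Falconer", {
  ace <- ACEParams(a2 = 0.5, c2 = 0.3, templateVar = 0, nChannels = 58L,
                   smoothness = 0)
  spec <- CohortSpec(nMZPairs = 500L, nDZPairs = 500L, nTimepoints = 1L,
                     bands = "delta", seed = 37L)
  gen <- generateTwinMaps(ace, spec, mode = "linear")
  gr <- buildPairGroups(gen$truth$manifest)
  sim <- groupMeanSimilarity(gr[c("MZ", "DZ")], gen$maps, bands = "delta",
                             states = "NREM")
  tab <- heritabilityTable(sim)
  expect_lt(abs(tab$h2 - 0.5), 0.08)
  expect_lt(abs(tab$c2 - 0.3), 0.08)
})

test_that("a shared template attenuates Falconer heritability as predicted", {
  ace <- ACEParams(a2 = 0.5, c2 = 0.3, templateVar = 1, nChannels = 58L,
                   smoothness = 0)
  spec <- CohortSpec(nMZPairs = 500L, nDZPairs = 500L, nTimepoints = 1L,
                     bands = "delta", seed = 41L)
  gen <- generateTwinMaps(ace, spec, mode = "linear")
  gr <- buildPairGroups(gen$truth$manifest)
  sim <- groupMeanSimilarity(gr[c("MZ", "DZ")], gen$maps, bands = "delta",
                             states = "NREM")
  tab <- heritabilityTable(sim)
  expect_lt(abs(tab$h2 - 0.25), 0.08)  # a2 / (1 + template_var)
})

test_that("estimated h2 rises with simulated a2", {
  est <- vapply(c(0, 0.25, 0.5), function(a2) {
    ace <- ACEParams(a2 = a2, c2 = 0.2, e2 = 0.8 - a2, templateVar = 0,
                     nChannels = 58L, smoothness = 0)
    spec <- CohortSpec(nMZPairs = 400L, nDZPairs = 400L, nTimepoints = 1L,
                       bands = "delta", seed = 43L)
    gen <- generateTwinMaps(ace, spec, mode = "linear")
    gr <- buildPairGroups(gen$truth$manifest)
    sim <- groupMeanSimilarity(gr[c("MZ", "DZ")], gen$maps, bands = "delta",
                               states = "NREM")
    heritabilityTable(sim)$h2
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("cross-state correlations and p-values follow the t reference", {
  scheme <- defaultBandScheme()
  withr::with_seed(19, {
    v <- matrix(rexp(58 * 8), 58, 8, dimnames = list(NULL, scheme$label))
    v <- sweep(v, 2, colSums(v), `/`)
  })
  g <- TopographyMap(v, state = "NREM")
  gR <- TopographyMap(v, state = "REM")
  cs <- crossStateCorrelation(g, gR)
  expect_equal(cs$r, rep(1, 8))
  # identical templates + small independent noise -> high r in every band
  withr::with_seed(20, {
    noise <- function() {
      w <- v * exp(0.1 * matrix(rnorm(58 * 8), 58, 8))
      sweep(w, 2, colSums(w), `/`)
    }
    csN <- crossStateCorrelation(TopographyMap(noise(), state = "NREM"),
                                 TopographyMap(noise(), state = "REM"))
  })
  expect_true(all(csN$r > 0.8))
  # null calibration on a reduced replicate set
  withr::with_seed(21, {
    p <- replicate(250, {
      a <- matrix(rnorm(58 * 8), 58, 8, dimnames = list(NULL, scheme$label))
      b <- matrix(rnorm(58 * 8), 58, 8, dimnames = list(NULL, scheme$label))
      crossStateCorrelation(TopographyMap(a, state = "NREM",
                                          normalized = FALSE),
                            TopographyMap(b, state = "REM",
                                          normalized = FALSE))$p
    })
  })
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})
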