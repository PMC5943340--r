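# Comparison groups, topographic correlations, Fisher-z averaging.

bandMap <- function(vals, subjectId = "s", timePoint = 1L) {
  TopographyMap(matrix(vals, ncol = 1, dimnames = list(NULL, "delta")),
                subjectId = subjectId, timePoint = timePoint,
                normalized = FALSE)
}

test_that("Fisher z transform round-trips and matches arctanh", {
  expect_identical(fisherZ(0), 0)
  expect_equal(fisherZ(0.5), 0.5493061, tolerance = 1e-6)
  expect_equal(fisherZInv(fisherZ(0.8)), 0.8, tolerance = 1e-12)
  expect_error(fisherZ(1), "< 1")
})

test_that("topographic correlation follows the Pearson contracts", {
  a <- bandMap(c(0.1, 0.2, 0.3, 0.4))
  expect_equal(topoCorrelation(a, a, "delta"), 1)
  rev <- bandMap(c(0.4, 0.3, 0.2, 0.1))
  expect_equal(topoCorrelation(a, rev, "delta"), -1)
  anti <- bandMap(2 * 0.25 - c(0.1, 0.2, 0.3, 0.4))
  expect_equal(topoCorrelation(a, anti, "delta"), -1)
  flat <- bandMap(rep(0.25, 4))
  expect_warning(r <- topoCorrelation(a, flat, "delta"), "zero-variance")
  expect_true(is.na(r))
  # symmetry and invariance under a common affine transform
  b <- bandMap(c(0.3, 0.1, 0.25, 0.35))
  expect_equal(topoCorrelation(a, b, "delta"), topoCorrelation(b, a, "delta"))
  a2 <- bandMap(3 * c(0.1, 0.2, 0.3, 0.4) + 1)
  b2 <- bandMap(3 * c(0.3, 0.1, 0.25, 0.35) + 1)
  expect_equal(topoCorrelation(a2, b2, "delta"),
               topoCorrelation(a, b, "delta"))
})

test_that("pair groups enumerate co-twins, cross-family and self pairs", {
  man <- data.frame(
    subject_id = paste0(rep(sprintf("F%02d", 1:25), each = 2), c("a", "b")),
    family_id = rep(sprintf("F%02d", 1:25), each = 2),
    zygosity = rep(c(rep("MZ", 14), rep("DZ", 11)), each = 2))
  g <- buildPairGroups(man)
  expect_identical(nrow(g$MZ), 14L)
  expect_identical(nrow(g$DZ), 11L)
  expect_identical(nrow(g$NR), as.integer(choose(50, 2) - 25))
  expect_identical(nrow(g$Self), 50L)
  # subject exclusion shrinks the NR pool combinatorially: 5 subjects gone
  # leaves 45, of whom 22 intact families
  g45 <- buildPairGroups(man, excludeSubjects = man$subject_id[1:5])
  expect_identical(nrow(g45$NR), as.integer(choose(45, 2) - 22))
  expect_identical(nrow(g45$MZ) + nrow(g45$DZ), 22L)
  # 2 families -> the 4 cross-family pairs
  g2 <- buildPairGroups(man[1:4, ])
  expect_identical(nrow(g2$NR), 4L)
  expect_error(buildPairGroups(man[1:3, ]), "exactly 2")
})

test_that("group means average in z and recover generator correlations", {
  maps <- list()
  maps[[mapKey("A1", 1, "NREM")]] <- bandMap(c(1, 2, 3, 5), "A1")
  maps[[mapKey("A2", 1, "NREM")]] <- bandMap(c(1, 2, 4, 4), "A2")
  groups <- list(MZ = data.frame(idA = "A1", idB = "A2"))
  s1 <- groupMeanSimilarity(groups, maps, bands = "delta", states = "NREM")
  expect_equal(s1$summary$mean_r,
               topoCorrelation(maps[[1]], maps[[2]], "delta"))
  # equal r values average to themselves through the z domain
  maps[[mapKey("B1", 1, "NREM")]] <- bandMap(c(1, 2, 3, 5), "B1")
  maps[[mapKey("B2", 1, "NREM")]] <- bandMap(c(1, 2, 4, 4), "B2")
  g2 <- list(MZ = data.frame(idA = c("A1", "B1"), idB = c("A2", "B2")))
  s2 <- groupMeanSimilarity(g2, maps, bands = "delta", states = "NREM")
  expect_equal(s2$summary$mean_r, s1$summary$mean_r)
  expect_identical(s2$summary$n_pairs, 2L)
  # synthetic linear cohort: MZ and DZ means near the closed form
  ace <- ACEParams(a2 = 0.5, c2 = 0.3, templateVar = 0, nChannels = 58L,
                   smoothness = 0)
  spec <- CohortSpec(nMZPairs = 500L, nDZPairs = 500L, nTimepoints = 1L,
                     bands = "delta", seed = 23L)
  gen <- generateTwinMaps(ace, spec, mode = "linear")
  gr <- buildPairGroups(gen$truth$manifest)
  sim <- groupMeanSimilarity(gr[c("MZ", "DZ")], gen$maps, bands = "delta",
                             states = "NREM")
  rMZ <- sim$summary$mean_r[sim$summary$group == "MZ"]
  rDZ <- sim$summary$mean_r[sim$summary$group == "DZ"]
  expect_lt(abs(rMZ - 0.8), 0.03)
  expect_lt(abs(rDZ - 0.55), 0.03)
})

test_that("z-domain averaging exceeds the naive mean for positive r", {
  withr::with_seed(11, {
    for (i in 1:20) {
      r <- runif(10, 0.1, 0.9)
      expect_gte(fisherZInv(mean(fisherZ(r))), mean(r))
    }
  })
})

test_that("similarity ordering Self >= MZ >= DZ >= NR emerges from the ACE
           structure", {
  ace <- ACEParams(a2 = 0.4, c2 = 0.3, templateVar = 0, nChannels = 58L,
                   smoothness = 0)
  spec <- CohortSpec(nMZPairs = 100L, nDZPairs = 100L, nTimepoints = 2L,
                     retestStability = 0.9, bands = "delta", seed = 29L)
  gen <- generateTwinMaps(ace, spec, mode = "linear")
  gr <- buildPairGroups(gen$truth$manifest)
  gr$NR <- gr$NR[seq(1, nrow(gr$NR), by = 40), ]  # thin the NR pool
  sim <- groupMeanSimilarity(gr, gen$maps, bands = "delta", states = "NREM",
                             timePoints = 1:2)
  s <- sim$summary[sim$summary$time %in% c(0L, 1L), ]
  m <- setNames(s$mean_r, s$group)
  expect_gte(m[["Self"]], m[["MZ"]])
  expect_gte(m[["MZ"]], m[["DZ"]])
  expect_gte(m[["DZ"]], m[["NR"]])
})
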