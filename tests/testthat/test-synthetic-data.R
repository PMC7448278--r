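test_that("sequence mutation respects the rate at the boundaries", {
  set.seed(1)
  s <- randomProtein(200)
  expect_equal(mutateSequence(s, 0), s)
  m1 <- mutateSequence(s, 1)
  expect_equal(nchar(m1), nchar(s))
  expect_true(all(strsplit(m1, "")[[1]] != strsplit(s, "")[[1]]))
  expect_error(mutateSequence(s, 1.5), "rate")
})

test_that("mutation rate yields the binomially expected identity", {
  set.seed(2)
  s <- randomProtein(500)
  ident <- replicate(200, {
    m <- mutateSequence(s, 0.2)
    mean(strsplit(m, "")[[1]] == strsplit(s, "")[[1]])
  })
  expect_equal(mean(ident), 0.8, tolerance = 0.02)
})

test_that("family simulation produces the requested bookkeeping, deterministically", {
  cfg <- SimulationConfig(nFamilies = 2, familySizes = c(3, 3),
                          nSingletons = 2, seed = 7,
                          seqLengthRange = c(60L, 90L))
  sim <- simulateFamilies(cfg)
  expect_equal(length(sim$clusters), 8L)
  part <- sim$truth$partition
  expect_equal(sort(names(part)), sort(clusterIds(sim$clusters)))
  expect_equal(as.vector(table(part, useNA = "no")), c(3L, 3L))
  expect_equal(sum(is.na(part)), 2L)

  # byte-identical determinism under the same seed
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  writeClusterManifest(sim$clusters, p1)
  writeClusterManifest(simulateFamilies(cfg)$clusters, p2)
  expect_identical(readLines(p1), readLines(p2))

  expect_error(simulateFamilies(
    SimulationConfig(nFamilies = 5, familySizes = 10, nSingletons = 5,
                     domainPool = paste0("PF", 1:20), seed = 1)),
    "pool too small")
  expect_error(SimulationConfig(withinIdentity = 0.5, betweenIdentity = 0.6,
                                seed = 1), "betweenIdentity")
  expect_error(SimulationConfig(nFamilies = 1), "seed")
})

test_that("realized within-family identity and jaccard track the targets", {
  cfg <- SimulationConfig(nFamilies = 2, familySizes = 4, nSingletons = 1,
                          withinIdentity = 0.9, betweenIdentity = 0.2,
                          seed = 19, seqLengthRange = c(250L, 350L))
  sim <- simulateFamilies(cfg)
  sm <- similarityMatrix(sim$clusters)
  idm <- identityMatrix(sm)
  part <- sim$truth$partition[clusterIds(sim$clusters)]
  within <- c(); between <- c(); withinJ <- c(); betweenJ <- c()
  jm <- jaccardMatrix(sm)
  n <- length(part)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (!is.na(part[i]) && !is.na(part[j]) && part[i] == part[j]) {
      within <- c(within, idm[i, j]); withinJ <- c(withinJ, jm[i, j])
    } else {
      between <- c(between, idm[i, j]); betweenJ <- c(betweenJ, jm[i, j])
    }
  }
  expect_gte(stats::median(within), 0.85)
  expect_lte(stats::median(within), 0.95)
  expect_lt(max(between), 0.4)
  expect_gte(stats::median(withinJ), 0.7)
  expect_lt(max(betweenJ), 0.25)
})

test_that("hit-table generation plants exact pass/fail ground truth", {
  ht <- simulateHitTable(7, 13, path = withr::local_tempfile(), seed = 3)
  expect_equal(sum(ht$truth$keep), 7L)
  expect_equal(nrow(ht$truth), 20L)
  hits <- readDomtblout(ht$path)
  expect_equal(nrow(hits), 20L)  # no silent row loss
  kept <- filterHits(hits)
  expect_setequal(kept$protein_id, ht$truth$protein_id[ht$truth$keep])

  # same seed, same bytes
  pA <- withr::local_tempfile(); pB <- withr::local_tempfile()
  simulateHitTable(5, 5, path = pA, seed = 99)
  simulateHitTable(5, 5, path = pB, seed = 99)
  expect_identical(readLines(pA), readLines(pB))
})
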