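mkHit <- function(protein, genome = "g1", acc = "PF01231", len = 400L,
                  evalue = 1e-35) {
  data.frame(protein_id = protein, genome_id = genome,
             model_accession = acc, model_name = "IDO",
             full_seq_evalue = evalue, bitscore = 300,
             subject_length = as.integer(len), env_start = 5L,
             env_end = as.integer(len) - 4L, stringsAsFactors = FALSE)
}

test_that("hit filtering applies the PF01231/350/1e-30 policy with inclusive bounds", {
  hits <- rbind(mkHit("p1", len = 412, evalue = 3e-33),
                mkHit("p2", len = 520, evalue = 2e-28),
                mkHit("p3", len = 341, evalue = 1e-45))
  kept <- filterHits(hits)
  expect_equal(kept$protein_id, "p1")

  boundary <- mkHit("pb", len = 350, evalue = 1e-30)
  expect_equal(nrow(filterHits(boundary)), 1L)
  expect_equal(nrow(filterHits(mkHit("pb", len = 349, evalue = 1e-30))), 0L)
  expect_equal(nrow(filterHits(mkHit("pb", len = 350,
                                     evalue = 1.0000001e-30))), 0L)
  expect_equal(nrow(filterHits(mkHit("pb", acc = "PF00001"))), 0L)
})

test_that("filtering keeps exactly the planted true rows of generated tables", {
  ht <- simulateHitTable(7, 13, path = withr::local_tempfile(), seed = 31)
  hits <- readDomtblout(ht$path)
  expect_equal(nrow(hits), 20L)
  kept <- filterHits(hits)
  expect_setequal(kept$protein_id, ht$truth$protein_id[ht$truth$keep])
  expect_equal(nrow(kept), 7L)

  ht0 <- simulateHitTable(0, 5, path = withr::local_tempfile(), seed = 32)
  expect_equal(nrow(filterHits(readDomtblout(ht0$path))), 0L)
})

test_that("filtering is idempotent, monotone in policy, and loses nothing silently", {
  ht <- simulateHitTable(10, 10, path = withr::local_tempfile(), seed = 33)
  hits <- readDomtblout(ht$path)
  kept <- filterHits(hits)
  expect_equal(filterHits(kept), kept)
  # kept + dropped = input
  pol <- FilterPolicy()
  dropped <- hits[!hits$protein_id %in% kept$protein_id, ]
  expect_equal(nrow(kept) + nrow(dropped), nrow(hits))
  # loosening any threshold never removes a kept hit
  looser <- list(FilterPolicy(minSubjectLength = 200L),
                 FilterPolicy(maxEvalue = 1e-20))
  for (p in looser)
    expect_true(all(kept$protein_id %in% filterHits(hits, p)$protein_id))
})

test_that("per-genome counts deduplicate multi-domain proteins", {
  hits <- rbind(mkHit("p1", "gA"), mkHit("p2", "gA"), mkHit("p3", "gA"))
  expect_equal(countPerGenome(hits), c(gA = 3L))
  # two domain rows on the same protein count once
  hits <- rbind(mkHit("p1", "gA"), mkHit("p1", "gA"))
  expect_equal(countPerGenome(hits), c(gA = 1L))
  expect_length(countPerGenome(mkHit("p1")[0, ]), 0)

  # planted copy numbers across genomes round-trip through file + filter
  ht <- simulateHitTable(9, 6, path = withr::local_tempfile(), seed = 34,
                         nGenomes = 3L)
  kept <- filterHits(readDomtblout(ht$path))
  counts <- countPerGenome(kept)
  expect_equal(sum(counts), 9L)
  expect_equal(unname(counts[paste0("genome", 1:3)]), c(3L, 3L, 3L))
})

test_that("clusters containing target proteins are flagged exactly", {
  sim <- simulateFamilies(SimulationConfig(nFamilies = 4, familySizes = 4,
                                           nSingletons = 4, seed = 12,
                                           seqLengthRange = c(60L, 80L)))
  cs <- sim$clusters
  expect_equal(length(cs), 20L)
  ids <- clusterIds(cs)
  planted <- ids[c(2, 7, 11, 19)]
  targets <- vapply(planted, function(id) names(cs[[id]]@proteins)[1],
                    character(1))
  expect_setequal(flagTargetClusters(cs, targets), planted)
  expect_equal(flagTargetClusters(cs, "no_such_protein"), character(0))
})
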