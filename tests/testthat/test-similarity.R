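test_that("global alignment recovers inputs and handles gaps and errors", {
  aln <- globalAlign("ACDEFG", "ACDEFG")
  expect_equal(aln$alignedA, "ACDEFG")
  expect_equal(aln$alignedB, "ACDEFG")

  aln <- globalAlign("ACDEFG", "ACDEYG")
  expect_equal(nchar(aln$alignedA), 6L)
  expect_equal(sum(strsplit(aln$alignedA, "")[[1]] !=
                     strsplit(aln$alignedB, "")[[1]]), 1L)

  aln <- globalAlign("ACD", "A")
  expect_equal(gsub("-", "", aln$alignedA), "ACD")
  expect_equal(gsub("-", "", aln$alignedB), "A")
  expect_equal(sum(strsplit(aln$alignedB, "")[[1]] == "-"), 2L)

  expect_error(globalAlign("", "ACD"), "non-empty")
  expect_error(globalAlign("AC1D", "ACD"), "invalid amino-acid")
})

test_that("alignment scores match an independent affine-gap DP oracle", {
  # frozen toy pairs
  expect_equal(globalAlign("ACDEFG", "ACDEYG")$score,
               gotohScoreOracle("ACDEFG", "ACDEYG"))
  expect_equal(globalAlign("ACD", "A")$score, gotohScoreOracle("ACD", "A"))
  # random suite, all lengths <= 8
  set.seed(404)
  for (rep in 1:60) {
    a <- randomProtein(sample(1:8, 1))
    b <- randomProtein(sample(1:8, 1))
    expect_equal(globalAlign(a, b)$score, gotohScoreOracle(a, b),
                 tolerance = 1e-9,
                 info = sprintf("pair %s / %s", a, b))
  }
})

test_that("percent identity counts identical columns over all columns", {
  expect_equal(percentIdentity(globalAlign("ACDEFG", "ACDEFG")), 1)
  expect_equal(percentIdentity("ACDEFG", "ACDEYG"), 5 / 6)
  expect_equal(percentIdentity("---", "ACD"), 0)
  expect_error(percentIdentity("", ""), "zero-length")
  expect_error(percentIdentity("AC", "A"), "equal length")
})

test_that("jaccard similarity follows |A∩B|/|A∪B| with empty-set convention 0", {
  expect_equal(jaccardSimilarity(c("KS", "AT"), c("KS", "C")), 1 / 3)
  expect_equal(jaccardSimilarity(c("KS", "AT"), c("AT", "KS", "KS")), 1)
  expect_equal(jaccardSimilarity(c("KS"), c("C")), 0)
  expect_equal(jaccardSimilarity(character(0), character(0)), 0)
})

test_that("backbone identity matches greedy best-pair matching, oracle-checked", {
  c1 <- toyCluster("c1")
  c2 <- toyCluster("c2")
  r <- backboneIdentity(c1, c2)
  expect_equal(r$identity, 1)
  expect_equal(r$nMatched, 1L)

  c3 <- toyCluster("c3", backbone = list("PKS_KS" = "MKDAWTEAAQNRV"))
  expect_equal(backboneIdentity(c1, c3), list(identity = 0, nMatched = 0L))

  # 2x2 copies: greedy must pick the (0.9, 0.8)-like pairing, not (0.9, 0.3);
  # sequences built so pairwise identities are far apart
  base <- randomProtein(40)
  near <- function(s, k) {    # change exactly k positions deterministically
    ch <- strsplit(s, "")[[1]]
    for (i in seq_len(k)) ch[i] <- setdiff(c("A", "G"), ch[i])[1]
    paste(ch, collapse = "")
  }
  set.seed(9)
  a1 <- randomProtein(40); a2 <- randomProtein(40)
  c4 <- toyCluster("c4", backbone = list("AMP-binding" = c(a1, a2)))
  c5 <- toyCluster("c5", backbone = list("AMP-binding" = c(near(a1, 2),
                                                           near(a2, 4))))
  got <- backboneIdentity(c4, c5)
  # enumerate both complete matchings as the oracle
  idm <- outer(c(a1, a2), c(near(a1, 2), near(a2, 4)),
               Vectorize(function(x, y) percentIdentity(globalAlign(x, y))))
  m1 <- stats::median(c(idm[1, 1], idm[2, 2]))
  m2 <- stats::median(c(idm[1, 2], idm[2, 1]))
  greedyBest <- if (max(idm) %in% c(idm[1, 1], idm[2, 2])) m1 else m2
  expect_equal(got$identity, greedyBest)
  expect_equal(got$nMatched, 2L)
  expect_gt(m1, m2)  # the greedy pairing is the high-identity one here
})

test_that("combined score applies the 0.8/0.2 weighting and validates input", {
  expect_equal(combinedScore(1, 0), 0.8)
  expect_equal(combinedScore(0, 1), 0.2)
  expect_equal(combinedScore(0.75, 0.5), 0.7)
  expect_error(combinedScore(1.2, 0), "\\[0, 1\\]")
  expect_error(ScoreWeights(0.8, 0.3), "sum to 1")
})

test_that("similarity matrix is symmetric, self-similar, and matches per-pair calls", {
  sim <- simulateFamilies(SimulationConfig(nFamilies = 2, familySizes = 2,
                                           nSingletons = 1, seed = 21,
                                           seqLengthRange = c(60L, 90L)))
  cs <- sim$clusters
  sm <- similarityMatrix(cs)
  S <- scoreMatrix(sm)
  expect_true(isSymmetric(unname(S)))
  expect_equal(unname(diag(S)), rep(1, length(cs)))
  # off-diagonal values equal independent per-pair recomputation
  ids <- clusterIds(cs)
  for (i in 1:2) for (j in (i + 1):3) {
    bi <- backboneIdentity(cs[[ids[i]]], cs[[ids[j]]])
    jj <- jaccardSimilarity(cs[[ids[i]]]@domainArray, cs[[ids[j]]]@domainArray)
    expect_equal(S[i, j], combinedScore(bi$identity, jj))
  }
  # identical clusters score 1
  twin <- ClusterSet(list(toyCluster("t1"), toyCluster("t2")))
  expect_equal(scoreMatrix(similarityMatrix(twin))["t1", "t2"], 1)
  # n(n-1)/2 edges
  expect_equal(nrow(similarityEdges(sm)), choose(length(cs), 2))
})

test_that("score is monotone in each component with the other fixed", {
  for (idv in c(0, 0.3, 0.9)) {
    s <- vapply(seq(0, 1, 0.25), function(j) combinedScore(idv, j), numeric(1))
    expect_true(all(diff(s) >= 0))
  }
  for (jv in c(0, 0.5, 1)) {
    s <- vapply(seq(0, 1, 0.25), function(i) combinedScore(i, jv), numeric(1))
    expect_true(all(diff(s) >= 0))
  }
})
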