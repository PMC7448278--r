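test_that("score-to-distance conversion matches the epsilon/score correspondence", {
  expect_equal(toDistance(0.45), 0.55)
  expect_equal(toDistance(1), 0)
  expect_equal(toDistance(0), 1)
  expect_error(toDistance(1.1), "outside")
})

test_that("family calling handles the hand-built cases", {
  d <- matrix(c(0, .1, .9, .1, 0, .9, .9, .9, 0), 3, 3,
              dimnames = list(c("x1", "x2", "x3"), c("x1", "x2", "x3")))
  fam <- callFamilies(d)
  expect_equal(nFamilies(fam), 1L)
  expect_equal(singletons(fam), "x3")
  expect_equal(familyTable(fam)$family_id, c("1", "1", "singleton"))

  # density chaining: 1-2 and 2-3 within epsilon, 1-3 not
  d <- matrix(c(0, .5, .9, .5, 0, .5, .9, .5, 0), 3, 3,
              dimnames = list(paste0("c", 1:3), paste0("c", 1:3)))
  fam <- callFamilies(d)
  expect_equal(nFamilies(fam), 1L)
  expect_equal(length(singletons(fam)), 0L)

  # all far apart: everything noise
  d <- matrix(0.9, 3, 3); diag(d) <- 0
  dimnames(d) <- list(paste0("c", 1:3), paste0("c", 1:3))
  fam <- callFamilies(d)
  expect_equal(nFamilies(fam), 0L)
  expect_equal(length(singletons(fam)), 3L)

  expect_error(callFamilies(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("epsilon neighbourhoods are inclusive (d <= eps)", {
  d <- matrix(c(0, 0.55, 0.55, 0), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(nFamilies(callFamilies(d, epsilon = 0.55)), 1L)
  d[1, 2] <- d[2, 1] <- 0.5500001
  expect_equal(nFamilies(callFamilies(d, epsilon = 0.55)), 0L)
})

test_that("DBSCAN at minPts 2 equals threshold-graph connected components (random suite)", {
  set.seed(1234)
  for (rep in 1:150) {
    n <- sample(2:7, 1)
    d <- randomDistanceMatrix(n)
    eps <- 0.55
    fam <- callFamilies(d, epsilon = eps)
    comp <- componentsOracle(d, eps)
    expect_true(samePartition(fam, comp),
                info = sprintf("rep %d n %d", rep, n))
  }
})

test_that("raising epsilon never shrinks families (monotone nesting)", {
  set.seed(77)
  for (rep in 1:20) {
    d <- randomDistanceMatrix(sample(4:7, 1))
    epss <- c(0.2, 0.4, 0.55, 0.7, 0.9)
    sizes <- vapply(epss, function(e) {
      fam <- callFamilies(d, epsilon = e)
      sum(!is.na(fam@assignments$family))
    }, numeric(1))
    expect_true(all(diff(sizes) >= 0))
    # each family at a smaller eps is contained in one family at larger eps
    for (k in seq_len(length(epss) - 1)) {
      f1 <- callFamilies(d, epsilon = epss[k])@assignments$family
      f2 <- callFamilies(d, epsilon = epss[k + 1])@assignments$family
      for (lab in unique(f1[!is.na(f1)])) {
        members <- which(f1 == lab)
        expect_equal(length(unique(f2[members])), 1L)
      }
    }
  }
})

test_that("network edges use the inclusive score threshold and match families", {
  sim <- simulateFamilies(SimulationConfig(nFamilies = 2, familySizes = 3,
                                           nSingletons = 2, seed = 7,
                                           seqLengthRange = c(60L, 90L)))
  sm <- similarityMatrix(sim$clusters)
  edges <- networkEdges(sm, scoreThreshold = 0.45)
  fam <- callFamilies(sm)
  # components of the edge graph equal called families
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                     vertices = clusterIds(sim$clusters))
  comp <- igraph::components(g)$membership[clusterIds(sim$clusters)]
  expect_true(samePartition(fam, as.integer(comp)))

  # inclusive threshold on a hand-made result
  ids <- c("a", "b", "c")
  mk <- function(v) {
    m <- matrix(1, 3, 3, dimnames = list(ids, ids))
    m[1, 2] <- m[2, 1] <- v[1]; m[1, 3] <- m[3, 1] <- v[2]
    m[2, 3] <- m[3, 2] <- v[3]; m
  }
  sr <- new("SimilarityResult", clusterIds = ids,
            identity = mk(c(.46, .45, .44)), jaccard = mk(c(.46, .45, .44)),
            score = mk(c(.46, .45, .44)),
            nMatched = matrix(0L, 3, 3, dimnames = list(ids, ids)),
            weights = ScoreWeights())
  expect_equal(nrow(networkEdges(sr, 0.45)), 2L)
})

test_that("UPGMA reproduces the hand-computed 3-leaf tree", {
  d <- matrix(c(0, .2, .6, .2, 0, .8, .6, .8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(d)
  expect_equal(tr@heights, c(0.1, 0.35))
  expect_equal(tr@newick, "((A:0.1,B:0.1):0.25,C:0.35);")

  d2 <- matrix(c(0, .4, .4, 0), 2, 2, dimnames = list(c("L", "R"), c("L", "R")))
  tr2 <- upgma(d2)
  expect_equal(tr2@heights, 0.2)
  expect_equal(tr2@newick, "(L:0.2,R:0.2);")

  expect_error(upgma(matrix(c(0, NA, NA, 0), 2, 2)), "NA")
})

test_that("UPGMA heights are non-decreasing and agree with average-linkage hclust", {
  set.seed(55)
  for (rep in 1:10) {
    n <- sample(4:7, 1)
    # unrounded distances: tie-free, so hclust and upgma agree exactly
    d <- matrix(0, n, n, dimnames = list(paste0("c", 1:n), paste0("c", 1:n)))
    d[upper.tri(d)] <- stats::runif(n * (n - 1) / 2)
    d <- d + t(d)
    tr <- upgma(d)
    expect_equal(length(tr@heights), n - 1L)
    expect_true(all(diff(tr@heights) >= -1e-12))
    # independent cross-check: hclust average-linkage merge heights
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    expect_equal(sort(tr@heights), sort(hc$height / 2), tolerance = 1e-9)
    # cophenetic distances agree too (pins the topology up to ties)
    expect_equal(
      as.matrix(stats::cophenetic(hc))[rownames(d), rownames(d)],
      ape::cophenetic.phylo(tr@phylo)[rownames(d), rownames(d)] / 1,
      tolerance = 1e-9)
  }
})

test_that("UPGMA on an ultrametric input reconstructs the generating tree", {
  # build an ultrametric tree: ((a,b):h1, (c,(d,e)):...) via known heights
  labs <- c("a", "b", "c", "d", "e")
  d <- matrix(0.8, 5, 5, dimnames = list(labs, labs))
  d["a", "b"] <- d["b", "a"] <- 0.1
  d["d", "e"] <- d["e", "d"] <- 0.2
  d["c", "d"] <- d["d", "c"] <- d["c", "e"] <- d["e", "c"] <- 0.4
  diag(d) <- 0
  tr <- upgma(d)
  coph <- ape::cophenetic.phylo(tr@phylo)[labs, labs]
  expect_equal(unname(coph), unname(d), tolerance = 1e-9)
})
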