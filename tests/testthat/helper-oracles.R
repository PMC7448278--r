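# Independent oracles and fixture builders used across the suite.

# Gotoh affine-gap global alignment *score* oracle, written independently
# of the alignment backend: gap of length L costs open + L * ext, end gaps
# penalized.  Returns the optimal global score.
.blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

gotohScoreOracle <- function(a, b, open = 10, ext = 0.5) {
  subMat <- .blosum62
  s <- function(x, y) subMat[x, y]
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)  # ends in gap in b (vertical)
  Y <- matrix(NEG, n + 1, m + 1)  # ends in gap in a (horizontal)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sc <- s(ca[i], cb[j])
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + sc
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                             X[i, j + 1] - ext,
                             Y[i, j + 1] - open - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext,
                             X[i + 1, j] - open - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Connected components of the epsilon-threshold graph (inclusive), as a
# brute-force BFS independent of the DBSCAN implementation.  Returns an
# integer component label per row; components of size 1 are singletons.
componentsOracle <- function(d, eps) {
  n <- nrow(d)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[q])) next
      comp[q] <- cur
      queue <- c(queue, which(d[q, ] <= eps & is.na(comp) &
                                seq_len(n) != q))
    }
  }
  comp
}

# compare a GCFAssignment against an oracle component labelling:
# families must equal multi-member components and singletons the size-1 ones
samePartition <- function(assignment, comp) {
  fam <- assignment@assignments$family
  sizes <- table(comp)
  oracleSingle <- as.integer(names(sizes)[sizes == 1])
  singleOK <- identical(which(is.na(fam)), which(comp %in% oracleSingle))
  multiIdx <- which(!comp %in% oracleSingle)
  if (!singleOK) return(FALSE)
  if (!length(multiIdx)) return(TRUE)
  f <- fam[multiIdx]; g <- comp[multiIdx]
  # identical partitions iff the label cross-table is a permutation matrix
  tab <- table(f, g)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

randomDistanceMatrix <- function(n, labels = NULL) {
  d <- matrix(0, n, n)
  vals <- round(stats::runif(n * (n - 1) / 2), 2)
  d[upper.tri(d)] <- vals
  d <- d + t(d)
  if (is.null(labels)) labels <- paste0("c", seq_len(n))
  dimnames(d) <- list(labels, labels)
  d
}

randomProtein <- function(len) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                 "F","P","S","T","W","Y","V"), len, replace = TRUE),
        collapse = "")
}

# a small hand-built cluster record
toyCluster <- function(id, genome = "g1", domains = c("PF1", "PF2"),
                       backbone = list("AMP-binding" = "MKDAWTEAAQNRV"),
                       proteins = setNames("MKDAWTE", paste0(id, "_p1"))) {
  ClusterRecord(clusterId = id, genomeId = genome, productClass = "NRPS",
                domainArray = domains, backboneDomains = backbone,
                proteins = proteins)
}

adjustedRand <- function(a, b) mclust::adjustedRandIndex(a, b)
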