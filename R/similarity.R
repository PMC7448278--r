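#' Backbone domain types used for sequence-identity scoring
#'
#' Core scaffold-building domain types of NRPS/PKS/hybrid backbone enzymes.
#' Only sequences filed under these types contribute to the median
#' backbone-domain identity between two clusters.
#'
#' @return Character vector of backbone domain type names.
#' @export
backboneDomainTypes <- function() {
  c("AMP-binding", "Condensation", "PCP", "PP-binding",
    "PKS_KS", "PKS_AT", "DMAT", "TE")
}

#' Deterministic global protein alignment
#'
#' Needleman-Wunsch global alignment with BLOSUM62 substitution scores and
#' affine gap penalties (opening 10, extension 0.5 per gap position), end
#' gaps penalized.  Backed by \code{Biostrings::pairwiseAlignment}, which
#' resolves score ties deterministically.
#'
#' @param a,b protein sequences (20-letter alphabet plus X).
#' @param gapOpening,gapExtension affine gap penalties; a gap of length L
#'   costs \code{gapOpening + L * gapExtension}.
#' @return A list with elements \code{alignedA}, \code{alignedB} (gapped
#'   strings of equal length) and \code{score}.
#' @examples
#' aln <- globalAlign("ACDEFG", "ACDEYG")
#' percentIdentity(aln)
#' @export
globalAlign <- function(a, b, gapOpening = 10, gapExtension = 0.5) {
  if (!nzchar(a) || !nzchar(b))
    stop("globalAlign: sequences must be non-empty")
  bad <- .checkAASeq(c(a, b))
  if (!is.null(bad)) stop("globalAlign: ", bad)
  aln <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = "BLOSUM62",
    gapOpening = gapOpening, gapExtension = gapExtension)
  list(alignedA = as.character(Biostrings::alignedPattern(aln)),
       alignedB = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}

#' Percent identity of a pairwise alignment
#'
#' Identical-residue columns divided by total alignment columns, end gaps
#' included in the denominator.  Columns where either row is a gap never
#' count as identical.
#'
#' @param alignment result of \code{\link{globalAlign}}, or a gapped string
#'   (then \code{b} must be the second gapped string).
#' @param b optional second gapped string.
#' @return Fraction in [0, 1].
#' @export
percentIdentity <- function(alignment, b = NULL) {
  if (is.list(alignment)) {
    ga <- alignment$alignedA; gb <- alignment$alignedB
  } else {
    ga <- alignment; gb <- b
  }
  if (is.null(ga) || is.null(gb) || nchar(ga) != nchar(gb))
    stop("percentIdentity: need two gapped strings of equal length")
  if (nchar(ga) == 0L) stop("percentIdentity: zero-length alignment")
  ca <- strsplit(ga, "")[[1]]
  cb <- strsplit(gb, "")[[1]]
  sum(ca == cb & ca != "-") / length(ca)
}

#' Jaccard similarity of two domain-name sets
#'
#' \code{|A intersect B| / |A union B|}; defined as 0 when both sets are
#' empty.  Inputs are deduplicated.
#'
#' @param domainsA,domainsB character vectors of domain names.
#' @return Fraction in [0, 1].
#' @export
jaccardSimilarity <- function(domainsA, domainsB) {
  a <- unique(as.character(domainsA))
  b <- unique(as.character(domainsB))
  u <- union(a, b)
  if (length(u) == 0L) return(0)
  length(intersect(a, b)) / length(u)
}

# identity matrix between two sets of sequences of the same backbone type
.pairIdentityMatrix <- function(seqsA, seqsB, gapOpening, gapExtension) {
  m <- matrix(0, length(seqsA), length(seqsB))
  for (i in seq_along(seqsA))
    for (j in seq_along(seqsB))
      m[i, j] <- percentIdentity(
        globalAlign(seqsA[i], seqsB[j], gapOpening, gapExtension))
  m
}

# greedy best-first matching on an identity matrix; returns matched values.
# Ties broken by row then column index, so the result is order-independent
# for distinct values and deterministic always.
.greedyMatch <- function(m) {
  vals <- numeric(0)
  while (nrow(m) > 0L && ncol(m) > 0L) {
    best <- which(m == max(m), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    vals <- c(vals, m[best[1], best[2]])
    m <- m[-best[1], -best[2], drop = FALSE]
  }
  vals
}

#' Median backbone-domain identity between two clusters
#'
#' For every backbone domain type present in both clusters (see
#' \code{\link{backboneDomainTypes}}), sequences are matched greedily by
#' best pairwise global-alignment identity, each sequence used at most
#' once; unmatched extra copies are ignored.  The value returned is the
#' median identity over all matched pairs across types.
#'
#' @param c1,c2 \linkS4class{ClusterRecord} objects.
#' @param backboneTypes domain types considered backbone.
#' @param gapOpening,gapExtension alignment penalties, see
#'   \code{\link{globalAlign}}.
#' @return list(identity = median identity in [0,1], nMatched = number of
#'   matched sequence pairs); (0, 0) if no backbone type is shared.
#' @export
backboneIdentity <- function(c1, c2, backboneTypes = backboneDomainTypes(),
                             gapOpening = 10, gapExtension = 0.5) {
  stopifnot(is(c1, "ClusterRecord"), is(c2, "ClusterRecord"))
  shared <- intersect(intersect(names(c1@backboneDomains), backboneTypes),
                      names(c2@backboneDomains))
  vals <- numeric(0)
  for (ty in shared) {
    sa <- c1@backboneDomains[[ty]]
    sb <- c2@backboneDomains[[ty]]
    if (!length(sa) || !length(sb)) next
    m <- .pairIdentityMatrix(sa, sb, gapOpening, gapExtension)
    vals <- c(vals, .greedyMatch(m))
  }
  if (!length(vals)) return(list(identity = 0, nMatched = 0L))
  list(identity = stats::median(vals), nMatched = length(vals))
}

#' Combined weighted cluster similarity score
#'
#' The defining similarity of the gene-cluster-family workflow:
#' \code{score = wId * seq_identity + wJac * jaccard}, with default
#' weights 0.8 and 0.2.
#'
#' @param seqIdentity median backbone-domain identity in [0, 1].
#' @param jaccard protein-domain-set Jaccard similarity in [0, 1].
#' @param weights a \linkS4class{ScoreWeights}.
#' @return Score in [0, 1].
#' @examples
#' combinedScore(1, 0)   # 0.8
#' combinedScore(0, 1)   # 0.2
#' @export
combinedScore <- function(seqIdentity, jaccard, weights = ScoreWeights()) {
  stopifnot(is(weights, "ScoreWeights"))
  validObject(weights)
  if (any(seqIdentity < 0 | seqIdentity > 1) ||
      any(jaccard < 0 | jaccard > 1))
    stop("combinedScore: inputs must lie in [0, 1]")
  s <- weights@wId * seqIdentity + weights@wJac * jaccard
  pmin(pmax(s, 0), 1)
}

#' All-pairs similarity matrices for a cluster set
#'
#' Scores every unordered pair of clusters: median backbone identity,
#' domain-set Jaccard, and the combined weighted score.  Diagonals are 1
#' by convention.
#'
#' @param clusterSet a \linkS4class{ClusterSet} with at least 2 clusters.
#' @param weights a \linkS4class{ScoreWeights}.
#' @param backboneTypes backbone domain type whitelist.
#' @param gapOpening,gapExtension alignment penalties.
#' @return A \linkS4class{SimilarityResult}.
#' @export
similarityMatrix <- function(clusterSet, weights = ScoreWeights(),
                             backboneTypes = backboneDomainTypes(),
                             gapOpening = 10, gapExtension = 0.5) {
  stopifnot(is(clusterSet, "ClusterSet"))
  validObject(clusterSet)
  ids <- clusterIds(clusterSet)
  n <- length(ids)
  if (n < 2L) stop("similarityMatrix: need at least 2 clusters")
  idm <- matrix(1, n, n, dimnames = list(ids, ids))
  jac <- matrix(1, n, n, dimnames = list(ids, ids))
  sco <- matrix(1, n, n, dimnames = list(ids, ids))
  nm  <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      ci <- clusterSet[[i]]; cj <- clusterSet[[j]]
      bi <- backboneIdentity(ci, cj, backboneTypes, gapOpening, gapExtension)
      jj <- jaccardSimilarity(ci@domainArray, cj@domainArray)
      sc <- combinedScore(bi$identity, jj, weights)
      idm[i, j] <- idm[j, i] <- bi$identity
      jac[i, j] <- jac[j, i] <- jj
      sco[i, j] <- sco[j, i] <- sc
      nm[i, j] <- nm[j, i] <- bi$nMatched
    }
  }
  new("SimilarityResult", clusterIds = ids, identity = idm, jaccard = jac,
      score = sco, nMatched = nm, weights = weights)
}

#' Edge list of a similarity result
#'
#' One row per unordered cluster pair, with the identity and Jaccard
#' components and the combined score.
#'
#' @param simResult a \linkS4class{SimilarityResult}.
#' @return data.frame(cluster_a, cluster_b, seq_identity, jaccard, score).
#' @export
similarityEdges <- function(simResult) {
  stopifnot(is(simResult, "SimilarityResult"))
  ids <- simResult@clusterIds
  n <- length(ids)
  idx <- which(upper.tri(simResult@score), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(cluster_a = ids[idx[, 1]],
             cluster_b = ids[idx[, 2]],
             seq_identity = simResult@identity[idx],
             jaccard = simResult@jaccard[idx],
             score = simResult@score[idx],
             stringsAsFactors = FALSE)
}
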