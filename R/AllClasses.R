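#' @import methods
#' @importFrom stats median setNames
#' @importFrom utils read.delim write.table
NULL

AA_ALPHABET_STRICT <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                        "F","P","S","T","W","Y","V")
AA_ALPHABET_X <- c(AA_ALPHABET_STRICT, "X")

.checkAASeq <- function(x) {
  chars <- unique(strsplit(paste(x, collapse = ""), "")[[1]])
  bad <- setdiff(chars, AA_ALPHABET_X)
  if (length(bad))
    sprintf("invalid amino-acid letters: %s", paste(bad, collapse = ", "))
  else
    NULL
}

#' Weights of the combined cluster similarity score
#'
#' The combined score between two gene clusters is
#' \code{wId * sequence_identity + wJac * jaccard}.  The defaults (0.8, 0.2)
#' weight median backbone-domain identity four times as heavily as
#' protein-domain-set Jaccard similarity.
#'
#' @slot wId weight on median backbone-domain sequence identity.
#' @slot wJac weight on protein-domain-set Jaccard similarity.
#' @export
setClass("ScoreWeights",
  representation(wId = "numeric", wJac = "numeric"),
  prototype(wId = 0.8, wJac = 0.2),
  validity = function(object) {
    msg <- character()
    if (length(object@wId) != 1L || length(object@wJac) != 1L)
      msg <- c(msg, "wId and wJac must be scalars")
    else {
      if (object@wId < 0 || object@wJac < 0)
        msg <- c(msg, "weights must be non-negative")
      if (abs(object@wId + object@wJac - 1) > 1e-9)
        msg <- c(msg, "weights must sum to 1")
    }
    if (length(msg)) msg else TRUE
  })

#' @param wId,wJac numeric weights, non-negative, summing to 1.
#' @return A \code{ScoreWeights} object.
#' @rdname ScoreWeights-class
#' @export
ScoreWeights <- function(wId = 0.8, wJac = 0.2) {
  new("ScoreWeights", wId = wId, wJac = wJac)
}

#' Profile-HMM hit filtering policy
#'
#' Thresholds applied to domain-table hits when mining an enzyme family.
#' Defaults reproduce the indoleamine 2,3-dioxygenase screen: Pfam model
#' PF01231, subject proteins of at least 350 residues, full-sequence
#' E value at most 1e-30.  Both thresholds are inclusive.
#'
#' @slot modelAccession Pfam (or other profile) accession to keep.
#' @slot minSubjectLength minimum full-length protein size in residues.
#' @slot maxEvalue maximum full-sequence E value.
#' @export
setClass("FilterPolicy",
  representation(modelAccession = "character",
                 minSubjectLength = "integer",
                 maxEvalue = "numeric"),
  prototype(modelAccession = "PF01231", minSubjectLength = 350L,
            maxEvalue = 1e-30),
  validity = function(object) {
    msg <- character()
    if (object@minSubjectLength < 1L)
      msg <- c(msg, "minSubjectLength must be >= 1")
    if (object@maxEvalue <= 0)
      msg <- c(msg, "maxEvalue must be > 0")
    if (length(msg)) msg else TRUE
  })

#' @param modelAccession,minSubjectLength,maxEvalue see slots.
#' @return A \code{FilterPolicy} object.
#' @rdname FilterPolicy-class
#' @export
FilterPolicy <- function(modelAccession = "PF01231",
                         minSubjectLength = 350L,
                         maxEvalue = 1e-30) {
  new("FilterPolicy", modelAccession = modelAccession,
      minSubjectLength = as.integer(minSubjectLength),
      maxEvalue = maxEvalue)
}

#' A single biosynthetic gene cluster record
#'
#' One BGC as read from a cluster manifest: its ordered protein-domain
#' array (used for Jaccard similarity), its backbone-enzyme domain
#' amino-acid sequences keyed by domain type (used for sequence identity),
#' and its protein complement.
#'
#' @slot clusterId unique cluster identifier.
#' @slot genomeId genome of origin.
#' @slot productClass free-text product class, e.g. "NRPS".
#' @slot domainArray ordered character vector of domain names; may be empty.
#' @slot backboneDomains named list; each element a character vector of
#'   amino-acid sequences of one backbone domain type (e.g. "AMP-binding").
#' @slot proteins named character vector of protein sequences; names are
#'   protein ids.
#' @export
setClass("ClusterRecord",
  representation(clusterId = "character", genomeId = "character",
                 productClass = "character", domainArray = "character",
                 backboneDomains = "list", proteins = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@clusterId) != 1L || !nzchar(object@clusterId))
      msg <- c(msg, "clusterId must be a non-empty string")
    if (length(object@genomeId) != 1L)
      msg <- c(msg, "genomeId must be a single string")
    bd <- object@backboneDomains
    if (length(bd) && is.null(names(bd)))
      msg <- c(msg, "backboneDomains must be a named list")
    for (ty in names(bd)) {
      if (!is.character(bd[[ty]]))
        msg <- c(msg, sprintf("backboneDomains[['%s']] must be character", ty))
      else {
        bad <- .checkAASeq(bd[[ty]])
        if (!is.null(bad))
          msg <- c(msg, sprintf("backboneDomains[['%s']]: %s", ty, bad))
      }
    }
    if (length(object@proteins) && is.null(names(object@proteins)))
      msg <- c(msg, "proteins must be a named character vector")
    if (length(msg)) msg else TRUE
  })

#' @param clusterId,genomeId,productClass,domainArray,backboneDomains,proteins
#'   see slots.
#' @return A \code{ClusterRecord}.
#' @rdname ClusterRecord-class
#' @export
ClusterRecord <- function(clusterId, genomeId, productClass = "",
                          domainArray = character(),
                          backboneDomains = list(),
                          proteins = character()) {
  new("ClusterRecord", clusterId = clusterId, genomeId = genomeId,
      productClass = productClass, domainArray = as.character(domainArray),
      backboneDomains = backboneDomains, proteins = proteins)
}

#' A set of gene cluster records
#'
#' Container for the clusters of one manifest.  Cluster ids are unique;
#' elements are \linkS4class{ClusterRecord} objects, accessible by id.
#'
#' @slot clusters named list of \code{ClusterRecord}s, names = cluster ids.
#' @export
setClass("ClusterSet",
  representation(clusters = "list"),
  validity = function(object) {
    msg <- character()
    ids <- vapply(object@clusters, function(x) x@clusterId, character(1))
    if (anyDuplicated(ids))
      msg <- c(msg, sprintf("duplicate cluster ids: %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    if (length(object@clusters) &&
        !identical(unname(names(object@clusters)), unname(ids)))
      msg <- c(msg, "list names must equal cluster ids")
    ok <- vapply(object@clusters, is, logical(1), class2 = "ClusterRecord")
    if (!all(ok)) msg <- c(msg, "all elements must be ClusterRecord")
    if (length(msg)) msg else TRUE
  })

#' @param clusters a list of \code{ClusterRecord}s.
#' @return A \code{ClusterSet}.
#' @rdname ClusterSet-class
#' @export
ClusterSet <- function(clusters = list()) {
  names(clusters) <- vapply(clusters, function(x) x@clusterId, character(1))
  new("ClusterSet", clusters = clusters)
}

#' Pairwise similarity matrices for a cluster set
#'
#' Symmetric matrices over all cluster pairs: median backbone-domain
#' sequence identity, protein-domain Jaccard similarity, the weighted
#' combined score, and the number of matched backbone sequence pairs
#' behind each identity value.  Diagonals are 1 (0 for pair counts).
#'
#' @slot clusterIds cluster identifiers (row/column order).
#' @slot identity,jaccard,score symmetric numeric matrices in [0,1].
#' @slot nMatched symmetric integer matrix of matched backbone pairs.
#' @slot weights the \linkS4class{ScoreWeights} used.
#' @export
setClass("SimilarityResult",
  representation(clusterIds = "character", identity = "matrix",
                 jaccard = "matrix", score = "matrix", nMatched = "matrix",
                 weights = "ScoreWeights"),
  validity = function(object) {
    n <- length(object@clusterIds)
    msg <- character()
    for (nm in c("identity", "jaccard", "score", "nMatched")) {
      m <- slot(object, nm)
      if (!identical(dim(m), c(n, n)))
        msg <- c(msg, sprintf("%s must be %d x %d", nm, n, n))
      else if (!isSymmetric(unname(m), tol = 1e-12))
        msg <- c(msg, sprintf("%s must be symmetric", nm))
    }
    if (length(msg)) msg else TRUE
  })

#' Gene cluster family assignment
#'
#' Result of density-based family calling: each cluster is assigned a
#' contiguous integer family label or flagged as a singleton (density
#' noise).
#'
#' @slot assignments data.frame with columns \code{cluster_id},
#'   \code{family} (integer, NA for singletons).
#' @slot epsilon neighbourhood radius used (on distance = 1 - score).
#' @slot minMembers DBSCAN minPts; families have at least this many members.
#' @export
setClass("GCFAssignment",
  representation(assignments = "data.frame", epsilon = "numeric",
                 minMembers = "integer"),
  validity = function(object) {
    msg <- character()
    a <- object@assignments
    if (!all(c("cluster_id", "family") %in% names(a)))
      msg <- c(msg, "assignments needs columns cluster_id, family")
    else {
      if (anyDuplicated(a$cluster_id))
        msg <- c(msg, "cluster ids must be unique")
      fams <- sort(unique(a$family[!is.na(a$family)]))
      if (length(fams) && !identical(as.integer(fams), seq_along(fams)))
        msg <- c(msg, "family labels must be contiguous integers from 1")
      if (length(fams)) {
        sizes <- table(a$family)
        if (any(sizes < object@minMembers))
          msg <- c(msg, "every family must have >= minMembers members")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Ultrametric UPGMA dendrogram
#'
#' Average-linkage merge tree over gene clusters, stored both as a Newick
#' string with branch lengths and as an \pkg{ape} \code{phylo} object.
#' Internal node heights are half the merge distance and non-decreasing
#' towards the root.
#'
#' @slot labels leaf labels.
#' @slot newick Newick serialization with branch lengths.
#' @slot heights merge heights in merge order.
#' @slot phylo the \pkg{ape} tree (class \code{phylo}), or NULL for a
#'   single-leaf tree.
#' @export
setClass("Dendrogram",
  representation(labels = "character", newick = "character",
                 heights = "numeric", phylo = "ANY"),
  validity = function(object) {
    msg <- character()
    if (length(object@labels) < 1L) msg <- c(msg, "tree must have >= 1 leaf")
    if (length(object@newick) != 1L) msg <- c(msg, "newick must be a string")
    if (length(object@heights) &&
        any(diff(sort(object@heights)) < -1e-12))
      msg <- c(msg, "heights must be sortable non-decreasingly")
    if (length(msg)) msg else TRUE
  })

#' Adenylation-domain substrate-specificity code
#'
#' Residues of a query A-domain read off at reference-defined
#' substrate-binding positions (gramicidin S synthetase numbering by
#' default).  Positions the query does not cover are rendered "-".
#'
#' @slot domainId identifier of the query domain.
#' @slot residues single string, one character per reference position.
#' @slot referencePositions 1-based positions in the reference sequence.
#' @export
setClass("SpecificityCode",
  representation(domainId = "character", residues = "character",
                 referencePositions = "integer"),
  validity = function(object) {
    msg <- character()
    if (nchar(object@residues) != length(object@referencePositions))
      msg <- c(msg, "residues length must equal number of reference positions")
    if (length(msg)) msg else TRUE
  })

#' Stable-isotope labelling scenario
#'
#' A labelled biosynthetic precursor and the bookkeeping of how many of its
#' heavy atoms survive the biosynthetic transformation into the product.
#' Each label entry records the element, the heavy isotope (e.g. "13C",
#' "2H"), how many atoms carry it in the precursor, and how many are
#' retained in the product.
#'
#' @slot precursorName e.g. "[13C6]anthranilate".
#' @slot labels data.frame with columns \code{element}, \code{isotope},
#'   \code{n_labeled}, \code{n_retained}.
#' @slot note free-text description of the atom-retention reasoning.
#' @export
setClass("LabelScenario",
  representation(precursorName = "character", labels = "data.frame",
                 note = "character"),
  validity = function(object) {
    msg <- character()
    l <- object@labels
    need <- c("element", "isotope", "n_labeled", "n_retained")
    if (!all(need %in% names(l)))
      msg <- c(msg, paste("labels needs columns", paste(need, collapse = ", ")))
    else {
      if (any(l$n_labeled < 0) || any(l$n_retained < 0))
        msg <- c(msg, "label counts must be non-negative")
      if (any(l$n_retained > l$n_labeled))
        msg <- c(msg, "n_retained cannot exceed n_labeled")
    }
    if (length(msg)) msg else TRUE
  })

#' @param precursorName,labels,note see slots.
#' @return A \code{LabelScenario}.
#' @rdname LabelScenario-class
#' @export
LabelScenario <- function(precursorName, labels, note = "") {
  new("LabelScenario", precursorName = precursorName, labels = labels,
      note = note)
}
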