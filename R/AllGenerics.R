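#' @rdname ClusterSet-class
#' @param x a \code{ClusterSet}, \code{SimilarityResult} or
#'   \code{GCFAssignment}.
#' @export
setGeneric("clusterIds", function(x) standardGeneric("clusterIds"))

#' @rdname SimilarityResult-class
#' @param x a \code{SimilarityResult}.
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @rdname SimilarityResult-class
#' @export
setGeneric("identityMatrix", function(x) standardGeneric("identityMatrix"))

#' @rdname SimilarityResult-class
#' @export
setGeneric("jaccardMatrix", function(x) standardGeneric("jaccardMatrix"))

#' @rdname GCFAssignment-class
#' @param x a \code{GCFAssignment}.
#' @export
setGeneric("familyTable", function(x) standardGeneric("familyTable"))

#' @rdname GCFAssignment-class
#' @export
setGeneric("nFamilies", function(x) standardGeneric("nFamilies"))

#' @rdname GCFAssignment-class
#' @export
setGeneric("singletons", function(x) standardGeneric("singletons"))

setMethod("clusterIds", "ClusterSet",
          function(x) unname(names(x@clusters)))
setMethod("clusterIds", "SimilarityResult", function(x) x@clusterIds)
setMethod("clusterIds", "GCFAssignment",
          function(x) x@assignments$cluster_id)

setMethod("scoreMatrix", "SimilarityResult", function(x) x@score)
setMethod("identityMatrix", "SimilarityResult", function(x) x@identity)
setMethod("jaccardMatrix", "SimilarityResult", function(x) x@jaccard)

#' @describeIn GCFAssignment-class family table with a readable
#'   \code{family_id} column (\code{"singleton"} for noise points).
#' @export
setMethod("familyTable", "GCFAssignment", function(x) {
  a <- x@assignments
  data.frame(cluster_id = a$cluster_id,
             family_id = ifelse(is.na(a$family), "singleton",
                                as.character(a$family)),
             stringsAsFactors = FALSE)
})

setMethod("nFamilies", "GCFAssignment", function(x) {
  length(unique(x@assignments$family[!is.na(x@assignments$family)]))
})

setMethod("singletons", "GCFAssignment", function(x) {
  x@assignments$cluster_id[is.na(x@assignments$family)]
})

#' @rdname ClusterSet-class
#' @export
setMethod("length", "ClusterSet", function(x) length(x@clusters))

#' @rdname ClusterSet-class
#' @param i cluster id or index.
#' @export
setMethod("[[", "ClusterSet", function(x, i) x@clusters[[i]])

setMethod("show", "ClusterRecord", function(object) {
  cat("ClusterRecord", object@clusterId,
      sprintf("(genome %s, %s)\n", object@genomeId,
              if (nzchar(object@productClass)) object@productClass else "unclassified"))
  cat("  domain array:", length(object@domainArray), "domains;",
      "backbone types:",
      if (length(object@backboneDomains))
        paste(names(object@backboneDomains), collapse = ", ") else "none",
      "\n")
})

setMethod("show", "ClusterSet", function(object) {
  cat("ClusterSet with", length(object@clusters), "clusters\n")
  ids <- clusterIds(object)
  if (length(ids))
    cat("  ids:", paste(utils::head(ids, 6), collapse = ", "),
        if (length(ids) > 6) "..." else "", "\n")
})

setMethod("show", "SimilarityResult", function(object) {
  n <- length(object@clusterIds)
  cat(sprintf("SimilarityResult over %d clusters (%d pairs)\n",
              n, n * (n - 1) / 2))
  cat(sprintf("  weights: identity %.2f, Jaccard %.2f\n",
              object@weights@wId, object@weights@wJac))
})

setMethod("show", "GCFAssignment", function(object) {
  cat(sprintf("GCFAssignment: %d families, %d singletons (epsilon %.2f, minPts %d)\n",
              nFamilies(object), length(singletons(object)),
              object@epsilon, object@minMembers))
})

setMethod("show", "Dendrogram", function(object) {
  cat(sprintf("UPGMA Dendrogram with %d leaves, root height %.4g\n",
              length(object@labels),
              if (length(object@heights)) max(object@heights) else 0))
  cat(" ", object@newick, "\n")
})

setMethod("show", "SpecificityCode", function(object) {
  cat(sprintf("SpecificityCode %s: %s (positions %s)\n", object@domainId,
              object@residues,
              paste(object@referencePositions, collapse = ",")))
})

setMethod("show", "LabelScenario", function(object) {
  cat("LabelScenario:", object@precursorName, "\n")
  print(object@labels)
})
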