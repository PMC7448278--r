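#' Filter profile-HMM hits by accession, length and E value
#'
#' Keeps exactly the hits matching the policy's model accession, with
#' subject length at least \code{minSubjectLength} residues and
#' full-sequence E value at most \code{maxEvalue}.  Both thresholds are
#' inclusive, matching the plain reading of "minimum length" and "maximum
#' E value".  Input order is preserved and filtering is idempotent.
#'
#' @param hits domain-hit data.frame (see \code{\link{readDomtblout}}).
#' @param policy a \linkS4class{FilterPolicy}; the default reproduces the
#'   IDO screen (PF01231, >= 350 residues, E <= 1e-30).
#' @return The kept subset of \code{hits}.
#' @export
filterHits <- function(hits, policy = FilterPolicy()) {
  stopifnot(is(policy, "FilterPolicy"))
  validObject(policy)
  keep <- hits$model_accession == policy@modelAccession &
    hits$subject_length >= policy@minSubjectLength &
    hits$full_seq_evalue <= policy@maxEvalue
  hits[keep, , drop = FALSE]
}

#' Count target proteins per genome
#'
#' Number of distinct proteins per genome among (filtered) hits: a protein
#' with several domain rows counts once.
#'
#' @param hits filtered domain-hit data.frame.
#' @return Named integer vector, genome id -> protein count.
#' @export
countPerGenome <- function(hits) {
  if (nrow(hits) == 0L) return(stats::setNames(integer(0), character(0)))
  uniq <- unique(hits[, c("genome_id", "protein_id")])
  counts <- table(uniq$genome_id)
  stats::setNames(as.integer(counts), names(counts))
}

#' Flag clusters containing target proteins
#'
#' Returns the ids of clusters with at least one gene whose protein id is
#' in the target set (e.g. proteins passing the IDO filter).
#'
#' @param clusterSet a \linkS4class{ClusterSet}; protein ids are assumed
#'   globally unique.
#' @param targetProteins character vector of protein ids.
#' @return Character vector of flagged cluster ids.
#' @export
flagTargetClusters <- function(clusterSet, targetProteins) {
  stopifnot(is(clusterSet, "ClusterSet"))
  hit <- vapply(clusterSet@clusters, function(r)
    any(names(r@proteins) %in% targetProteins), logical(1))
  unname(clusterIds(clusterSet)[hit])
}

#' Write a mining report TSV
#'
#' One row per input hit with its thresholds verdict, for audit.
#'
#' @param hits full (unfiltered) hit table.
#' @param policy the \linkS4class{FilterPolicy} applied.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeMiningReport <- function(hits, policy, path) {
  kept <- hits$model_accession == policy@modelAccession &
    hits$subject_length >= policy@minSubjectLength &
    hits$full_seq_evalue <= policy@maxEvalue
  rep <- data.frame(genome_id = hits$genome_id,
                    protein_id = hits$protein_id,
                    length = hits$subject_length,
                    evalue = hits$full_seq_evalue,
                    kept = kept, stringsAsFactors = FALSE)
  utils::write.table(rep, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
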