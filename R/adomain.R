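#' Canonical A-domain specificity positions
#'
#' The ten substrate-binding-pocket positions of the phenylalanine-
#' activating adenylation domain of gramicidin S synthetase (GrsA),
#' in GrsA numbering, as used throughout the specificity-code
#' ("Stachelhaus code") literature.
#'
#' @return Integer vector of ten 1-based reference positions.
#' @export
stachelhausPositions <- function() {
  c(235L, 236L, 239L, 278L, 299L, 301L, 322L, 330L, 331L, 517L)
}

#' Extract a substrate-specificity code from an A-domain
#'
#' Globally aligns the query adenylation-domain sequence to the reference
#' synthetase sequence and reads off the query residues in the alignment
#' columns of the given reference positions.  Positions where the query
#' carries a gap are rendered \code{"-"}.
#'
#' @param query A-domain amino-acid sequence.
#' @param reference reference synthetase sequence (e.g. GrsA A-domain
#'   region).
#' @param positions 1-based positions in the ungapped reference.
#' @param domainId identifier recorded in the result.
#' @return A \linkS4class{SpecificityCode}.
#' @export
extractCode <- function(query, reference,
                        positions = stachelhausPositions(),
                        domainId = "query") {
  positions <- as.integer(positions)
  if (any(positions < 1L) || any(positions > nchar(reference)))
    stop("extractCode: position out of range of reference (1..",
         nchar(reference), ")")
  aln <- globalAlign(query, reference)
  qa <- strsplit(aln$alignedA, "")[[1]]
  ra <- strsplit(aln$alignedB, "")[[1]]
  # map ungapped reference position -> alignment column
  refpos <- cumsum(ra != "-")
  col <- match(positions, refpos)  # first column where that residue sits
  residues <- vapply(col, function(cc) {
    if (is.na(cc)) "-" else qa[cc]
  }, character(1))
  new("SpecificityCode", domainId = domainId,
      residues = paste(residues, collapse = ""),
      referencePositions = positions)
}

#' Identity between two specificity codes
#'
#' Fraction of reference positions carrying the same residue in both
#' codes.  Gaps (\code{"-"}) match nothing, including other gaps.
#'
#' @param a,b \linkS4class{SpecificityCode} objects over the same
#'   reference positions.
#' @return Fraction in [0, 1].
#' @export
codeIdentity <- function(a, b) {
  stopifnot(is(a, "SpecificityCode"), is(b, "SpecificityCode"))
  if (!identical(a@referencePositions, b@referencePositions))
    stop("codeIdentity: codes use different reference positions")
  ca <- strsplit(a@residues, "")[[1]]
  cb <- strsplit(b@residues, "")[[1]]
  sum(ca == cb & ca != "-") / length(ca)
}

#' Specificity-code table for all A-domains of a cluster set
#'
#' Extracts one code per AMP-binding backbone sequence, ordered by cluster
#' and then by domain index within the cluster (A_1, A_2, ...).
#'
#' @param clusterSet a \linkS4class{ClusterSet}.
#' @param reference reference synthetase sequence.
#' @param positions 1-based reference positions.
#' @param adomainType backbone type holding adenylation domains.
#' @return data.frame(cluster_id, domain_id, code).
#' @export
codeTable <- function(clusterSet, reference,
                      positions = stachelhausPositions(),
                      adomainType = "AMP-binding") {
  stopifnot(is(clusterSet, "ClusterSet"))
  rows <- list()
  for (id in clusterIds(clusterSet)) {
    rec <- clusterSet[[id]]
    seqs <- rec@backboneDomains[[adomainType]]
    if (is.null(seqs) || !length(seqs)) next
    for (i in seq_along(seqs)) {
      did <- sprintf("%s_A_%d", id, i)
      code <- extractCode(seqs[i], reference, positions, domainId = did)
      rows[[length(rows) + 1L]] <-
        data.frame(cluster_id = id, domain_id = did,
                   code = code@residues, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(cluster_id = character(), domain_id = character(),
                      code = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
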