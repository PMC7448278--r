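#' Read a HMMER3 per-domain table (domtblout)
#'
#' Parses the 23-column whitespace-delimited per-domain output of
#' \code{hmmsearch --domtblout}.  Lines starting with \code{#} are
#' comments.  The free-text description field (column 23 onwards) is
#' scanned for a \code{genome=<id>} token, which fills \code{genome_id}.
#'
#' @param path path to a domtblout file.
#' @return data.frame of domain hits with columns \code{protein_id},
#'   \code{genome_id}, \code{model_accession}, \code{model_name},
#'   \code{full_seq_evalue}, \code{bitscore}, \code{subject_length},
#'   \code{env_start}, \code{env_end}.  Coordinates are 1-based inclusive.
#' @export
readDomtblout <- function(path) {
  if (!file.exists(path))
    stop("readDomtblout: file not found: ", path)
  lines <- readLines(path)
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  out <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    ln <- keep[k]
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(f) < 22L)
      stop(sprintf("readDomtblout: line %d: expected >= 22 columns, got %d",
                   ln, length(f)))
    num <- suppressWarnings(as.numeric(f[c(3, 7, 8, 20, 21)]))
    if (anyNA(num))
      stop(sprintf("readDomtblout: line %d: unparsable numeric field", ln))
    desc <- if (length(f) >= 23L) paste(f[23:length(f)], collapse = " ") else ""
    gm <- regmatches(desc, regexec("genome=(\\S+)", desc))[[1]]
    out[[k]] <- data.frame(
      protein_id = f[1],
      genome_id = if (length(gm) == 2L) gm[2] else NA_character_,
      model_accession = f[5],
      model_name = f[4],
      full_seq_evalue = num[2],
      bitscore = num[3],
      subject_length = as.integer(num[1]),
      env_start = as.integer(num[4]),
      env_end = as.integer(num[5]),
      stringsAsFactors = FALSE)
  }
  hits <- if (length(out)) do.call(rbind, out) else
    data.frame(protein_id = character(), genome_id = character(),
               model_accession = character(), model_name = character(),
               full_seq_evalue = numeric(), bitscore = numeric(),
               subject_length = integer(), env_start = integer(),
               env_end = integer(), stringsAsFactors = FALSE)
  bad <- which(hits$env_start < 1L | hits$env_end < hits$env_start |
                 hits$subject_length < hits$env_end |
                 hits$full_seq_evalue < 0)
  if (length(bad))
    stop(sprintf("readDomtblout: line %d: coordinate/E-value invariant violated",
                 keep[bad[1]]))
  hits
}

#' Write a HMMER3-style domtblout file
#'
#' Inverse of \code{\link{readDomtblout}} for hit tables produced by this
#' package (columns not represented in the hit table are filled with
#' placeholder values in the HMMER layout).
#'
#' @param hits a domain-hit data.frame (see \code{\link{readDomtblout}}).
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeDomtblout <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target"),
    con)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    desc <- if (!is.na(h$genome_id)) sprintf("genome=%s", h$genome_id) else "-"
    writeLines(sprintf(
      "%s - %d %s %s %d %.9g %.1f 0.0 1 1 %.9g %.9g %.1f 0.0 1 %d %d %d %d %d 0.99 %s",
      h$protein_id, h$subject_length, h$model_name, h$model_accession,
      h$subject_length, h$full_seq_evalue, h$bitscore, h$full_seq_evalue,
      h$full_seq_evalue, h$bitscore, h$env_end - h$env_start + 1L,
      h$env_start, h$env_end, h$env_start, h$env_end, desc), con)
  }
  invisible(path)
}

.recordFromList <- function(x, idx) {
  need <- c("cluster_id", "genome_id")
  for (f in need)
    if (is.null(x[[f]]))
      stop(sprintf("readClusterManifest: cluster %d: missing field '%s'",
                   idx, f))
  bd <- x$backbone_domains
  bd <- if (is.null(bd)) list() else
    lapply(bd, function(s) as.character(unlist(s)))
  prot <- character()
  if (!is.null(x$proteins) && length(x$proteins)) {
    ids <- vapply(x$proteins, function(p) {
      if (is.null(p$id) || is.null(p$seq))
        stop(sprintf("readClusterManifest: cluster %d: protein entries need 'id' and 'seq'", idx))
      as.character(p$id)
    }, character(1))
    prot <- vapply(x$proteins, function(p) as.character(p$seq), character(1))
    names(prot) <- ids
  }
  rec <- tryCatch(
    ClusterRecord(clusterId = as.character(x$cluster_id),
                  genomeId = as.character(x$genome_id),
                  productClass = if (is.null(x$product_class)) "" else
                    as.character(x$product_class),
                  domainArray = as.character(unlist(x$domain_array)),
                  backboneDomains = bd, proteins = prot),
    error = function(e)
      stop(sprintf("readClusterManifest: cluster %d ('%s'): %s", idx,
                   as.character(x$cluster_id), conditionMessage(e)),
           call. = FALSE))
  rec
}

#' Read a cluster manifest (JSON)
#'
#' The manifest is the canonical BGC interchange format of this package:
#' \code{{"clusters": [{"cluster_id", "genome_id", "product_class",
#' "domain_array": [...], "backbone_domains": {"type": [seq, ...]},
#' "proteins": [{"id", "seq"}]}]}}.
#'
#' @param path path to the manifest JSON file.
#' @return A \linkS4class{ClusterSet}.
#' @export
readClusterManifest <- function(path) {
  if (!file.exists(path))
    stop("readClusterManifest: file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$clusters))
    stop("readClusterManifest: manifest lacks a 'clusters' array")
  recs <- lapply(seq_along(doc$clusters), function(i)
    .recordFromList(doc$clusters[[i]], i))
  ids <- vapply(recs, function(r) r@clusterId, character(1))
  if (anyDuplicated(ids))
    stop("readClusterManifest: duplicate cluster_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ClusterSet(recs)
}

#' Write a cluster manifest (JSON)
#'
#' @param clusterSet a \linkS4class{ClusterSet}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeClusterManifest <- function(clusterSet, path) {
  stopifnot(is(clusterSet, "ClusterSet"))
  clusters <- lapply(clusterSet@clusters, function(r) {
    list(cluster_id = r@clusterId,
         genome_id = r@genomeId,
         product_class = r@productClass,
         domain_array = as.list(r@domainArray),
         backbone_domains = lapply(r@backboneDomains, as.list),
         proteins = if (length(r@proteins))
           lapply(seq_along(r@proteins), function(i)
             list(id = names(r@proteins)[i], seq = unname(r@proteins[i])))
         else list())
  })
  json <- jsonlite::toJSON(list(clusters = unname(clusters)),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' Write a protein FASTA file
#'
#' @param seqs named character vector of protein sequences.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeProteinFasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Read a protein FASTA file
#'
#' @param path path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) stop("readProteinFasta: file not found: ", path)
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a dendrogram in Newick format
#'
#' @param tree a \linkS4class{Dendrogram}.
#' @param path output path.
#' @return Invisibly, the Newick string written.
#' @export
writeNewick <- function(tree, path) {
  stopifnot(is(tree, "Dendrogram"))
  if (length(tree@labels) == 0L) stop("writeNewick: empty tree")
  writeLines(tree@newick, path)
  invisible(tree@newick)
}

#' Read a Newick tree
#'
#' @param path path to a Newick file.
#' @return An \pkg{ape} \code{phylo} object.
#' @export
readNewick <- function(path) {
  if (!file.exists(path)) stop("readNewick: file not found: ", path)
  ape::read.tree(path)
}

#' Write a similarity edge list as TSV
#'
#' @param edges data.frame as returned by \code{\link{similarityEdges}}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeEdgeList <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a similarity edge list TSV
#'
#' @param path path to a TSV written by \code{\link{writeEdgeList}}.
#' @return data.frame(cluster_a, cluster_b, seq_identity, jaccard, score).
#' @export
readEdgeList <- function(path) {
  if (!file.exists(path)) stop("readEdgeList: file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(cluster_a = "character",
                                   cluster_b = "character"))
}

#' Write a family table as TSV
#'
#' Columns \code{cluster_id} and \code{family_id} (integer label or
#' \code{"singleton"}).
#'
#' @param assignment a \linkS4class{GCFAssignment}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeFamilyTable <- function(assignment, path) {
  utils::write.table(familyTable(assignment), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
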