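.pipelineStage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full gene-cluster-family pipeline
#'
#' Orchestrates manifest reading, all-pairs similarity scoring, network
#' edge extraction, density-based family calling, UPGMA dendrograms (over
#' the full set and per family), optional profile-HMM mining and optional
#' A-domain specificity-code extraction, materializing every stage output
#' under \code{outDir} together with a machine-readable JSON summary.
#' Reruns with an identical config overwrite to identical bytes.
#'
#' @param config a named list (or path to a JSON file holding one) with
#'   entries: \code{manifest} (path, required), \code{outDir} (path,
#'   required), \code{wId}, \code{wJac} (score weights, default 0.8/0.2),
#'   \code{epsilon} (default 0.55), \code{minMembers} (default 2),
#'   \code{scoreThreshold} (default \code{1 - epsilon}),
#'   \code{domtblout} (optional path), \code{modelAccession},
#'   \code{minSubjectLength}, \code{maxEvalue} (filter policy, defaults
#'   PF01231/350/1e-30), \code{adomainReference} (optional sequence or
#'   FASTA path), \code{adomainPositions} (defaults to
#'   \code{\link{stachelhausPositions}}).
#' @param quiet suppress progress messages.
#' @return Invisibly, the summary list (counts of clusters, edges,
#'   families, singletons, flagged clusters, plus the parameters used).
#' @export
runGcfPipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  for (f in c("manifest", "outDir"))
    if (is.null(config[[f]]))
      stop("runGcfPipeline: config requires '", f, "'")
  if (!file.exists(config$manifest))
    stop("runGcfPipeline: manifest not found: ", config$manifest)
  wId <- config$wId %||% 0.8
  wJac <- config$wJac %||% 0.2
  epsilon <- config$epsilon %||% 0.55
  minMembers <- config$minMembers %||% 2L
  scoreThreshold <- config$scoreThreshold %||% (1 - epsilon)
  weights <- ScoreWeights(wId, wJac)
  note <- function(...) if (!quiet) message(sprintf(...))
  note("gcfkit pipeline: weights id=%.2f jac=%.2f, epsilon=%.2f, minPts=%d",
       wId, wJac, epsilon, as.integer(minMembers))

  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outDir, f)

  clusters <- .pipelineStage("manifest", {
    cs <- readClusterManifest(config$manifest)
    if (length(cs) < 2L) stop("manifest must contain at least 2 clusters")
    cs
  })
  note("read %d clusters", length(clusters))

  sim <- .pipelineStage("similarity",
                        similarityMatrix(clusters, weights = weights))
  .pipelineStage("similarity", writeEdgeList(similarityEdges(sim),
                                             out("edges.tsv")))

  edges <- .pipelineStage("network", {
    e <- networkEdges(sim, scoreThreshold)
    writeEdgeList(e, out("network_edges.tsv"))
    e
  })

  fams <- .pipelineStage("families", {
    a <- callFamilies(sim, epsilon = epsilon, minMembers = minMembers)
    writeFamilyTable(a, out("families.tsv"))
    a
  })
  note("called %d families, %d singletons", nFamilies(fams),
       length(singletons(fams)))

  .pipelineStage("dendrogram", {
    writeNewick(upgma(sim), out("dendrogram_all.nwk"))
    ft <- familyTable(fams)
    d <- distanceMatrix(sim)
    for (fid in sort(unique(ft$family_id[ft$family_id != "singleton"]))) {
      members <- ft$cluster_id[ft$family_id == fid]
      tr <- if (length(members) >= 2L)
        upgma(d[members, members, drop = FALSE])
      else leafDendrogram(members)
      writeNewick(tr, out(sprintf("dendrogram_family_%s.nwk", fid)))
    }
  })

  flagged <- character(0)
  minedCount <- NA_integer_
  if (!is.null(config$domtblout)) {
    policy <- FilterPolicy(
      modelAccession = config$modelAccession %||% "PF01231",
      minSubjectLength = config$minSubjectLength %||% 350L,
      maxEvalue = config$maxEvalue %||% 1e-30)
    mined <- .pipelineStage("mining", {
      hits <- readDomtblout(config$domtblout)
      writeMiningReport(hits, policy, out("mining_report.tsv"))
      kept <- filterHits(hits, policy)
      counts <- countPerGenome(kept)
      utils::write.table(
        data.frame(genome_id = names(counts), n_proteins = counts,
                   row.names = NULL),
        out("counts_per_genome.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      kept
    })
    minedCount <- nrow(mined)
    flagged <- flagTargetClusters(clusters, unique(mined$protein_id))
    note("mining kept %d hits; %d clusters flagged", minedCount,
         length(flagged))
  }

  if (!is.null(config$adomainReference)) {
    ref <- config$adomainReference
    if (file.exists(ref)) ref <- unname(readProteinFasta(ref)[1])
    positions <- config$adomainPositions %||% stachelhausPositions()
    .pipelineStage("adomain", {
      tab <- codeTable(clusters, ref, positions)
      utils::write.table(tab, out("adomain_codes.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    })
  }

  summary <- list(
    n_clusters = length(clusters),
    n_edges_above_threshold = nrow(edges),
    n_families = nFamilies(fams),
    n_singletons = length(singletons(fams)),
    n_mined_hits = minedCount,
    n_flagged_clusters = length(flagged),
    flagged_clusters = flagged,
    parameters = list(wId = wId, wJac = wJac, epsilon = epsilon,
                      minMembers = as.integer(minMembers),
                      scoreThreshold = scoreThreshold))
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, na = "null"),
             out("summary.json"))
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
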