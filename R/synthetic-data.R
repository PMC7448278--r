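#' Simulation configuration for synthetic BGC families
#'
#' Parameters of the fixture generator.  Identity targets are pairwise
#' member-to-member values: members of one family are mutated copies of a
#' family archetype, and family archetypes are mutated copies of a common
#' root, with per-position substitution rates chosen so that realized
#' within- and between-family identities match the targets in
#' expectation.  Jaccard targets are met by giving each family a shared
#' domain core plus per-member private domains, on top of a small
#' background of domains common to all clusters.
#'
#' @param nFamilies number of families.
#' @param familySizes integer vector of family sizes (recycled to
#'   \code{nFamilies}).
#' @param withinIdentity,betweenIdentity target pairwise backbone identity
#'   within and between families; \code{0 <= between < within <= 1}.
#' @param withinJaccard,betweenJaccard target pairwise domain-set Jaccard.
#' @param nSingletons number of unrelated background clusters.
#' @param domainPool pool of accessory domain names.
#' @param archetypeDomainArray backbone module string; the default
#'   \code{"A-T-C-A-T-C-T"} is the two-module NRPS architecture with a
#'   terminal extra thiolation domain (A = adenylation, T = thiolation,
#'   C = condensation).
#' @param coreSize size of the per-family shared accessory-domain core.
#' @param seqLengthRange backbone-domain sequence length range (residues).
#' @param seed mandatory integer RNG seed; identical seeds give
#'   byte-identical fixtures.
#' @return A list of class \code{"SimulationConfig"}.
#' @export
SimulationConfig <- function(nFamilies = 2L,
                             familySizes = 3L,
                             withinIdentity = 0.9,
                             betweenIdentity = 0.1,
                             withinJaccard = 0.8,
                             betweenJaccard = 0.1,
                             nSingletons = 2L,
                             domainPool = sprintf("PF%05d", 1:400),
                             archetypeDomainArray = "A-T-C-A-T-C-T",
                             coreSize = 8L,
                             seqLengthRange = c(300L, 600L),
                             seed) {
  if (missing(seed)) stop("SimulationConfig: seed is mandatory")
  if (!(betweenIdentity >= 0 && betweenIdentity < withinIdentity &&
        withinIdentity <= 1))
    stop("SimulationConfig: need 0 <= betweenIdentity < withinIdentity <= 1")
  if (!(betweenJaccard >= 0 && betweenJaccard < withinJaccard &&
        withinJaccard <= 1))
    stop("SimulationConfig: need 0 <= betweenJaccard < withinJaccard <= 1")
  familySizes <- rep_len(as.integer(familySizes), as.integer(nFamilies))
  if (any(familySizes < 1L)) stop("SimulationConfig: family sizes must be >= 1")
  structure(list(nFamilies = as.integer(nFamilies),
                 familySizes = familySizes,
                 withinIdentity = withinIdentity,
                 betweenIdentity = betweenIdentity,
                 withinJaccard = withinJaccard,
                 betweenJaccard = betweenJaccard,
                 nSingletons = as.integer(nSingletons),
                 domainPool = domainPool,
                 archetypeDomainArray = archetypeDomainArray,
                 coreSize = as.integer(coreSize),
                 seqLengthRange = as.integer(seqLengthRange),
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Randomly substitute residues of a protein sequence
#'
#' Each position is independently substituted with probability
#' \code{rate}, always to a uniformly chosen different residue (so at
#' rate 1 every position differs from the original).  Length is
#' preserved; no indels.
#'
#' @param seq protein sequence (20-letter alphabet).
#' @param rate per-position substitution probability in [0, 1].
#' @return Mutated sequence.
#' @export
mutateSequence <- function(seq, rate) {
  if (rate < 0 || rate > 1) stop("mutateSequence: rate must be in [0, 1]")
  chars <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(ch) {
      sample(setdiff(AA_ALPHABET_STRICT, ch), 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  paste(chars, collapse = "")
}

.randomProtein <- function(len) {
  paste(sample(AA_ALPHABET_STRICT, len, replace = TRUE), collapse = "")
}

# backbone slot layout from a module string like "A-T-C-A-T-C-T"
.slotTypes <- function(archetype) {
  mods <- strsplit(archetype, "-")[[1]]
  map <- c(A = "AMP-binding", T = "PCP", C = "Condensation")
  unknown <- setdiff(mods, names(map))
  if (length(unknown))
    stop("unknown module letter(s): ", paste(unknown, collapse = ", "))
  unname(map[mods])
}

#' Simulate families of gene clusters with ground truth
#'
#' Generates a \linkS4class{ClusterSet} of \code{nFamilies} families plus
#' background singletons.  Each backbone slot of the module architecture
#' has a root sequence; family archetypes are mutated copies of the roots
#' at rate \code{1 - sqrt(between/within)}, and members are mutated copies
#' of their archetype at rate \code{1 - sqrt(within)}, so that realized
#' member-member identity is \code{within} inside a family and
#' \code{between} across families, in expectation.  Domain arrays combine
#' the backbone type names, a shared background, a per-family core and
#' per-member private domains sized to hit the Jaccard targets in
#' expectation.  Deterministic under the config seed.
#'
#' @param config a \code{\link{SimulationConfig}}.
#' @return list(clusters = \linkS4class{ClusterSet},
#'   truth = list(partition = named family labels with \code{NA} for
#'   singletons, familyIds, singletonIds)).
#' @export
simulateFamilies <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  wi <- config$withinIdentity; bi <- config$betweenIdentity
  rMember <- 1 - sqrt(wi)
  rArch <- 1 - sqrt(bi / wi)

  slots <- .slotTypes(config$archetypeDomainArray)
  slotLens <- sample(seq(config$seqLengthRange[1], config$seqLengthRange[2]),
                     length(slots), replace = TRUE)
  roots <- vapply(slotLens, .randomProtein, character(1))

  # accessory-domain bookkeeping: shared background + per-family cores +
  # private domains, all drawn from the pool without replacement
  k <- config$coreSize
  p <- max(0L, round(k * (1 - config$withinJaccard) /
                       (2 * config$withinJaccard)))
  nBackboneNames <- length(unique(slots))
  bNeeded <- round(config$betweenJaccard * 2 * (k + p) /
                     (1 - config$betweenJaccard))
  bExtra <- max(0L, bNeeded - nBackboneNames)
  p <- max(0L, round((bExtra + nBackboneNames + k) *
                       (1 - config$withinJaccard) /
                       (2 * config$withinJaccard)))
  nMembers <- sum(config$familySizes)
  nUnits <- config$nFamilies + config$nSingletons
  need <- bExtra + nUnits * k + (nMembers + config$nSingletons) * p
  if (need > length(config$domainPool))
    stop(sprintf("simulateFamilies: domain pool too small (%d needed, %d available)",
                 need, length(config$domainPool)))
  pool <- sample(config$domainPool)   # shuffled, consumed left to right
  take <- function(n) {
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  background <- if (bExtra > 0L) take(bExtra) else character(0)

  makeCluster <- function(cid, genome, backboneSeqs, core, private) {
    bd <- split(backboneSeqs, slots)
    domainArray <- c(unique(slots), background, core, private)
    proteins <- stats::setNames(
      c(paste(backboneSeqs, collapse = ""), .randomProtein(120L)),
      paste0(cid, c("_p1", "_p2")))
    ClusterRecord(clusterId = cid, genomeId = genome,
                  productClass = "NRPS",
                  domainArray = domainArray,
                  backboneDomains = bd, proteins = proteins)
  }

  clusters <- list()
  partition <- integer(0)
  for (f in seq_len(config$nFamilies)) {
    archSeqs <- unname(vapply(roots, mutateSequence, character(1),
                              rate = rArch))
    core <- take(k)
    for (m in seq_len(config$familySizes[f])) {
      cid <- sprintf("fam%d_c%d", f, m)
      memberSeqs <- unname(vapply(archSeqs, mutateSequence, character(1),
                                  rate = rMember))
      private <- if (p > 0L) take(p) else character(0)
      clusters[[cid]] <- makeCluster(cid, sprintf("genome_f%d_m%d", f, m),
                                     memberSeqs, core, private)
      partition[cid] <- f
    }
  }
  for (s in seq_len(config$nSingletons)) {
    cid <- sprintf("single_%d", s)
    # singletons are independent random sequences: unrelated to any family
    sgSeqs <- vapply(slotLens, .randomProtein, character(1))
    core <- take(k)
    private <- if (p > 0L) take(p) else character(0)
    clusters[[cid]] <- makeCluster(cid, sprintf("genome_s%d", s),
                                   sgSeqs, core, private)
    partition[cid] <- NA_integer_
  }
  cs <- ClusterSet(unname(clusters))
  list(clusters = cs,
       truth = list(partition = partition,
                    familyIds = names(partition)[!is.na(partition)],
                    singletonIds = names(partition)[is.na(partition)]))
}

#' Simulate a domain-hit table with planted pass/fail rows
#'
#' Writes a domtblout file with \code{nTrue} rows that satisfy the filter
#' policy and \code{nDecoys} rows that each violate exactly one criterion
#' (short subject, weak E value, or wrong model accession, cycling in
#' that order).  The first decoy of the E-value kind sits just past the
#' inclusive threshold (policy E value times 1.0000001).
#'
#' @param nTrue,nDecoys row counts (>= 0).
#' @param policy a \linkS4class{FilterPolicy}.
#' @param path output path for the domtblout file.
#' @param seed integer RNG seed.
#' @param nGenomes number of genomes the true hits are spread over.
#' @return list(path, truth = data.frame(protein_id, keep)).
#' @export
simulateHitTable <- function(nTrue, nDecoys, policy = FilterPolicy(),
                             path = tempfile(fileext = ".domtblout"),
                             seed = 1L, nGenomes = 3L) {
  set.seed(seed)
  rows <- list(); truth <- list()
  rlen <- function(lo, hi) sample(seq(lo, hi), 1L)
  for (i in seq_len(nTrue)) {
    len <- rlen(policy@minSubjectLength, policy@minSubjectLength + 250L)
    ev <- policy@maxEvalue * 10^(-stats::runif(1, 1, 40))
    if (i == 1L) { len <- policy@minSubjectLength; ev <- policy@maxEvalue }
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = sprintf("true_p%03d", i),
      genome_id = sprintf("genome%d", ((i - 1L) %% nGenomes) + 1L),
      model_accession = policy@modelAccession,
      model_name = "IDO",
      full_seq_evalue = ev, bitscore = stats::runif(1, 200, 600),
      subject_length = len,
      env_start = 5L, env_end = len - 4L, stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <-
      data.frame(protein_id = sprintf("true_p%03d", i), keep = TRUE)
  }
  kinds <- rep_len(c("short", "evalue", "accession"), nDecoys)
  for (i in seq_len(nDecoys)) {
    len <- rlen(policy@minSubjectLength, policy@minSubjectLength + 250L)
    ev <- policy@maxEvalue * 10^(-stats::runif(1, 1, 40))
    acc <- policy@modelAccession
    if (kinds[i] == "short") len <- rlen(50L, policy@minSubjectLength - 1L)
    if (kinds[i] == "evalue")
      ev <- if (i <= 3L) policy@maxEvalue * 1.0000001 else
        policy@maxEvalue * 10^stats::runif(1, 1, 10)
    if (kinds[i] == "accession") acc <- "PF00501"
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = sprintf("decoy_p%03d", i),
      genome_id = sprintf("genome%d", ((i - 1L) %% nGenomes) + 1L),
      model_accession = acc, model_name = "IDO",
      full_seq_evalue = ev, bitscore = stats::runif(1, 20, 600),
      subject_length = len,
      env_start = 5L, env_end = len - 4L, stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <-
      data.frame(protein_id = sprintf("decoy_p%03d", i), keep = FALSE)
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character())
  if (length(rows)) writeDomtblout(hits, path) else writeLines(
    "# empty domtblout", path)
  list(path = path,
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(protein_id = character(), keep = logical()))
}
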