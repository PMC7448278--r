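#' Convert a similarity score to a distance
#'
#' Distance = 1 - score, so the family-calling radius epsilon = 0.55
#' corresponds to a combined similarity score of 0.45.
#'
#' @param score similarity score(s) in [0, 1].
#' @return Distance(s) in [0, 1].
#' @export
toDistance <- function(score) {
  if (any(score < 0 | score > 1)) stop("toDistance: score outside [0, 1]")
  1 - score
}

#' Distance matrix of a similarity result
#'
#' @param simResult a \linkS4class{SimilarityResult}.
#' @return Symmetric matrix of 1 - score with zero diagonal.
#' @export
distanceMatrix <- function(simResult) {
  stopifnot(is(simResult, "SimilarityResult"))
  d <- toDistance(scoreMatrix(simResult))
  diag(d) <- 0
  d
}

# DBSCAN on a precomputed distance matrix. Neighbourhoods are inclusive
# (d <= eps) and contain the point itself.  With minPts = 2 this reduces to
# connected components of the eps-threshold graph, noise = isolated points.
.dbscanPrecomputed <- function(d, eps, minPts) {
  n <- nrow(d)
  labels <- rep(NA_integer_, n)  # NA = noise/unvisited
  visited <- rep(FALSE, n)
  nextLabel <- 0L
  neighbours <- function(i) which(d[i, ] <= eps)
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- neighbours(i)
    if (length(nb) < minPts) next      # not core; may become border later
    nextLabel <- nextLabel + 1L
    labels[i] <- nextLabel
    queue <- setdiff(nb, i)
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      if (is.na(labels[q])) labels[q] <- nextLabel
      if (!visited[q]) {
        visited[q] <- TRUE
        nbq <- neighbours(q)
        if (length(nbq) >= minPts)     # q is core: expand
          queue <- c(queue, setdiff(nbq[is.na(labels[nbq]) |
                                          !visited[nbq]], q))
      }
    }
  }
  labels
}

#' Call gene cluster families by density clustering
#'
#' DBSCAN on the precomputed cluster distance matrix (1 - combined score)
#' with inclusive neighbourhood radius \code{epsilon} and
#' \code{minPts = minMembers}.  With the default minPts of 2 this is
#' exactly the connected components of the graph joining pairs at
#' distance <= epsilon; components of size one are reported as singletons
#' (density noise).
#'
#' @param dist symmetric distance matrix with zero diagonal (rownames are
#'   cluster ids), or a \linkS4class{SimilarityResult}.
#' @param epsilon neighbourhood radius on the distance scale; the default
#'   0.55 corresponds to a combined similarity score of 0.45.
#' @param minMembers DBSCAN minPts (minimum family size).
#' @return A \linkS4class{GCFAssignment}.
#' @export
callFamilies <- function(dist, epsilon = 0.55, minMembers = 2L) {
  if (is(dist, "SimilarityResult")) dist <- distanceMatrix(dist)
  if (!is.matrix(dist) || nrow(dist) != ncol(dist))
    stop("callFamilies: dist must be a square matrix")
  if (!isSymmetric(unname(dist), tol = 1e-12))
    stop("callFamilies: distance matrix must be symmetric")
  if (any(abs(diag(dist)) > 1e-12))
    stop("callFamilies: distance matrix must have zero diagonal")
  if (anyNA(dist)) stop("callFamilies: NA distances not allowed")
  ids <- rownames(dist)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(dist)))
  labels <- .dbscanPrecomputed(dist, epsilon, as.integer(minMembers))
  # relabel contiguously in order of first appearance
  seen <- unique(labels[!is.na(labels)])
  labels <- match(labels, seen)
  new("GCFAssignment",
      assignments = data.frame(cluster_id = ids, family = as.integer(labels),
                               stringsAsFactors = FALSE),
      epsilon = epsilon, minMembers = as.integer(minMembers))
}

#' Network edges above a similarity threshold
#'
#' Pairs of clusters whose combined score is at least the threshold; the
#' subgraphs of this network are the gene cluster families.
#'
#' @param simResult a \linkS4class{SimilarityResult}.
#' @param scoreThreshold inclusive minimum combined score (default 0.45,
#'   matching the epsilon = 0.55 family-calling radius).
#' @return data.frame(cluster_a, cluster_b, seq_identity, jaccard, score).
#' @export
networkEdges <- function(simResult, scoreThreshold = 0.45) {
  edges <- similarityEdges(simResult)
  edges[edges$score >= scoreThreshold, , drop = FALSE]
}

#' UPGMA dendrogram of a distance matrix
#'
#' Standard unweighted pair-group average-linkage clustering: iteratively
#' merge the closest pair of groups; the new node's height is half the
#' merge distance; distances to the merged group are the size-weighted
#' average of the members' distances.  Ties are broken deterministically
#' by the lexicographically smallest leaf labels of the candidate pairs.
#'
#' @param dist symmetric distance matrix with labelled rows, or a
#'   \linkS4class{SimilarityResult} (then distance = 1 - score).
#' @return A \linkS4class{Dendrogram}.
#' @examples
#' d <- matrix(c(0, .2, .6, .2, 0, .8, .6, .8, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgma(d)
#' @export
upgma <- function(dist) {
  if (is(dist, "SimilarityResult")) dist <- distanceMatrix(dist)
  if (!is.matrix(dist) || nrow(dist) != ncol(dist))
    stop("upgma: dist must be a square matrix")
  if (nrow(dist) < 2L) stop("upgma: need at least 2 leaves")
  if (anyNA(dist)) stop("upgma: NA distances not allowed")
  if (!isSymmetric(unname(dist), tol = 1e-12))
    stop("upgma: distance matrix must be symmetric")
  labels <- rownames(dist)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(dist)))
  leafset <- labels

  d <- dist
  active <- seq_len(nrow(d))
  newick <- labels                  # growing subtree strings
  height <- rep(0, nrow(d))         # height of each active node
  size <- rep(1L, nrow(d))
  rep_label <- labels               # lexicographic representative
  heights <- numeric(0)

  fmt <- function(x) as.character(round(x, 10))

  while (length(active) > 1L) {
    da <- d[active, active, drop = FALSE]
    dmin <- min(da[upper.tri(da)])
    cand <- which(da <= dmin + 1e-12 & upper.tri(da), arr.ind = TRUE)
    # tie-break: smallest (sorted) representative-label pair
    keyA <- pmin(rep_label[active[cand[, 1]]], rep_label[active[cand[, 2]]])
    keyB <- pmax(rep_label[active[cand[, 1]]], rep_label[active[cand[, 2]]])
    pick <- order(keyA, keyB)[1]
    i <- active[cand[pick, 1]]; j <- active[cand[pick, 2]]
    h <- d[i, j] / 2
    heights <- c(heights, h)
    # order children by representative label for a canonical Newick
    ch <- if (rep_label[i] <= rep_label[j]) c(i, j) else c(j, i)
    nwk <- sprintf("(%s:%s,%s:%s)",
                   newick[ch[1]], fmt(h - height[ch[1]]),
                   newick[ch[2]], fmt(h - height[ch[2]]))
    # merged node reuses slot i
    others <- setdiff(active, c(i, j))
    for (k in others) {
      dk <- (size[i] * d[i, k] + size[j] * d[j, k]) / (size[i] + size[j])
      d[i, k] <- d[k, i] <- dk
    }
    newick[i] <- nwk
    height[i] <- h
    size[i] <- size[i] + size[j]
    rep_label[i] <- min(rep_label[i], rep_label[j])
    active <- setdiff(active, j)
  }
  nwk <- paste0(newick[active], ";")
  new("Dendrogram", labels = leafset, newick = nwk, heights = heights,
      phylo = ape::read.tree(text = nwk))
}

#' Single-leaf dendrogram
#'
#' Degenerate tree used when a family has only one member.
#'
#' @param label the leaf label.
#' @return A \linkS4class{Dendrogram} with Newick \code{"label;"}.
#' @export
leafDendrogram <- function(label) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  new("Dendrogram", labels = label, newick = paste0(label, ";"),
      heights = numeric(0), phylo = NULL)
}
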