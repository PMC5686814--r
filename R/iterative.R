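#' Iterative refinement configuration
#'
#' A first clustering pass over a whole chromosome tends to produce
#' large, coarse clusters and correspondingly large TADs. Further rounds
#' re-cluster the largest clusters into sub-clusters, sharpening large
#' domains into sub-domains.
#'
#' @param maxRounds total clustering rounds including the first
#'   (default 3).
#' @param reclusterFraction fraction of clusters (largest first)
#'   selected for re-clustering each round; 0.3 and 0.5 are typical
#'   (default 0.5).
#' @param keepFloor minimum fraction of current clusters that must be
#'   kept unsplit (default 0.5); caps the selection.
#' @return a list of class "IterativeConfig".
#' @export
iterativeConfig <- function(maxRounds = 3L, reclusterFraction = 0.5,
                            keepFloor = 0.5) {
  if (maxRounds < 1L) stop("maxRounds must be >= 1")
  if (reclusterFraction <= 0 || reclusterFraction > 1 - keepFloor + 1e-12) {
    stop("reclusterFraction must lie in (0, 1 - keepFloor]")
  }
  structure(list(maxRounds = as.integer(maxRounds),
                 reclusterFraction = reclusterFraction,
                 keepFloor = keepFloor),
            class = "IterativeConfig")
}

#' Pick the largest clusters for re-clustering
#'
#' Clusters are ranked by member count (descending, ties toward the
#' lower cluster id) and the top \code{ceiling(fraction * k)} are
#' selected, capped so that at least \code{keepFloor} of the current
#' clusters remain unsplit.
#'
#' @param a a [ClusterAssignment-class].
#' @param cfg an [iterativeConfig()].
#' @return integer vector of selected cluster ids (possibly empty).
#' @export
selectClustersForRecluster <- function(a, cfg = iterativeConfig()) {
  stopifnot(is(a, "ClusterAssignment"))
  sizes <- table(clusterLabels(a))
  ids <- as.integer(names(sizes))
  k <- length(ids)
  if (k <= 1L) return(integer(0))
  ord <- order(-as.integer(sizes), ids)
  nSel <- min(ceiling(cfg$reclusterFraction * k),
              floor((1 - cfg$keepFloor) * k))
  if (nSel < 1L) return(integer(0))
  ids[ord][seq_len(nSel)]
}

#' One re-clustering round
#'
#' Each selected cluster's member bins are re-clustered (same algorithm
#' and metric, on their existing global feature vectors) with
#' K = sqrt(size / 2) per the rule-of-thumb estimate; the resulting
#' sub-cluster labels are renumbered to be globally unique. Unselected
#' clusters keep their bins together under a fresh label. Selected
#' clusters smaller than 4 bins are left unsplit (their K estimate would
#' fall below 2).
#'
#' @param f the [FeatureTable-class] the assignment was built on.
#' @param a the current [ClusterAssignment-class].
#' @param cfg an [iterativeConfig()].
#' @param algorithm,metric,seed,nRestarts clustering options as in
#'   [kmeansCluster()].
#' @return a new [ClusterAssignment-class] with refined labels.
#' @export
reclusterRound <- function(f, a, cfg = iterativeConfig(),
                           algorithm = "KM", metric = "euclidean",
                           seed = 1L, nRestarts = 10L) {
  stopifnot(is(f, "FeatureTable"), is(a, "ClusterAssignment"))
  selected <- selectClustersForRecluster(a, cfg)
  labels <- clusterLabels(a)
  if (!length(selected)) return(a)
  newLabels <- rep(NA_integer_, length(labels))
  nextId <- 1L
  X <- featureMatrix(f)
  for (id in sort(unique(labels))) {
    mem <- which(labels == id)
    if (!(id %in% selected) || length(mem) < 4L) {
      newLabels[mem] <- nextId
      nextId <- nextId + 1L
      next
    }
    subK <- min(estimateKHan(length(mem)), length(mem))
    # a view over the member bins; non-members count as excluded
    subF <- new("FeatureTable",
                features = X[mem, , drop = FALSE],
                binIndex = binIndex(f)[mem],
                excludedBins = setdiff(seq_len(nBins(f)) - 1L,
                                       binIndex(f)[mem]),
                nBins = nBins(f))
    subA <- tryCatch(
      .clusterDispatch(subF, subK, algorithm, metric,
                       seed = as.integer(seed) + id, nRestarts = nRestarts),
      error = function(e) NULL)
    if (is.null(subA)) {
      newLabels[mem] <- nextId
      nextId <- nextId + 1L
      next
    }
    sub <- clusterLabels(subA)
    remap <- setNames(seq_along(unique(sub)) + nextId - 1L,
                      sort(unique(sub)))
    newLabels[mem] <- as.integer(remap[as.character(sub)])
    nextId <- nextId + length(unique(sub))
  }
  new("ClusterAssignment",
      labels = newLabels,
      binIndex = binIndex(a),
      k = nextId - 1L,
      algorithm = a@algorithm,
      metric = a@metric,
      seed = as.integer(seed),
      withinVariance = NA_real_)
}

#' Multi-round TAD refinement
#'
#' Round 1 selects the best TAD set over a K range; each later round
#' re-clusters the largest clusters of the previous round and
#' re-extracts TADs. Mean TAD size shrinks across rounds as large
#' domains split into sub-domains; the round with the highest overall
#' quality is typically an intermediate one.
#'
#' @param m a [ContactMatrix-class].
#' @param cfg an [iterativeConfig()].
#' @param extractionCfg an [extractionConfig()].
#' @param kRange,algorithm,metric,seed,nRestarts options for the
#'   round-1 model selection (see [selectBestTadSet()]).
#' @return a list with one element per round, each a list of
#'   \code{round}, \code{tadSet} and \code{assignment}.
#' @export
runIterative <- function(m, cfg = iterativeConfig(),
                         extractionCfg = extractionConfig(),
                         kRange = NULL, algorithm = "KM",
                         metric = "euclidean", seed = 1L,
                         nRestarts = 10L) {
  stopifnot(is(m, "ContactMatrix"))
  f <- buildDiagonalFeatures(m)
  first <- selectBestTadSet(m, kRange = kRange, algorithm = algorithm,
                            metric = metric, seed = seed, cfg = extractionCfg,
                            nRestarts = nRestarts, features = f)
  a <- first$assignment
  ts <- first$best
  ts@provenance$round <- 1L
  rounds <- list(list(round = 1L, tadSet = ts, assignment = a))
  if (cfg$maxRounds > 1L) {
    for (r in 2L:cfg$maxRounds) {
      a <- reclusterRound(f, a, cfg, algorithm = algorithm, metric = metric,
                          seed = as.integer(seed) + 97L * r,
                          nRestarts = nRestarts)
      ts <- extractTads(m, a, extractionCfg)
      ts@provenance$round <- r
      rounds[[r]] <- list(round = r, tadSet = ts, assignment = a)
    }
  }
  rounds
}

#' Summarize an iterative run
#'
#' @param rounds result of [runIterative()].
#' @return data.frame with round, nTads, meanSizeBins, overallQuality.
#' @export
summarizeRounds <- function(rounds) {
  do.call(rbind, lapply(rounds, function(r) {
    tt <- tadTable(r$tadSet)
    data.frame(round = r$round,
               nTads = nrow(tt),
               meanSizeBins = if (nrow(tt)) {
                 mean(tt$endBin - tt$startBin + 1)
               } else NA_real_,
               overallQuality = overallQuality(r$tadSet))
  }))
}
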