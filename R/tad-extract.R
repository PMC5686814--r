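#' Extraction configuration
#'
#' Controls how labeled segments are classified and how TAD quality is
#' computed. The minimum TAD size of ~180 kb reflects the smallest
#' domains reported for mammalian genomes; at 40 kb bins this admits
#' domains of 5 bins and more. For unitless matrices (no resolution) the
#' minimum is expressed directly in bins.
#'
#' @param minTadBp minimum TAD span in bp (default 180000) when the
#'   matrix resolution is known.
#' @param minTadBins minimum TAD span in bins (default 3) for unitless
#'   matrices.
#' @param includeDiagonal include the main-diagonal self-contact cells in
#'   the within-TAD mean (default FALSE; self-contacts are dominated by
#'   proximity artifacts and inflate the within mean).
#' @return a list of class "ExtractionConfig".
#' @export
extractionConfig <- function(minTadBp = 180000L, minTadBins = 3L,
                             includeDiagonal = FALSE) {
  if (is.na(minTadBp) || minTadBp <= 0) stop("minTadBp must be positive")
  if (!is.null(minTadBins) && (is.na(minTadBins) || minTadBins < 1)) {
    stop("minTadBins must be >= 1")
  }
  structure(list(minTadBp = as.integer(minTadBp),
                 minTadBins = if (is.null(minTadBins)) NULL else
                   as.integer(minTadBins),
                 includeDiagonal = isTRUE(includeDiagonal)),
            class = "ExtractionConfig")
}

.asConfig <- function(cfg) {
  if (is.null(cfg)) extractionConfig() else cfg
}

#' Segment a per-bin label sequence into runs
#'
#' Maximal runs of equal labels become segments; NA labels mark gap bins.
#' The output tiles bins 0..nBins-1 with no overlap.
#'
#' @param labels vector of cluster labels, one per bin, NA for gaps.
#' @param nBins total number of bins (defaults to length(labels)).
#' @return data.frame with columns startBin, endBin, label, class
#'   (class is "GAP" for NA runs, "TAD" placeholder otherwise — see
#'   [classifySegments()]).
#' @export
segmentsFromLabels <- function(labels, nBins = length(labels)) {
  if (length(labels) != nBins) stop("one label per bin required")
  if (nBins == 0L) {
    return(data.frame(startBin = integer(0), endBin = integer(0),
                      label = integer(0), class = character(0)))
  }
  key <- ifelse(is.na(labels), ".gap", as.character(labels))
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(startBin = as.integer(starts - 1L),
             endBin = as.integer(ends - 1L),
             label = suppressWarnings(
               ifelse(r$values == ".gap", NA_integer_,
                      as.integer(r$values))),
             class = ifelse(r$values == ".gap", "GAP", "UNCLASSIFIED"),
             stringsAsFactors = FALSE)
}

#' Classify segments as TAD, boundary or gap
#'
#' Gap runs stay GAP. Other segments are TADs when their span reaches the
#' minimum TAD size (bins * resolution >= minTadBp when the resolution is
#' known, else bins >= minTadBins) and boundaries otherwise.
#'
#' @param segments segment table from [segmentsFromLabels()].
#' @param cfg an [extractionConfig()].
#' @param resolution bin width in bp or NA for unitless matrices.
#' @return the segment table with the class column filled in.
#' @export
classifySegments <- function(segments, cfg = extractionConfig(),
                             resolution = NA) {
  cfg <- .asConfig(cfg)
  spanBins <- segments$endBin - segments$startBin + 1L
  if (!is.na(resolution)) {
    isTad <- spanBins * as.numeric(resolution) >= cfg$minTadBp
  } else {
    if (is.null(cfg$minTadBins)) {
      stop("unitless matrix: set minTadBins in the extraction config")
    }
    isTad <- spanBins >= cfg$minTadBins
  }
  segments$class <- ifelse(segments$class == "GAP", "GAP",
                           ifelse(isTad, "TAD", "BOUNDARY"))
  segments
}

# mean contact between the bins of two inclusive 0-based ranges
.rectMean <- function(v, a, b) {
  mean(v[(a[1]:a[2]) + 1L, (b[1]:b[2]) + 1L])
}

.intraMean <- function(v, tad, includeDiagonal) {
  block <- v[(tad[1]:tad[2]) + 1L, (tad[1]:tad[2]) + 1L, drop = FALSE]
  if (includeDiagonal) {
    mean(block[upper.tri(block, diag = TRUE)])
  } else {
    if (nrow(block) < 2L) {
      stop("single-bin TAD: within-TAD mean undefined with the diagonal ",
           "excluded")
    }
    mean(block[upper.tri(block)])
  }
}

#' Quality of one TAD (within minus between mean contact)
#'
#' intra(i) is the mean contact over the TAD's diagonal block (upper
#' triangle, self-contacts excluded unless configured otherwise);
#' inter(i, j) is the mean contact over the rectangle between TAD i's
#' bins and the bins of the adjacent TAD j (intervening boundary/gap
#' segments are skipped). Interior TADs average the two neighbor values;
#' terminal TADs use their single neighbor. The quality is
#' intra(i) - inter(i, j).
#'
#' @param m a [ContactMatrix-class].
#' @param tads matrix/data.frame of ordered TAD ranges (columns
#'   startBin, endBin, 0-based inclusive).
#' @param i index of the TAD to score (1-based into \code{tads}).
#' @param cfg an [extractionConfig()].
#' @return scalar quality score.
#' @export
tadQuality <- function(m, tads, i, cfg = extractionConfig()) {
  stopifnot(is(m, "ContactMatrix"))
  cfg <- .asConfig(cfg)
  v <- contactValues(m)
  tads <- as.matrix(as.data.frame(tads)[, c("startBin", "endBin")])
  if (i < 1L || i > nrow(tads)) stop("TAD index out of range")
  this <- tads[i, ]
  intra <- .intraMean(v, this, cfg$includeDiagonal)
  inters <- numeric(0)
  if (i > 1L) inters <- c(inters, .rectMean(v, this, tads[i - 1L, ]))
  if (i < nrow(tads)) inters <- c(inters, .rectMean(v, this, tads[i + 1L, ]))
  if (!length(inters)) {
    # lone TAD: fall back to the mean contact with all bins outside it
    outside <- setdiff(seq_len(nrow(v)) - 1L, this[1]:this[2])
    inter <- if (length(outside)) {
      mean(v[(this[1]:this[2]) + 1L, outside + 1L])
    } else 0
  } else {
    inter <- mean(inters)
  }
  intra - inter
}

.tadSetFromSegments <- function(m, segments, cfg) {
  tad <- segments[segments$class == "TAD", , drop = FALSE]
  q <- if (nrow(tad)) {
    vapply(seq_len(nrow(tad)), function(i) tadQuality(m, tad, i, cfg),
           numeric(1))
  } else numeric(0)
  new("TadSet",
      segments = segments,
      tadQualities = q,
      overallQuality = if (length(q)) mean(q) else -Inf,
      chrom = chromName(m),
      resolution = resolutionBp(m))
}

#' Extract a classified, scored TAD set from a clustering
#'
#' Composes run segmentation, size classification and per-TAD quality
#' scoring. Gap bins excluded from the feature table re-enter as GAP
#' segments.
#'
#' @param m a [ContactMatrix-class].
#' @param assignment a [ClusterAssignment-class] over the matrix's
#'   non-gap bins.
#' @param cfg an [extractionConfig()].
#' @return A [TadSet-class].
#' @export
extractTads <- function(m, assignment, cfg = extractionConfig()) {
  stopifnot(is(m, "ContactMatrix"), is(assignment, "ClusterAssignment"))
  cfg <- .asConfig(cfg)
  n <- nBins(m)
  labels <- rep(NA_integer_, n)
  labels[binIndex(assignment) + 1L] <- clusterLabels(assignment)
  seg <- segmentsFromLabels(labels, n)
  seg <- classifySegments(seg, cfg, resolution = resolutionBp(m))
  ts <- .tadSetFromSegments(m, seg, cfg)
  ts@kUsed <- assignment@k
  ts@provenance <- list(algorithm = assignment@algorithm,
                        metric = assignment@metric,
                        seed = assignment@seed)
  ts
}

#' Select the best-scoring TAD set over a range of cluster numbers
#'
#' Clusters the features at every K in the range, extracts and scores a
#' TAD set for each, and returns the set with the highest overall
#' quality; ties break toward the smallest K.
#'
#' @param m a [ContactMatrix-class].
#' @param kRange integer vector \code{c(lo, hi)} (lo >= 2); defaults to
#'   the +/-10 window around the sqrt(n/2) estimate.
#' @param algorithm "KM", "HC" or "EM".
#' @param metric distance metric for KM/HC.
#' @param seed integer seed for stochastic algorithms.
#' @param cfg an [extractionConfig()].
#' @param nRestarts k-means restarts.
#' @param features optional precomputed [FeatureTable-class].
#' @return list with \code{best} (TadSet), \code{perK} (data.frame of
#'   k and overallQuality), and \code{assignment} (the winning
#'   ClusterAssignment). When no K yields a TAD, \code{best} is a TadSet
#'   with zero TADs and overall quality -Inf.
#' @export
selectBestTadSet <- function(m, kRange = NULL, algorithm = "KM",
                             metric = "euclidean", seed = 1L,
                             cfg = extractionConfig(), nRestarts = 10L,
                             features = NULL) {
  stopifnot(is(m, "ContactMatrix"))
  cfg <- .asConfig(cfg)
  f <- if (is.null(features)) buildDiagonalFeatures(m) else features
  nPts <- nrow(featureMatrix(f))
  if (is.null(kRange)) {
    kRange <- kSearchWindow(estimateKHan(nPts), nPts)
  }
  lo <- as.integer(kRange[1]); hi <- as.integer(min(kRange[2], nPts))
  if (lo < 2L) stop("kRange lower bound must be >= 2")
  if (hi < lo) stop("empty K range")
  best <- NULL; bestA <- NULL
  perK <- data.frame(k = lo:hi, overallQuality = NA_real_)
  for (idx in seq_len(hi - lo + 1L)) {
    k <- lo + idx - 1L
    a <- .clusterDispatch(f, k, algorithm, metric, seed, nRestarts)
    ts <- extractTads(m, a, cfg)
    perK$overallQuality[idx] <- overallQuality(ts)
    if (is.null(best) || overallQuality(ts) > overallQuality(best)) {
      best <- ts
      bestA <- a
    }
  }
  list(best = best, perK = perK, assignment = bestA)
}
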