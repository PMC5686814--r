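#' Classify how one TAD relates to another annotation
#'
#' Given a TAD from method A and the full TAD set of method B:
#' \itemize{
#'   \item Case "A": some B TAD matches both boundaries within
#'     \code{tol} bins (exact match).
#'   \item Case "B": two or more B TADs lie fully within the A TAD
#'     (within tolerance): the A TAD contains sub-TADs.
#'   \item Case "C": some B TAD overlaps it but neither matches nor is
#'     contained twice over (conflict).
#'   \item "none": no B TAD overlaps the region. (The converse
#'     situation — a region without an A TAD that B annotates — is
#'     obtained by swapping the two sets.)
#' }
#'
#' @param tadA numeric length-2 vector (startBin, endBin, 0-based
#'   inclusive) or a one-row segment table.
#' @param tadsB a [TadSet-class].
#' @param tol boundary tolerance in bins (default 0: strict).
#' @return one of "A", "B", "C", "none".
#' @export
matchCase <- function(tadA, tadsB, tol = 0L) {
  stopifnot(is(tadsB, "TadSet"))
  if (is.data.frame(tadA)) tadA <- c(tadA$startBin[1], tadA$endBin[1])
  sA <- tadA[1]; eA <- tadA[2]
  tb <- tadTable(tadsB)
  if (!nrow(tb)) return("none")
  sB <- tb$startBin; eB <- tb$endBin
  if (any(abs(sB - sA) <= tol & abs(eB - eA) <= tol)) return("A")
  contained <- sB >= sA - tol & eB <= eA + tol
  if (sum(contained) >= 2L) return("B")
  if (any(sB <= eA & eB >= sA)) return("C")
  "none"
}

#' Consistency between two TAD annotations
#'
#' A TAD of method A counts as "also detected" by method B when its case
#' is A (exact match) or B (contains two or more B sub-TADs). The report
#' carries the per-TAD case labels and the percentage detected.
#'
#' @param tadsA,tadsB [TadSet-class] objects on the same binning.
#' @param tol boundary tolerance in bins.
#' @return list of class "ConsistencyReport": \code{perTad} (data.frame
#'   startBin, endBin, case), \code{percentDetected} in [0, 100], and
#'   \code{toleranceBins}.
#' @export
consistencyPercentage <- function(tadsA, tadsB, tol = 0L) {
  stopifnot(is(tadsA, "TadSet"), is(tadsB, "TadSet"))
  ta <- tadTable(tadsA)
  if (!nrow(ta)) stop("method A has no TADs; consistency undefined")
  cases <- vapply(seq_len(nrow(ta)), function(i) {
    matchCase(c(ta$startBin[i], ta$endBin[i]), tadsB, tol)
  }, character(1))
  structure(list(
    perTad = data.frame(startBin = ta$startBin, endBin = ta$endBin,
                        case = cases, stringsAsFactors = FALSE),
    percentDetected = 100 * mean(cases %in% c("A", "B")),
    toleranceBins = as.integer(tol)),
    class = "ConsistencyReport")
}

#' @export
print.ConsistencyReport <- function(x, ...) {
  cat("ConsistencyReport:", nrow(x$perTad), "TADs compared,",
      sprintf("%.1f%%", x$percentDetected), "detected (cases A/B)",
      "at tolerance", x$toleranceBins, "bin(s)\n")
  print(table(factor(x$perTad$case, levels = c("A", "B", "C", "none"))))
  invisible(x)
}

#' Peak enrichment profile around TAD borders
#'
#' For every TAD border (the start and end bin of each TAD), counts the
#' peaks whose midpoint falls into each bin at offsets
#' \code{-windowBins..windowBins} from the border and averages the
#' counts over all borders. Boundary enrichment of architectural marks
#' (CTCF, promoter/enhancer histone modifications) shows as a maximum
#' at offset 0.
#'
#' @param tads a [TadSet-class] with known resolution (or pass
#'   \code{resolution}).
#' @param peaks a GRanges of peaks (see [readPeaksBed()]); only seqnames
#'   matching the TadSet's chromosome are used, unless the TadSet chrom
#'   is absent from the peaks entirely, in which case all peaks count.
#' @param resolution bin width in bp.
#' @param windowBins half-width of the offset window (default 1).
#' @return list of class "EnrichmentProfile": \code{profile} (data.frame
#'   offsetBin, meanPeakCount) and \code{nBoundaries}.
#' @export
boundaryPeakEnrichment <- function(tads, peaks,
                                   resolution = resolutionBp(tads),
                                   windowBins = 1L) {
  stopifnot(is(tads, "TadSet"))
  if (is.na(resolution)) stop("resolution required for peak enrichment")
  resolution <- as.numeric(resolution)
  tb <- tadTable(tads)
  if (!nrow(tb)) stop("TadSet has no TADs; no borders to profile")
  borders <- sort(unique(c(tb$startBin, tb$endBin)))
  offsets <- (-windowBins):windowBins
  if (length(peaks) == 0L) {
    warning("empty peak set; profile is all zero")
    counts <- numeric(length(offsets))
  } else {
    sel <- as.character(GenomicRanges::seqnames(peaks)) == chromName(tads)
    if (any(sel)) peaks <- peaks[sel]
    mid0 <- (GenomicRanges::start(peaks) - 1 +
             GenomicRanges::end(peaks)) / 2
    peakBin <- floor(mid0 / resolution)
    binCounts <- table(peakBin)
    countAt <- function(b) {
      v <- binCounts[as.character(b)]
      ifelse(is.na(v), 0, as.numeric(v))
    }
    counts <- vapply(offsets, function(o) {
      mean(vapply(borders + o, countAt, numeric(1)))
    }, numeric(1))
  }
  structure(list(
    profile = data.frame(offsetBin = offsets, meanPeakCount = counts),
    nBoundaries = length(borders)),
    class = "EnrichmentProfile")
}

#' @export
print.EnrichmentProfile <- function(x, ...) {
  cat("EnrichmentProfile over", x$nBoundaries, "borders\n")
  print(x$profile, row.names = FALSE)
  invisible(x)
}
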