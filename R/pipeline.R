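#' End-to-end TAD calling pipeline
#'
#' Reads (or accepts) a contact matrix, builds diagonal features,
#' chooses the cluster-number policy, extracts and scores TAD sets and
#' writes BED tracks plus a per-K quality table. This is the function
#' behind the \code{tadclust call} command.
#'
#' @param input a [ContactMatrix-class], or a path to a dense matrix
#'   file (see [readDenseMatrix()]).
#' @param outPrefix output path prefix; writes \code{<prefix>.tads.bed}
#'   (plus boundary/gap companions) and \code{<prefix>.perK.tsv}. NULL
#'   suppresses file output.
#' @param resolution bin width in bp (used when \code{input} is a path,
#'   and for BED output).
#' @param chrom chromosome label (when \code{input} is a path).
#' @param kPolicy "han-window" (default: search the +/-10 window around
#'   sqrt(n/2)), "elbow" (search 2..kMaxElbow, pick the elbow K), or
#'   "fixed" (use \code{k}).
#' @param k fixed K for \code{kPolicy = "fixed"}.
#' @param kMaxElbow upper K for the elbow scan (default 10).
#' @param algorithm,metric,seed,nRestarts clustering options.
#' @param cfg an [extractionConfig()].
#' @param iterative NULL, or an [iterativeConfig()] to run multi-round
#'   refinement after the round-1 selection.
#' @return for a plain run, the [selectBestTadSet()] result (plus
#'   \code{elbow} when the elbow policy was used); with
#'   \code{iterative}, the [runIterative()] round list with a
#'   \code{summary} attribute.
#' @export
callTads <- function(input, outPrefix = NULL, resolution = NA,
                     chrom = "chrU", kPolicy = c("han-window", "elbow",
                                                 "fixed"),
                     k = NULL, kMaxElbow = 10L, algorithm = "KM",
                     metric = "euclidean", seed = 1L, nRestarts = 10L,
                     cfg = extractionConfig(), iterative = NULL) {
  kPolicy <- match.arg(kPolicy)
  m <- if (is(input, "ContactMatrix")) input else
    readDenseMatrix(input, resolution = resolution, chrom = chrom)
  f <- buildDiagonalFeatures(m)
  nPts <- nrow(featureMatrix(f))
  elbow <- NULL
  kRange <- switch(kPolicy,
    "han-window" = kSearchWindow(estimateKHan(nPts), nPts),
    "elbow" = {
      elbow <- elbowK(f, 2L, min(kMaxElbow, nPts - 1L),
                      algorithm = algorithm, metric = metric, seed = seed,
                      nRestarts = nRestarts)
      rep(elbow$kElbow, 2L)
    },
    "fixed" = {
      if (is.null(k)) stop("kPolicy 'fixed' requires k")
      rep(as.integer(k), 2L)
    })
  if (!is.null(iterative)) {
    res <- runIterative(m, cfg = iterative, extractionCfg = cfg,
                        kRange = kRange, algorithm = algorithm,
                        metric = metric, seed = seed,
                        nRestarts = nRestarts)
    attr(res, "summary") <- summarizeRounds(res)
    bestRound <- which.max(attr(res, "summary")$overallQuality)
    best <- res[[bestRound]]$tadSet
  } else {
    res <- selectBestTadSet(m, kRange = kRange, algorithm = algorithm,
                            metric = metric, seed = seed, cfg = cfg,
                            nRestarts = nRestarts, features = f)
    res$elbow <- elbow
    best <- res$best
  }
  if (!is.null(outPrefix)) {
    writeTadsBed(best, paste0(outPrefix, ".tads.bed"),
                 resolution = if (!is.na(resolutionBp(m)))
                   resolutionBp(m) else 1L)
    perK <- if (!is.null(iterative)) attr(res, "summary") else res$perK
    write.table(perK, paste0(outPrefix, ".perK.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  res
}
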