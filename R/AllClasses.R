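#' @import methods
#' @importFrom stats cor dist hclust cutree median rnorm rpois runif sd setNames
#' @importFrom utils read.table write.table
NULL

#' ContactMatrix: an intra-chromosomal Hi-C contact matrix
#'
#' Container for one square, symmetric, non-negative contact matrix at a
#' fixed bin resolution. \code{values[i, j]} holds the (normalized)
#' interaction frequency between bins \code{i} and \code{j} of one
#' chromosome. Unitless matrices (simulated data with no genomic
#' coordinates) carry \code{resolution = NA}.
#'
#' @slot values numeric matrix, N x N, symmetric, non-negative.
#' @slot resolution integer bin width in bp, or \code{NA_integer_} for
#'   unitless matrices.
#' @slot chrom single character chromosome label.
#'
#' @seealso [readDenseMatrix()], [readSparseTriples()],
#'   [generateBlockMatrix()]
#' @export
setClass("ContactMatrix",
  representation(
    values = "matrix",
    resolution = "integer",
    chrom = "character"
  ),
  prototype(resolution = NA_integer_, chrom = "chrU")
)

setValidity("ContactMatrix", function(object) {
  v <- object@values
  msg <- character(0)
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  if (any(!is.finite(v))) msg <- c(msg, "values must be finite (no NaN/Inf)")
  else {
    if (any(v < 0)) msg <- c(msg, "values must be non-negative")
    if (max(abs(v - t(v))) > 1e-8) {
      msg <- c(msg, "values must be symmetric (tolerance 1e-8)")
    }
  }
  if (length(object@chrom) != 1L) msg <- c(msg, "chrom must be length 1")
  if (length(object@resolution) != 1L) {
    msg <- c(msg, "resolution must be length 1")
  } else if (!is.na(object@resolution) && object@resolution <= 0L) {
    msg <- c(msg, "resolution must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ContactMatrix
#'
#' Small asymmetries (up to \code{1e-6 * max(values)}) are symmetrized by
#' averaging with the transpose; larger asymmetries are an error.
#'
#' @param values square numeric matrix of non-negative contact counts.
#' @param resolution bin width in bp, or \code{NA} for unitless matrices.
#' @param chrom chromosome label used in BED output.
#' @return A [ContactMatrix-class] object.
#' @examples
#' m <- ContactMatrix(matrix(c(0, 1, 1, 0), 2), chrom = "chr1")
#' nBins(m)
#' @export
ContactMatrix <- function(values, resolution = NA, chrom = "chrU") {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("contact matrix must be square, got ", nrow(values), " x ",
         ncol(values))
  }
  if (any(!is.finite(values))) stop("contact matrix contains NaN/Inf")
  if (any(values < 0)) stop("contact matrix contains negative entries")
  asym <- max(abs(values - t(values)))
  tol <- 1e-6 * max(values, 1e-300)
  if (asym > tol) {
    stop("matrix asymmetry ", format(asym),
         " exceeds tolerance; refusing to symmetrize")
  }
  if (asym > 0) values <- (values + t(values)) / 2
  dimnames(values) <- NULL
  new("ContactMatrix",
      values = values,
      resolution = if (is.na(resolution)) NA_integer_ else
        as.integer(resolution),
      chrom = as.character(chrom))
}

#' FeatureTable: per-bin contact-profile feature vectors
#'
#' One row per non-gap bin; each row is the concatenation of the bin's
#' matrix row and matrix column (length 2N), describing the bin's full
#' interaction profile. Gap bins (all-zero rows) carry no feature row and
#' are listed in \code{excludedBins}.
#'
#' @slot features numeric matrix, (N - #gaps) x 2N.
#' @slot binIndex integer 0-based bin index of each feature row.
#' @slot excludedBins integer 0-based indices of gap bins.
#' @slot nBins integer total number of bins N in the source matrix.
#' @seealso [buildDiagonalFeatures()]
#' @export
setClass("FeatureTable",
  representation(
    features = "matrix",
    binIndex = "integer",
    excludedBins = "integer",
    nBins = "integer"
  )
)

# validity stays permissive on shape so that subset views (used by the
# iterative re-clustering) and bespoke tables are representable; the
# (N - #gaps) x 2N shape contract is guaranteed by buildDiagonalFeatures
setValidity("FeatureTable", function(object) {
  msg <- character(0)
  if (length(object@binIndex) != nrow(object@features)) {
    msg <- c(msg, "binIndex must index the feature rows")
  }
  if (anyDuplicated(c(object@binIndex, object@excludedBins))) {
    msg <- c(msg, "binIndex and excludedBins must partition distinct bins")
  }
  if (anyNA(object@features)) msg <- c(msg, "features must not contain NA")
  if (length(msg)) msg else TRUE
})

#' ClusterAssignment: labels from one clustering run
#'
#' @slot labels integer cluster label per non-gap bin (bin order follows
#'   \code{binIndex}).
#' @slot binIndex integer 0-based bin index for each label.
#' @slot k integer number of clusters requested.
#' @slot algorithm "KM", "HC" or "EM".
#' @slot metric "euclidean", "pearson" or "cityblock" (ignored for EM).
#' @slot seed integer seed used (NA for deterministic algorithms).
#' @slot withinVariance within-cluster sum of squared distances of the run.
#' @export
setClass("ClusterAssignment",
  representation(
    labels = "integer",
    binIndex = "integer",
    k = "integer",
    algorithm = "character",
    metric = "character",
    seed = "integer",
    withinVariance = "numeric"
  )
)

setValidity("ClusterAssignment", function(object) {
  msg <- character(0)
  if (length(object@labels) != length(object@binIndex)) {
    msg <- c(msg, "labels and binIndex lengths differ")
  }
  if (any(is.na(object@labels))) msg <- c(msg, "labels must not be NA")
  if (length(unique(object@labels)) > object@k) {
    msg <- c(msg, "more distinct labels than k")
  }
  if (length(object@withinVariance) == 1L &&
      !is.na(object@withinVariance) && object@withinVariance < -1e-12) {
    msg <- c(msg, "withinVariance must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' TadSet: classified, scored segments tiling a chromosome
#'
#' Ordered, non-overlapping segments covering bins \code{0..N-1}, each
#' classified as TAD, BOUNDARY or GAP. TAD segments carry a quality score:
#' the mean within-domain contact frequency minus the mean contact
#' frequency to adjacent domains.
#'
#' @slot segments data.frame with columns \code{startBin}, \code{endBin}
#'   (0-based inclusive), \code{label} (cluster id, NA for gaps) and
#'   \code{class} ("TAD", "BOUNDARY" or "GAP").
#' @slot tadQualities numeric, one score per TAD segment (in segment order).
#' @slot overallQuality mean of \code{tadQualities}; \code{-Inf} when the
#'   set has no TAD.
#' @slot kUsed integer number of clusters behind this call.
#' @slot chrom chromosome label.
#' @slot resolution integer bin width in bp or NA.
#' @slot provenance list of run metadata (algorithm, metric, seed, round).
#' @seealso [extractTads()], [selectBestTadSet()], [tadSegments()]
#' @export
setClass("TadSet",
  representation(
    segments = "data.frame",
    tadQualities = "numeric",
    overallQuality = "numeric",
    kUsed = "integer",
    chrom = "character",
    resolution = "integer",
    provenance = "list"
  ),
  prototype(kUsed = NA_integer_, chrom = "chrU",
            resolution = NA_integer_, provenance = list())
)

setValidity("TadSet", function(object) {
  seg <- object@segments
  msg <- character(0)
  need <- c("startBin", "endBin", "label", "class")
  if (!all(need %in% names(seg))) {
    return("segments must have columns startBin, endBin, label, class")
  }
  if (nrow(seg)) {
    if (any(seg$startBin > seg$endBin)) {
      msg <- c(msg, "segment start must not exceed end")
    }
    if (nrow(seg) > 1) {
      if (any(seg$startBin[-1] != seg$endBin[-nrow(seg)] + 1L)) {
        msg <- c(msg, "segments must tile contiguously")
      }
    }
    if (seg$startBin[1] != 0L) msg <- c(msg, "segments must start at bin 0")
    if (!all(seg$class %in% c("TAD", "BOUNDARY", "GAP"))) {
      msg <- c(msg, "segment class must be TAD/BOUNDARY/GAP")
    }
  }
  if (length(object@tadQualities) != sum(seg$class == "TAD")) {
    msg <- c(msg, "one quality per TAD segment required")
  }
  if (length(msg)) msg else TRUE
})
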